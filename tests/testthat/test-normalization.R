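test_that("F-J values are reporter minus housekeeping Ct", {
  w <- tibble::tibble(
    plate_id = "P01", well = sprintf("A%02d", 1:3),
    strain_id = c("s1", "s2", "s3"), condition = "KCl", role = "library",
    ct_fam = c(22.0, 20.0, 25.4), ct_joe = c(22.0, 23.0, 23.1)
  )
  expect_equal(compute_fj(w)$fj, c(0.0, -3.0, 2.3))
  w$ct_fam[1] <- NA
  expect_error(compute_fj(w), "filter_wells")
})

test_that("EM flags an all-identical plate as degenerate at that value", {
  fit <- fit_mixture_em(rep(1.7, 96))
  expect_true(fit$degenerate)
  expect_true(fit$converged)
  expect_equal(fit$means, c(1.7, 1.7))
  expect_error(fit_mixture_em(rnorm(7)), "at least 8")
})

test_that("EM recovers both populations of a 90/6 plate within 0.15", {
  set.seed(501)
  bulk <- rnorm(90, 0, 0.3)
  outliers <- rnorm(6, 3.0, 0.3)
  fit <- fit_mixture_em(c(bulk, outliers))
  expect_false(fit$degenerate)
  maj <- fit$majority_component
  min_c <- 3 - maj
  # oracle: per-label sample means from the known labels
  expect_lt(abs(fit$means[maj] - mean(bulk)), 0.15)
  expect_lt(abs(fit$means[min_c] - mean(outliers)), 0.15)
  expect_gt(fit$weights[maj], 0.8)
})

test_that("the EM log-likelihood trace never decreases", {
  set.seed(77)
  cases <- list(
    rnorm(50), c(rnorm(40, 0, 0.2), rnorm(10, 2, 0.4)),
    runif(30, -1, 1), c(rep(0, 20), rnorm(10, 4, 0.1))
  )
  for (x in cases) {
    fit <- fit_mixture_em(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("EM matches an independent mixture fitter on a clean sample", {
  withr::local_package("mclust")
  set.seed(99)
  x <- c(rnorm(70, -0.1, 0.25), rnorm(26, 2.4, 0.35))
  fit <- fit_mixture_em(x)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("mixture normalization centers nulls and flips the sign", {
  # constant plate: everything normalizes to exactly 0
  norm <- normalize_plate(make_fj(rep(2.2, 12)))
  expect_equal(norm$log2_ratio, rep(0, 12))

  # spiked plate, noise-free: spikes sit 2.5 below the null mean in F-J and
  # must come out at +2.5; oracle is manual centering
  values <- c(rep(0.8, 86), rep(0.8 - 2.5, 10))
  norm <- normalize_plate(make_fj(values))
  expect_equal(norm$log2_ratio[1:86], rep(0, 86), tolerance = 1e-9)
  expect_equal(norm$log2_ratio[87:96], rep(2.5, 10), tolerance = 1e-9)
})

test_that("normalization is invariant to a reporter-channel run offset", {
  set.seed(31)
  base <- c(rnorm(88, 0.5, 0.3), rnorm(8, 0.5 - 2.8, 0.3))
  for (offset in c(0.3, 0.45, 0.6)) {
    n1 <- normalize_plate(make_fj(base))
    n2 <- normalize_plate(make_fj(base + offset))
    expect_lt(max(abs(n1$log2_ratio - n2$log2_ratio)), 1e-6)
  }
})

test_that("spiked wells are kept out of the majority population", {
  set.seed(41)
  for (sep in c(1.5, 2.5, 3.5)) {
    values <- c(rnorm(88, 0, 0.3), rnorm(8, -sep, 0.3))
    fit <- fit_mixture_em(values)
    resp_major <- fit$responsibilities[89:96, fit$majority_component]
    expect_true(all(resp_major < 0.5))
  }
})

test_that("control-based normalization zeroes the controls", {
  fj <- make_fj(c(rep(1.2, 4), -0.8),
                role = c(rep("control_center_peak", 4), "library"))
  norm <- normalize_with_controls(fj)
  expect_equal(norm$log2_ratio[5], 2.0)
  expect_equal(norm$log2_ratio[1:4], rep(0, 4))

  # all wells controls: mean-zero sign-flipped residuals
  fj_all <- make_fj(c(1, 2, 3, 4), role = rep("control_center_peak", 4))
  norm_all <- normalize_with_controls(fj_all)
  expect_equal(mean(norm_all$log2_ratio), 0)
  expect_equal(norm_all$log2_ratio, -(c(1, 2, 3, 4) - 2.5))

  expect_error(normalize_with_controls(make_fj(1:8)), "control")
  too_few <- make_fj(1:8, role = c(rep("control_center_peak", 3),
                                   rep("library", 5)))
  expect_error(normalize_with_controls(too_few), "at least 4")
})

test_that("noise-free re-arrayed plates recover true effects exactly", {
  cfg <- noise_free_config(n_strains = 144, seed = 6)
  truth <- simulate_truth(cfg)
  hits <- truth$strain_id[1:48]
  truth$effect_kcl[1:48] <- seq(1.0, 4.5, length.out = 48)
  truth$is_hit[1:48] <- TRUE
  truth$true_kcl_level[1:48] <- truth$effect_kcl[1:48]
  controls <- truth$strain_id[49:96]
  wells <- simulate_rearray(truth, cfg, hits, controls, condition = "KCl")
  norm <- normalize_screen(wells, method = "controls")
  got <- norm$log2_ratio[match(hits, norm$strain_id)]
  expect_equal(got, truth$effect_kcl[1:48], tolerance = 1e-9)
})

test_that("EM beats a brute-force parameter grid on tiny inputs", {
  set.seed(13)
  for (i in 1:3) {
    x <- c(rnorm(6, 0.2, 0.08), rnorm(6, 0.75, 0.08))
    fit <- fit_mixture_em(x)
    grid_best <- grid_mixture_loglik(x, res = 0.05, mean_range = c(0, 1),
                                     sd_max = 0.5)
    expect_gte(fit$log_likelihood, grid_best)
  }
})

test_that("normalize_screen keeps per-plate fits and collapse averages runs", {
  scr <- simulate_screen(screen_config(n_strains = 192, seed = 10), "KCl")
  norm <- normalize_screen(filter_wells(scr$wells)$wells)
  diag <- mixture_diagnostics(norm)
  expect_equal(nrow(diag), 2)
  # within-plate majority-member mean is zero by construction
  fits <- attr(norm, "mixture_fits")
  for (key in names(fits)) {
    fit <- fits[[key]]
    plate <- sub("/.*", "", key)
    vals <- norm$log2_ratio[norm$plate_id == plate]
    members <- fit$responsibilities[, fit$majority_component] >= 0.5
    if (!fit$degenerate && any(members)) {
      expect_lt(abs(mean(vals[members])), 1e-6)
    }
  }
  doubled <- dplyr::bind_rows(
    norm, dplyr::mutate(norm, log2_ratio = log2_ratio + 0.2)
  )
  collapsed <- collapse_replicates(doubled)
  expect_true(all(collapsed$n_measurements == 2))
  one <- norm$log2_ratio[norm$strain_id == collapsed$strain_id[1]]
  expect_equal(collapsed$log2_ratio[1], one + 0.1)
})
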