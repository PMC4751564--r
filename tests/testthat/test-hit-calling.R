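test_that("replicate concordance handles exact and shifted replicates", {
  r1 <- ratio_tbl(c(a = 0.1, b = 1.4, c = -0.5, d = 2.2))
  expect_equal(replicate_concordance(r1, r1)$pearson_r, 1.0)
  expect_equal(replicate_concordance(r1, r1)$mean_abs_diff, 0.0)
  r2 <- dplyr::mutate(r1, log2_ratio = log2_ratio + 0.29)
  stats <- replicate_concordance(r1, r2)
  expect_equal(stats$mean_abs_diff, 0.29)
  expect_equal(stats$pearson_r, 1.0)
  expect_equal(stats$n_pairs, 4)
  expect_error(replicate_concordance(r1[1:2, ], r1), "3 shared")
})

test_that("the null model rounds the error estimate to one decimal", {
  m <- fit_null_model(0.29)
  expect_equal(m$sd, 0.3)
  expect_equal(m$mean, 0)
  expect_equal(fit_null_model(0.26)$sd, 0.3)
  expect_equal(fit_null_model(0.55)$sd, 0.6)
  expect_error(fit_null_model(-1), "positive")
  stats <- replicate_concordance(
    ratio_tbl(c(a = 0, b = 1, c = 2)),
    ratio_tbl(c(a = 0.29, b = 1.29, c = 2.29))
  )
  mm <- fit_null_model(stats)
  expect_equal(mm$sd, 0.3)
  expect_equal(mm$source, "replicate_derived")
})

test_that("Z-scores and tail probabilities follow the Gaussian null", {
  m03 <- fit_null_model(0.3)
  expect_equal(round(z_score(1.0, m03), 1), 3.3)
  expect_equal(z_score(0, m03), 0)
  expect_equal(z_score(1.0, fit_null_model(0.5)), 2.0)
  # oracle: standard normal CDF
  expect_equal(tail_probability(1.0, m03), pnorm(-1 / 0.3), tolerance = 1e-12)
  expect_lt(tail_probability(1.0, m03), 0.001)
  expect_equal(tail_probability(0, m03), 0.5)
  expect_lt(tail_probability(1e6, m03), 1e-12)
})

test_that("primary calling uses a strict threshold", {
  ratios <- ratio_tbl(c(a = 0.2, b = 1.5, c = -0.4, d = 3.0))
  expect_setequal(call_primary_hits(ratios)$strain_id, c("b", "d"))
  expect_equal(nrow(call_primary_hits(ratio_tbl(c(x = 1.0)))), 0)
})

test_that("raising any threshold never enlarges the called set", {
  set.seed(61)
  ratios <- ratio_tbl(setNames(rnorm(500, 0.3, 0.8),
                               sprintf("s%03d", 1:500)))
  prev <- call_primary_hits(ratios, 0)$strain_id
  for (thr in c(0.5, 1.0, 1.3, 2.0)) {
    cur <- call_primary_hits(ratios, thr)$strain_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("rescreen selection takes >1.3 strains plus center-peak controls", {
  expect_equal(
    select_for_rescreen(ratio_tbl(c(a = 1.2, b = 1.4)), n_controls = 0)$
      selected$strain_id,
    "b"
  )
  empty <- select_for_rescreen(ratio_tbl(setNames(rep(0.5, 80),
                                                  sprintf("s%d", 1:80))),
                               n_controls = 8)
  expect_equal(nrow(empty$selected), 0)
  sel <- select_for_rescreen(
    ratio_tbl(setNames(c(rep(0.1, 80), 1.5, 2.0), sprintf("s%d", 1:82))),
    n_controls = 8
  )
  expect_setequal(sel$selected$strain_id, c("s81", "s82"))
  expect_equal(length(sel$controls), 8)
  expect_true(all(table(sel$layout$plate[
    sel$layout$role == "control_center_peak"]) >= 1))
})

test_that("confirmation requires the rescreen to clear its threshold", {
  primary <- ratio_tbl(c(a = 2.0, b = 1.6))
  calls <- confirm_hits(primary, ratio_tbl(c(a = 0.5, b = 1.4)))
  expect_false(calls$confirmed[calls$strain_id == "a"])
  expect_true(calls$confirmed[calls$strain_id == "b"])
  expect_equal(calls$final_class[calls$strain_id == "a"], "not_hit")
  expect_error(confirm_hits(primary, ratio_tbl(c(zz = 1.5))), "absent")
})

test_that("false-positive rate in null-only screens matches the analytic tail", {
  n_screens <- 200
  n_per <- 96
  called <- 0L
  total <- 0L
  for (i in seq_len(n_screens)) {
    cfg <- screen_config(n_strains = n_per, hit_fraction = 0, seed = 3000 + i)
    scr <- simulate_screen(cfg, conditions = "KCl")
    norm <- collapse_replicates(normalize_screen(filter_wells(scr$wells)$wells))
    called <- called + sum(norm$log2_ratio > 1.0)
    total <- total + nrow(norm)
  }
  combined_sd <- sqrt(0.26^2 + 0.20^2)  # technical + biological null spread
  p_expected <- pnorm(1.0, 0, combined_sd, lower.tail = FALSE)
  tol <- 3 * sqrt(total * p_expected * (1 - p_expected))
  expect_lt(abs(called - total * p_expected), tol)
})

test_that("strong true effects are called and null strains almost never are", {
  called_strong <- 0L; n_strong <- 0L
  called_null <- 0L; n_null <- 0L
  for (seed in 1:5) {
    cfg <- screen_config(n_strains = 960, seed = seed)
    scr <- simulate_screen(cfg, conditions = "KCl")
    norm <- collapse_replicates(normalize_screen(filter_wells(scr$wells)$wells))
    hits <- call_primary_hits(dplyr::select(norm, strain_id, log2_ratio))
    truth <- scr$truth[scr$truth$strain_id %in% norm$strain_id, ]
    strong <- truth$strain_id[truth$effect_kcl >= 1.5]
    nulls <- truth$strain_id[!truth$is_hit]
    called_strong <- called_strong + sum(strong %in% hits$strain_id)
    n_strong <- n_strong + length(strong)
    called_null <- called_null + sum(nulls %in% hits$strain_id)
    n_null <- n_null + length(nulls)
  }
  expect_gte(called_strong / n_strong, 0.90)
  expect_lte(called_null / n_null, 0.01)
})

test_that("the two-stage design reduces false positives at equal threshold", {
  primary_fp <- 0L
  confirmed_fp <- 0L
  for (seed in 1:10) {
    cfg <- screen_config(n_strains = 960, hit_fraction = 0, seed = 400 + seed)
    truth <- simulate_truth(cfg)
    wells <- simulate_wells(truth, cfg, condition = "KCl")
    ratios <- collapse_replicates(normalize_screen(filter_wells(wells)$wells)) |>
      dplyr::select(strain_id, log2_ratio)
    primary <- call_primary_hits(ratios, 1.0)
    primary_fp <- primary_fp + nrow(primary)
    if (nrow(primary) == 0) next
    sel <- select_for_rescreen(ratios, 1.0, n_controls = 48)
    rw <- simulate_rearray(truth, cfg, sel$selected$strain_id, sel$controls,
                           condition = "KCl", seed = 900 + seed)
    rr <- normalize_screen(filter_wells(rw)$wells, method = "controls") |>
      dplyr::filter(role == "library") |>
      collapse_replicates() |>
      dplyr::select(strain_id, log2_ratio)
    calls <- confirm_hits(ratios, rr, 1.0)
    confirmed_fp <- confirmed_fp + sum(calls$confirmed)
  }
  expect_gt(primary_fp, 0)
  expect_lt(confirmed_fp, primary_fp)
})
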