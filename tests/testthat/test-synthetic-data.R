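test_that("the generator is byte-identical under a fixed seed", {
  cfg <- screen_config(n_strains = 192, seed = 42)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_screen(screen_config(n_strains = 192, seed = 43))
  expect_false(identical(s1$wells, s3$wells))
})

test_that("config validation rejects impossible parameters", {
  expect_error(screen_config(hit_fraction = 1.2), "proportion")
  expect_error(screen_config(dropout_rate = -0.1), "proportion")
  expect_error(screen_config(null_bio_sd = -1), "non-negative")
  expect_error(screen_config(hit_effect_range = c(4, 1)), "lower")
})

test_that("null-only screens reproduce the closed-form composite noise SD", {
  # with biology and plate offsets off, the only spread left is the
  # two-channel technical noise, whose F-J composite SD is well_noise_sd
  cfg <- screen_config(
    n_strains = 4709, hit_fraction = 0, null_bio_sd = 0,
    plate_offset_range = c(0, 0), dropout_rate = 0, seed = 11
  )
  scr <- simulate_screen(cfg, conditions = "KCl")
  norm <- normalize_screen(filter_wells(scr$wells)$wells)
  composite_sd <- cfg$well_noise_sd
  expect_lt(abs(sd(norm$log2_ratio) - composite_sd), 0.02)
  expect_lt(abs(mean(norm$log2_ratio)), 0.02)
})

test_that("a forced effect propagates exactly through noise-free plates", {
  cfg <- noise_free_config(n_strains = 96, seed = 3)
  truth <- simulate_truth(cfg)
  truth$effect_kcl[5] <- 3.0
  truth$is_hit[5] <- TRUE
  truth$true_kcl_level[5] <- 3.0
  wells <- simulate_wells(truth, cfg, condition = "KCl")
  norm <- normalize_screen(wells)  # nonzero plate offsets are still present
  expect_equal(norm$log2_ratio[norm$strain_id == truth$strain_id[5]], 3.0,
               tolerance = 1e-9)
  expect_equal(max(abs(norm$log2_ratio[norm$strain_id != truth$strain_id[5]])),
               0, tolerance = 1e-9)
})

test_that("dropout wells appear at the configured rate", {
  cfg <- screen_config(n_strains = 4709, seed = 5)
  scr <- simulate_screen(cfg, conditions = "KCl")
  flt <- filter_wells(scr$wells)
  n <- flt$report$n_input
  frac <- 1 - flt$report$n_retained / n
  tol <- 3 * sqrt(cfg$dropout_rate * (1 - cfg$dropout_rate) / n)
  expect_lt(abs(frac - cfg$dropout_rate), tol)
})

test_that("truth invariants hold: effects imply hits, labels imply hits", {
  truth <- simulate_truth(screen_config(n_strains = 2000, seed = 8))
  expect_true(all(truth$is_hit[truth$effect_kcl > 0]))
  expect_true(all(truth$is_hit[truth$is_downstream_torc1]))
  expect_true(all(truth$is_hit[truth$is_constitutive]))
  expect_equal(mean(truth$is_hit), 0.10, tolerance = 0.01)
})

test_that("two replicate runs of one truth match the replicate calibration", {
  cfg <- screen_config(n_strains = 560, seed = 21)
  truth <- simulate_truth(cfg)
  norm_run <- function(seed) {
    w <- simulate_wells(truth, cfg, condition = "KCl",
                        plate_prefix = paste0("R", seed), seed = seed)
    collapse_replicates(normalize_screen(filter_wells(w)$wells)) |>
      dplyr::select(strain_id, log2_ratio)
  }
  stats <- replicate_concordance(norm_run(101), norm_run(202))
  expect_lt(abs(stats$pearson_r - 0.90), 0.05)
  expect_lt(abs(stats$mean_abs_diff - 0.29), 0.03)
})

test_that("graph generator produces forced and saturated graphs exactly", {
  genes3 <- c("a", "b", "c")
  cfg <- graph_config(n_genes = 3, background_edges = 0,
                      planted_set_size = 3, planted_extra_edges = 3, seed = 1)
  g <- simulate_graph(cfg, planted_genes = genes3, genes = genes3)
  expect_equal(nrow(g$edges), 3)
  expect_setequal(paste(g$edges$gene_a, g$edges$gene_b),
                  c("a b", "a c", "b c"))

  cfg5 <- graph_config(n_genes = 5, background_edges = 10,
                       planted_set_size = 0, planted_extra_edges = 0, seed = 2)
  g5 <- simulate_graph(cfg5)
  expect_equal(nrow(g5$edges), 10)  # complete graph on 5 nodes
  expect_equal(anyDuplicated(paste(g5$edges$gene_a, g5$edges$gene_b)), 0L)
  expect_true(all(g5$edges$gene_a != g5$edges$gene_b))

  expect_error(graph_config(n_genes = 4, background_edges = 7), "exceeds")
})

test_that("planted-set induced edges match background expectation plus extras", {
  cfg <- graph_config(n_genes = 1000, background_edges = 5000,
                      planted_set_size = 100, planted_extra_edges = 300,
                      seed = 9)
  planted <- sprintf("gene%05d", sample.int(1000, 100))
  g <- simulate_graph(cfg, planted_genes = planted)
  expected_bg <- 5000 * 100 * 99 / (1000 * 999)
  observed <- count_induced_edges(g$edges, planted)
  p <- 100 * 99 / (1000 * 999)
  tol <- 3 * sqrt(5000 * p * (1 - p))
  expect_lt(abs(observed - (expected_bg + 300)), tol)
})
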