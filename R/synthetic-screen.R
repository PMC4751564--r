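#' Configuration for the synthetic screen generator
#'
#' Parameters controlling the simulated genome-wide duplex qPCR screen. The
#' defaults reproduce the statistical structure of the yeast knock-out
#' collection screen the pipeline was designed for: ~4700 deletion strains on
#' 96-well plates, a two-population strain mixture (null strains vs strains
#' with a repression defect), per-plate qPCR run offsets of 0.3--0.6 cycles, a
#' composite technical noise of 0.26 log2 units per measurement, ~4% well
#' dropout, and a 2.3 log2-unit reporter de-repression under mock (unstressed)
#' conditions.
#'
#' @param n_strains Number of library strains (default 4709).
#' @param n_per_plate Wells per plate (default 96; 8 x 12 grid).
#' @param hit_fraction Fraction of strains carrying a true repression defect.
#' @param hit_effect_range Range (log2 units) from which true defect effects
#'   are drawn uniformly.
#' @param null_bio_sd SD (log2) of strain-intrinsic biological deviation,
#'   shared between technical replicates of the same strain.
#' @param well_noise_sd Composite technical SD (log2) of one normalized
#'   measurement; each Ct channel receives independent noise with SD
#'   `well_noise_sd / sqrt(2)` so the reporter-minus-housekeeping difference
#'   has SD `well_noise_sd`.
#' @param plate_offset_range Magnitude range (cycles) of per-plate offsets; a
#'   random sign is drawn per plate. Applied once to both channels (cancels in
#'   the ratio) and once more to the reporter channel alone (the run-to-run
#'   variation the plate normalization must remove).
#' @param dropout_rate Fraction of wells that fail amplification; such wells
#'   report a late Ct (> 28 cycles) on one or both channels.
#' @param mock_shift Log2 units by which the reporter exceeds its stressed
#'   level in unstressed (mock) cultures.
#' @param downstream_fraction Fraction of hit strains whose defect persists
#'   under rapamycin (genes downstream of TORC1).
#' @param constitutive_fraction Fraction of hit strains with constitutively
#'   elevated reporter expression (high in mock as well).
#' @param ct_baseline Housekeeping-channel Ct at nominal expression (cycles).
#' @param seed Integer seed; the same seed reproduces identical output.
#'
#' @return An object of class `screen_config` (a named list).
#' @export
#' @examples
#' cfg <- screen_config(n_strains = 96, seed = 1)
#' scr <- simulate_screen(cfg, conditions = "KCl")
#' head(scr$wells)
screen_config <- function(n_strains = 4709,
                          n_per_plate = 96,
                          hit_fraction = 0.10,
                          hit_effect_range = c(1.0, 4.5),
                          null_bio_sd = 0.20,
                          well_noise_sd = 0.26,
                          plate_offset_range = c(0.3, 0.6),
                          dropout_rate = 0.04,
                          mock_shift = 2.3,
                          downstream_fraction = 53 / 332,
                          constitutive_fraction = 5 / 332,
                          ct_baseline = 22,
                          seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_per_plate = as.integer(n_per_plate),
    hit_fraction = hit_fraction,
    hit_effect_range = as.numeric(hit_effect_range),
    null_bio_sd = null_bio_sd,
    well_noise_sd = well_noise_sd,
    plate_offset_range = as.numeric(plate_offset_range),
    dropout_rate = dropout_rate,
    mock_shift = mock_shift,
    downstream_fraction = downstream_fraction,
    constitutive_fraction = constitutive_fraction,
    ct_baseline = ct_baseline,
    seed = as.integer(seed)
  )
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  props <- c("hit_fraction", "dropout_rate", "downstream_fraction",
             "constitutive_fraction")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single proportion in [0, 1].", p))
    }
  }
  for (p in c("null_bio_sd", "well_noise_sd")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0) {
      abort(sprintf("`%s` must be a non-negative SD.", p))
    }
  }
  for (p in c("hit_effect_range", "plate_offset_range")) {
    v <- cfg[[p]]
    if (length(v) != 2 || any(is.na(v)) || v[1] > v[2]) {
      abort(sprintf("`%s` must be a length-2 range with lower <= upper.", p))
    }
  }
  if (cfg$n_strains < 1) abort("`n_strains` must be at least 1.")
  if (cfg$n_per_plate < 8 || cfg$n_per_plate > 96) {
    abort("`n_per_plate` must be between 8 and 96.")
  }
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  %d strains on %d-well plates; hit fraction %.3f\n",
              x$n_strains, x$n_per_plate, x$hit_fraction))
  cat(sprintf("  noise: technical %.2f, biological %.2f log2 units; dropout %.1f%%\n",
              x$well_noise_sd, x$null_bio_sd, 100 * x$dropout_rate))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate the ground-truth strain table
#'
#' Draws, for every strain, its hit status, true repression-defect effect in
#' KCl stress, downstream-of-TORC1 and constitutive flags, and its true
#' reporter levels (log2, relative to the stressed null baseline) under KCl,
#' mock and rapamycin. Strain-intrinsic biological deviation (SD
#' `null_bio_sd`) is drawn once per strain per condition and is part of the
#' truth, so technical replicates share it.
#'
#' Truth model: null strains repress the reporter fully in KCl and rapamycin
#' (level 0) and sit at `mock_shift` in mock. Hit strains fail to repress in
#' KCl (level = `effect_kcl`, drawn uniformly from `hit_effect_range`).
#' Downstream-of-TORC1 hits keep their defect under rapamycin; other hits
#' repress normally there. Constitutive hits are elevated in every condition:
#' their mock level is `mock_shift + effect_kcl` and they behave like
#' downstream hits under rapamycin.
#'
#' @param config A [screen_config()].
#' @return A tibble with one row per strain: `strain_id`, `is_hit`,
#'   `effect_kcl`, `is_downstream_torc1`, `is_constitutive`,
#'   `true_kcl_level`, `true_mock_level`, `true_rap_level`.
#' @export
simulate_truth <- function(config) {
  validate_screen_config(config)
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_strains
    strain_id <- sprintf("strain%05d", seq_len(n))
    n_hits <- round(config$hit_fraction * n)
    is_hit <- rep(FALSE, n)
    if (n_hits > 0) is_hit[sample.int(n, n_hits)] <- TRUE

    effect_kcl <- numeric(n)
    effect_kcl[is_hit] <- runif(n_hits, config$hit_effect_range[1],
                                config$hit_effect_range[2])

    is_downstream <- rep(FALSE, n)
    is_constitutive <- rep(FALSE, n)
    if (n_hits > 0) {
      hit_idx <- which(is_hit)
      n_down <- round(config$downstream_fraction * n_hits)
      n_con <- round(config$constitutive_fraction * n_hits)
      if (n_down > 0) is_downstream[sample(hit_idx, n_down)] <- TRUE
      if (n_con > 0) is_constitutive[sample(hit_idx, n_con)] <- TRUE
    }

    dev <- matrix(rnorm(3 * n, 0, config$null_bio_sd), ncol = 3)
    true_kcl <- effect_kcl + dev[, 1]
    true_mock <- config$mock_shift +
      ifelse(is_constitutive, effect_kcl, 0) + dev[, 2]
    true_rap <- ifelse(is_downstream | is_constitutive, effect_kcl, 0) + dev[, 3]

    tibble::tibble(
      strain_id = strain_id,
      is_hit = is_hit,
      effect_kcl = effect_kcl,
      is_downstream_torc1 = is_downstream,
      is_constitutive = is_constitutive,
      true_kcl_level = true_kcl,
      true_mock_level = true_mock,
      true_rap_level = true_rap
    )
  })
}

# True reporter level (log2, relative to stressed null baseline) per strain
# under one condition.
truth_levels <- function(truth, condition) {
  col <- switch(condition,
    KCl = "true_kcl_level",
    mock = "true_mock_level",
    rapamycin = "true_rap_level",
    abort(sprintf("Unknown condition '%s'.", condition))
  )
  setNames(truth[[col]], truth$strain_id)
}

# Core well generator: given a layout (plate_id, well, strain_id, role) and a
# strain -> true log2 level map, produce Ct values under the duplex qPCR
# error model. Ct decreases one cycle per doubling of transcript.
generate_wells <- function(layout, levels, config, condition, seed) {
  with_seed(seed, {
    plates <- unique(layout$plate_id)
    n_plates <- length(plates)
    # shared plate offset (both channels) and reporter-only run offset
    off_mag <- runif(n_plates, config$plate_offset_range[1],
                     config$plate_offset_range[2])
    off_sgn <- sample(c(-1, 1), n_plates, replace = TRUE)
    run_mag <- runif(n_plates, config$plate_offset_range[1],
                     config$plate_offset_range[2])
    run_sgn <- sample(c(-1, 1), n_plates, replace = TRUE)
    shared_off <- setNames(off_mag * off_sgn, plates)
    run_off <- setNames(run_mag * run_sgn, plates)

    n <- nrow(layout)
    chan_sd <- config$well_noise_sd / sqrt(2)
    lev <- unname(levels[layout$strain_id])
    if (anyNA(lev)) abort("Layout contains strains absent from the truth table.")
    ct_joe <- config$ct_baseline + shared_off[layout$plate_id] +
      rnorm(n, 0, chan_sd)
    ct_fam <- config$ct_baseline - lev + shared_off[layout$plate_id] +
      run_off[layout$plate_id] + rnorm(n, 0, chan_sd)

    # dropout wells amplify late (> 28 cycles) on one or both channels
    drop <- runif(n) < config$dropout_rate
    if (any(drop)) {
      which_chan <- sample(c("fam", "joe", "both"), sum(drop), replace = TRUE)
      late <- function(k) runif(k, 28.5, 36)
      idx <- which(drop)
      fam_late <- idx[which_chan %in% c("fam", "both")]
      joe_late <- idx[which_chan %in% c("joe", "both")]
      ct_fam[fam_late] <- late(length(fam_late))
      ct_joe[joe_late] <- late(length(joe_late))
    }

    tibble::tibble(
      plate_id = layout$plate_id,
      well = layout$well,
      strain_id = layout$strain_id,
      condition = condition,
      role = layout$role,
      ct_fam = unname(ct_fam),
      ct_joe = unname(ct_joe)
    )
  })
}

# Sequential library layout: strains fill 96-well plates in row-major order;
# the last plate may be partial.
library_layout <- function(strain_ids, n_per_plate, plate_prefix) {
  n <- length(strain_ids)
  plate_no <- (seq_len(n) - 1L) %/% n_per_plate + 1L
  pos <- (seq_len(n) - 1L) %% n_per_plate + 1L
  tibble::tibble(
    plate_id = sprintf("%s_P%02d", plate_prefix, plate_no),
    well = plate_wells(n_per_plate)[pos],
    strain_id = strain_ids,
    role = "library"
  )
}

#' Simulate wells for a set of strains under one condition
#'
#' Lays the given strains out on sequential 96-well plates and generates raw
#' duplex qPCR Ct values under the generator's error model: both channels
#' share a per-plate offset (which cancels in the reporter/housekeeping
#' ratio), the reporter channel receives an additional per-plate run offset of
#' magnitude `plate_offset_range` (which does not cancel and must be removed
#' by plate normalization), each channel receives independent Gaussian noise,
#' and a `dropout_rate` fraction of wells amplify late (Ct > 28).
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config The [screen_config()] used to build `truth`.
#' @param condition One of `"KCl"`, `"mock"`, `"rapamycin"`.
#' @param strains Strain ids to array (default: all strains in `truth`).
#' @param plate_prefix Prefix for plate barcodes (default the condition name);
#'   use distinct prefixes for replicate runs so (plate, well) stays unique.
#' @param seed Seed for this run's noise (default derived from the config
#'   seed and condition).
#' @return A tibble of wells: `plate_id`, `well`, `strain_id`, `condition`,
#'   `role`, `ct_fam` (reporter), `ct_joe` (housekeeping).
#' @export
simulate_wells <- function(truth, config, condition = "KCl",
                           strains = truth$strain_id,
                           plate_prefix = condition,
                           seed = NULL) {
  condition <- match.arg(condition, .conditions)
  seed <- seed %||% child_seed(config$seed, match(condition, .conditions) + 10L)
  layout <- library_layout(strains, config$n_per_plate, plate_prefix)
  generate_wells(layout, truth_levels(truth, condition), config, condition, seed)
}

#' Simulate a complete synthetic screen
#'
#' Generates the ground-truth strain table and raw well measurements for one
#' or more conditions. Identical `config` (including seed) reproduces
#' identical output.
#'
#' @param config A [screen_config()].
#' @param conditions Conditions to simulate (default all three).
#' @return A list of class `ribi_screen` with elements `wells` (one tibble,
#'   all conditions), `truth`, and `config`.
#' @export
simulate_screen <- function(config = screen_config(),
                            conditions = c("KCl", "mock", "rapamycin")) {
  conditions <- match.arg(conditions, .conditions, several.ok = TRUE)
  truth <- simulate_truth(config)
  wells <- purrr::map(conditions, function(cond) {
    simulate_wells(truth, config, condition = cond)
  })
  structure(
    list(wells = dplyr::bind_rows(wells), truth = truth, config = config),
    class = "ribi_screen"
  )
}

#' @export
print.ribi_screen <- function(x, ...) {
  cat("<ribi_screen>\n")
  cat(sprintf("  %d wells, %d strains, conditions: %s\n",
              nrow(x$wells), nrow(x$truth),
              paste(unique(x$wells$condition), collapse = ", ")))
  cat(sprintf("  true hits: %d (%.1f%%)\n", sum(x$truth$is_hit),
              100 * mean(x$truth$is_hit)))
  invisible(x)
}

#' Simulate a re-arrayed plate set with center-peak control wells
#'
#' Re-arrays selected strains together with center-peak control strains
#' (strains whose primary-screen value sat at the mode of the distribution,
#' log2 ~ 0) onto fresh plates, distributing the controls evenly so every
#' plate carries controls, and generates Ct values under `condition`. Used
#' for the confirmation rescreen and the mock/rapamycin subscreens, which are
#' hit-enriched and therefore normalized against the controls rather than by
#' the plate mixture.
#'
#' @inheritParams simulate_wells
#' @param test_strains Strain ids selected for re-array.
#' @param control_strains Strain ids used as center-peak controls.
#' @return A tibble of wells; control wells carry role
#'   `"control_center_peak"`, test wells `"library"`.
#' @export
simulate_rearray <- function(truth, config, test_strains, control_strains,
                             condition = "KCl",
                             plate_prefix = paste0(condition, "_rearray"),
                             seed = NULL) {
  condition <- match.arg(condition, .conditions)
  if (length(intersect(test_strains, control_strains)) > 0) {
    abort("`test_strains` and `control_strains` must be disjoint.")
  }
  seed <- seed %||% child_seed(config$seed, match(condition, .conditions) + 20L)
  n_total <- length(test_strains) + length(control_strains)
  n_plates <- ceiling(n_total / config$n_per_plate)
  # controls spread round-robin across plates, tests fill the remainder
  ctrl_plate <- rep(seq_len(n_plates), length.out = length(control_strains))
  # per plate: controls first, then test strains fill the free wells
  per_plate_ctrl <- split(control_strains, ctrl_plate)
  capacity <- rep(config$n_per_plate, n_plates)
  layout <- vector("list", n_plates)
  remaining <- test_strains
  for (p in seq_len(n_plates)) {
    ctrls <- per_plate_ctrl[[as.character(p)]] %||% character(0)
    n_free <- capacity[p] - length(ctrls)
    take <- head(remaining, n_free)
    remaining <- tail(remaining, max(0, length(remaining) - n_free))
    ids <- c(ctrls, take)
    layout[[p]] <- tibble::tibble(
      plate_id = sprintf("%s_P%02d", plate_prefix, p),
      well = plate_wells(config$n_per_plate)[seq_along(ids)],
      strain_id = ids,
      role = c(rep("control_center_peak", length(ctrls)),
               rep("library", length(take)))
    )
  }
  layout <- dplyr::bind_rows(layout)
  generate_wells(layout, truth_levels(truth, condition), config, condition, seed)
}
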