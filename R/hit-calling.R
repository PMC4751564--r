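#' Replicate concordance statistics
#'
#' Pearson correlation and mean absolute difference between two replicate
#' runs of the same strains, computed over strains present in both. The SD
#' of the differences is reported alongside, since "average difference" can
#' be read either way; the mean absolute difference is the primary statistic.
#'
#' @param rep1,rep2 Tibbles with columns `strain_id`, `log2_ratio` (one row
#'   per strain), or named numeric vectors.
#' @return An object of class `replicate_stats`: `pearson_r`,
#'   `mean_abs_diff`, `sd_diff`, `n_pairs`.
#' @export
#' @examples
#' r1 <- tibble::tibble(strain_id = c("a", "b", "c"), log2_ratio = c(0, 1, 2))
#' r2 <- dplyr::mutate(r1, log2_ratio = log2_ratio + 0.29)
#' replicate_concordance(r1, r2)
replicate_concordance <- function(rep1, rep2) {
  v1 <- if (is.data.frame(rep1)) as_ratio_vector(rep1) else rep1
  v2 <- if (is.data.frame(rep2)) as_ratio_vector(rep2) else rep2
  shared <- intersect(names(v1), names(v2))
  if (length(shared) < 3) {
    abort("At least 3 shared strains are required for concordance statistics.")
  }
  d <- v1[shared] - v2[shared]
  structure(
    list(
      pearson_r = cor(v1[shared], v2[shared]),
      mean_abs_diff = mean(abs(d)),
      sd_diff = sd(d),
      n_pairs = length(shared)
    ),
    class = "replicate_stats"
  )
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat("<replicate_stats>\n")
  cat(sprintf("  %d shared strains; Pearson r = %.3f; mean |diff| = %.3f (sd of diff %.3f)\n",
              x$n_pairs, x$pearson_r, x$mean_abs_diff, x$sd_diff))
  invisible(x)
}

#' @rdname replicate_concordance
#' @param x A `replicate_stats`.
#' @param ... Unused.
#' @export
tidy.replicate_stats <- function(x, ...) {
  tibble::tibble(
    pearson_r = x$pearson_r,
    mean_abs_diff = x$mean_abs_diff,
    sd_diff = x$sd_diff,
    n_pairs = x$n_pairs
  )
}

#' Replicate-derived Gaussian null model
#'
#' Models the normalized log2 ratio of strains without a real expression
#' defect as Normal with mean 0 and an SD taken from the replicate error
#' estimate, rounded to one decimal (0.29 becomes 0.3). The error estimate
#' may be a `replicate_stats` object (its mean absolute difference or SD of
#' differences, per `statistic`) or a bare numeric SD.
#'
#' @param estimate A `replicate_stats` or a positive number.
#' @param statistic Which replicate statistic estimates the error when
#'   `estimate` is a `replicate_stats` (default `mean_abs_diff`).
#' @return An object of class `null_model`: `mean` (0), `sd`, `source`.
#' @export
#' @examples
#' fit_null_model(0.29)  # N(0, 0.3)
fit_null_model <- function(estimate, statistic = c("mean_abs_diff", "sd_diff")) {
  statistic <- match.arg(statistic)
  if (inherits(estimate, "replicate_stats")) {
    value <- estimate[[statistic]]
    source <- "replicate_derived"
  } else {
    value <- as.numeric(estimate)
    source <- "fixed"
  }
  if (!is.finite(value) || value <= 0) {
    abort("The error estimate must be a positive number.")
  }
  sd <- round(value, 1)
  if (sd <= 0) sd <- 0.1  # one-decimal rounding floor
  structure(list(mean = 0, sd = sd, source = source), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> N(%.1f, %.1f) [%s]\n", x$mean, x$sd, x$source))
  invisible(x)
}

#' @rdname fit_null_model
#' @param x A `null_model`.
#' @param ... Unused.
#' @export
tidy.null_model <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, source = x$source)
}

#' Z-score of a calling threshold under the null model
#'
#' `(threshold - mean) / sd`; at the default threshold of 1.0 log2 units and
#' the replicate-derived null N(0, 0.3) this is 3.33 (displayed as 3.3).
#'
#' @param threshold Calling threshold (log2 units).
#' @param model A [fit_null_model()] object.
#' @return The Z-score (exact; round to one decimal for display).
#' @export
z_score <- function(threshold, model) {
  stopifnot(inherits(model, "null_model"), model$sd > 0)
  (threshold - model$mean) / model$sd
}

#' One-sided upper tail probability under the null model
#'
#' Probability that a strain without a defect exceeds `threshold` by chance;
#' at threshold 1.0 under N(0, 0.3) this is about 4.3e-4, i.e. below 0.1%.
#'
#' @inheritParams z_score
#' @return A probability.
#' @export
tail_probability <- function(threshold, model) {
  stopifnot(inherits(model, "null_model"), model$sd > 0)
  pnorm(threshold, model$mean, model$sd, lower.tail = FALSE)
}

#' Call primary-screen hits
#'
#' Strains whose normalized log2 ratio strictly exceeds `threshold`
#' (default 1.0, the Z = 3.3 cutoff of the null model). A value exactly at
#' the threshold is not called.
#'
#' @param ratios Tibble `strain_id`, `log2_ratio` (one row per strain).
#' @param threshold Calling threshold (log2 units).
#' @return A tibble of called strains (`strain_id`, `log2_ratio`), sorted by
#'   decreasing ratio.
#' @export
call_primary_hits <- function(ratios, threshold = 1.0) {
  assert_columns(ratios, c("strain_id", "log2_ratio"))
  ratios |>
    dplyr::filter(.data$log2_ratio > threshold) |>
    dplyr::arrange(dplyr::desc(.data$log2_ratio)) |>
    dplyr::select("strain_id", "log2_ratio")
}

#' Select strains for the confirmation rescreen
#'
#' Takes strains with log2 ratio strictly above `selection_threshold`
#' (default 1.3) and packages them, together with center-peak control
#' strains, into re-array plate layouts for the confirmation run against a
#' second housekeeping gene.
#'
#' @inheritParams call_primary_hits
#' @param selection_threshold Selection cutoff (log2 units, default 1.3).
#' @param n_controls Number of center-peak control wells to add (default 72).
#' @param n_per_plate Wells per re-array plate.
#' @return A list of class `rescreen_selection`: `selected` (tibble of
#'   selected strains), `controls` (center-peak strain ids), `layout`
#'   (tibble `plate`, `strain_id`, `role`).
#' @export
select_for_rescreen <- function(ratios, selection_threshold = 1.3,
                                n_controls = 72, n_per_plate = 96) {
  assert_columns(ratios, c("strain_id", "log2_ratio"))
  selected <- call_primary_hits(ratios, threshold = selection_threshold)
  controls <- select_center_controls(
    dplyr::filter(ratios, !.data$strain_id %in% selected$strain_id),
    n_controls
  )
  n_total <- nrow(selected) + length(controls)
  n_plates <- max(1L, ceiling(n_total / n_per_plate))
  ctrl_plate <- rep(seq_len(n_plates), length.out = length(controls))
  # controls round-robin first, then selected strains fill remaining slots
  per_plate_ctrl <- split(controls, ctrl_plate)
  rows <- list(); remaining <- selected$strain_id
  for (p in seq_len(n_plates)) {
    ctrls <- per_plate_ctrl[[as.character(p)]] %||% character(0)
    n_free <- n_per_plate - length(ctrls)
    take <- head(remaining, n_free)
    remaining <- tail(remaining, max(0, length(remaining) - length(take)))
    rows[[p]] <- tibble::tibble(
      plate = p,
      strain_id = c(ctrls, take),
      role = c(rep("control_center_peak", length(ctrls)),
               rep("library", length(take)))
    )
  }
  structure(
    list(selected = selected, controls = controls,
         layout = dplyr::bind_rows(rows)),
    class = "rescreen_selection"
  )
}

#' @export
print.rescreen_selection <- function(x, ...) {
  cat(sprintf("<rescreen_selection> %d strains + %d center-peak controls on %d plate(s)\n",
              nrow(x$selected), length(x$controls),
              length(unique(x$layout$plate))))
  invisible(x)
}

#' Pick center-peak control strains
#'
#' Strains whose normalized primary-screen value is closest to 0 (the mode
#' of the screen distribution), used to zero hit-enriched re-array plates.
#'
#' @inheritParams call_primary_hits
#' @param n Number of control strains.
#' @return Character vector of strain ids.
#' @export
select_center_controls <- function(ratios, n) {
  assert_columns(ratios, c("strain_id", "log2_ratio"))
  if (nrow(ratios) < n) {
    abort("Not enough strains to pick center-peak controls from.")
  }
  ratios$strain_id[order(abs(ratios$log2_ratio))][seq_len(n)]
}

#' Confirm hits from the rescreen
#'
#' A selected strain is confirmed when its control-normalized rescreen value
#' (against the second housekeeping gene) strictly exceeds
#' `confirmation_threshold`; unconfirmed strains are classed `not_hit`.
#'
#' @param primary Tibble `strain_id`, `log2_ratio` of primary-screen values
#'   (must cover every rescreened strain).
#' @param rescreen Tibble `strain_id`, `log2_ratio` of control-normalized
#'   rescreen values for the selected strains.
#' @param confirmation_threshold Confirmation cutoff (log2 units).
#' @return A tibble of hit calls: `strain_id`, `primary_log2`,
#'   `selected_for_rescreen`, `rescreen_log2`, `confirmed`, `mock_log2`,
#'   `rap_log2`, `final_class` (`"unclassified"` for confirmed strains until
#'   the epistasis subscreens assign one, `"not_hit"` otherwise).
#' @export
confirm_hits <- function(primary, rescreen, confirmation_threshold = 1.0) {
  p <- as_ratio_vector(primary)
  r <- as_ratio_vector(rescreen)
  missing <- setdiff(names(r), names(p))
  if (length(missing) > 0) {
    abort(sprintf(
      "Rescreened strain(s) absent from the primary screen: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    strain_id = names(r),
    primary_log2 = unname(p[names(r)]),
    selected_for_rescreen = TRUE,
    rescreen_log2 = unname(r),
    confirmed = unname(r) > confirmation_threshold,
    mock_log2 = NA_real_,
    rap_log2 = NA_real_,
    final_class = ifelse(unname(r) > confirmation_threshold,
                         "unclassified", "not_hit")
  )
}
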