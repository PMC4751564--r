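#' Compute F-J values (reporter minus housekeeping Ct)
#'
#' For every well, the reporter-channel Ct minus the housekeeping-channel Ct.
#' Because Ct falls by one cycle per doubling of transcript, F-J is (minus)
#' the log2 reporter/housekeeping expression ratio; the sign is flipped later
#' by normalization so that more reporter transcript means a larger ratio.
#'
#' @param wells A well tibble with both Ct channels present (filter with
#'   [filter_wells()] first; missing channels are an error here).
#' @return A tibble `strain_id`, `plate_id`, `condition`, `role`, `fj`.
#' @export
#' @examples
#' w <- tibble::tibble(plate_id = "P01", well = "A01", strain_id = "s1",
#'                     condition = "KCl", role = "library",
#'                     ct_fam = 25.4, ct_joe = 23.1)
#' compute_fj(w)$fj  # 2.3
compute_fj <- function(wells) {
  assert_columns(wells, c("strain_id", "plate_id", "condition", "ct_fam",
                          "ct_joe"))
  if (anyNA(wells$ct_fam) || anyNA(wells$ct_joe)) {
    abort("Missing Ct values; run filter_wells() before compute_fj().")
  }
  tibble::tibble(
    strain_id = wells$strain_id,
    plate_id = wells$plate_id,
    condition = wells$condition,
    role = if ("role" %in% names(wells)) wells$role else "library",
    fj = wells$ct_fam - wells$ct_joe
  )
}

#' Normalize one plate's F-J values via the two-population mixture
#'
#' Fits the two-component mixture to the plate's F-J values and subtracts
#' the mean F-J of the majority population (strains without an expression
#' defect, identified as the wells whose posterior responsibility for the
#' higher-weight component is at least 0.5), setting the plate mean minus the
#' outliers to 0. All values are then multiplied by -1 so that higher
#' reporter transcript gives a higher log2 ratio. When the mixture is
#' degenerate (no resolvable outlier population) the plate's 20%-trimmed mean
#' is subtracted instead.
#'
#' Because any constant added to one plate's reporter channel shifts every
#' F-J value equally, this centering removes the 0.3--0.6 cycle run-to-run
#' variation between plates.
#'
#' @param fj_values Tibble from [compute_fj()] holding one plate and one
#'   condition (at least 8 wells).
#' @param trim Trim fraction for the degenerate fallback (default 0.2).
#' @param ... Passed to [fit_mixture_em()].
#' @return A tibble `strain_id`, `plate_id`, `condition`, `role`,
#'   `log2_ratio`, with the plate's `mixture_fit` attached as attribute
#'   `"mixture_fit"`.
#' @export
normalize_plate <- function(fj_values, trim = 0.2, ...) {
  assert_columns(fj_values, c("strain_id", "plate_id", "condition", "fj"))
  if (length(unique(fj_values$plate_id)) != 1 ||
      length(unique(fj_values$condition)) != 1) {
    abort("`fj_values` must hold exactly one plate and one condition; use normalize_screen() for full datasets.")
  }
  if (nrow(fj_values) < 8) {
    abort("At least 8 wells are required to normalize a plate.")
  }
  fit <- fit_mixture_em(fj_values$fj, ...)
  if (fit$degenerate) {
    center <- mean(fj_values$fj, trim = trim)
  } else {
    members <- fit$responsibilities[, fit$majority_component] >= 0.5
    if (!any(members)) {
      center <- mean(fj_values$fj, trim = trim)
    } else {
      center <- mean(fj_values$fj[members])
    }
  }
  out <- tibble::tibble(
    strain_id = fj_values$strain_id,
    plate_id = fj_values$plate_id,
    condition = fj_values$condition,
    role = if ("role" %in% names(fj_values)) fj_values$role else "library",
    log2_ratio = -(fj_values$fj - center)
  )
  attr(out, "mixture_fit") <- fit
  out
}

#' Normalize F-J values against center-peak control wells
#'
#' For re-arrayed, hit-enriched plates the mixture's majority-population
#' assumption fails, so the mean F-J of designated control wells
#' (center-peak strains, whose expression sat at the distribution mode in the
#' primary screen) is subtracted instead, and all values multiplied by -1.
#' When several plates are present each plate is centered by its own control
#' wells, which also removes per-plate run offsets; every plate must carry at
#' least 4 control wells.
#'
#' @param fj_values Tibble from [compute_fj()].
#' @param control_strains Strain ids of the control wells; defaults to wells
#'   with role `"control_center_peak"`.
#' @return A tibble `strain_id`, `plate_id`, `condition`, `role`,
#'   `log2_ratio`.
#' @export
normalize_with_controls <- function(fj_values, control_strains = NULL) {
  assert_columns(fj_values, c("strain_id", "plate_id", "condition", "fj"))
  role <- if ("role" %in% names(fj_values)) fj_values$role else
    rep("library", nrow(fj_values))
  is_control <- if (is.null(control_strains)) {
    role == "control_center_peak"
  } else {
    fj_values$strain_id %in% control_strains
  }
  if (!any(is_control)) {
    abort("No control wells found for control-based normalization.")
  }
  per_plate <- tapply(is_control, fj_values$plate_id, sum)
  if (any(per_plate < 4)) {
    abort(sprintf(
      "Every plate needs at least 4 control wells; plate(s) %s have fewer.",
      paste(names(per_plate)[per_plate < 4], collapse = ", ")
    ))
  }
  centers <- tapply(fj_values$fj[is_control],
                    fj_values$plate_id[is_control], mean)
  tibble::tibble(
    strain_id = fj_values$strain_id,
    plate_id = fj_values$plate_id,
    condition = fj_values$condition,
    role = role,
    log2_ratio = as.vector(-(fj_values$fj - centers[fj_values$plate_id]))
  )
}

#' Normalize a whole screen plate by plate
#'
#' Computes F-J values and applies [normalize_plate()] (or
#' [normalize_with_controls()]) separately to every (plate, condition)
#' group, mirroring the per-plate normalization of the screen design.
#'
#' @param wells A filtered well tibble (both channels present).
#' @param method `"mixture"` for library plates, `"controls"` for re-arrayed
#'   hit-enriched plates carrying center-peak control wells.
#' @param ... Passed to [normalize_plate()] / [normalize_with_controls()].
#' @return A tibble of normalized ratios for all plates; for
#'   `method = "mixture"` the per-plate `mixture_fit`s are attached as
#'   attribute `"mixture_fits"` (named `plate/condition`).
#' @export
#' @examples
#' scr <- simulate_screen(screen_config(n_strains = 192, seed = 4), "KCl")
#' norm <- scr$wells |> filter_wells() |> _$wells |> normalize_screen()
#' head(norm)
normalize_screen <- function(wells, method = c("mixture", "controls"), ...) {
  method <- match.arg(method)
  fj <- compute_fj(wells)
  if (method == "controls") {
    return(normalize_with_controls(fj, ...))
  }
  groups <- split(fj, paste(fj$plate_id, fj$condition, sep = "/"))
  normalized <- purrr::map(groups, function(g) {
    if (nrow(g) < 8) {
      # trailing partial plate: too few wells for a mixture; center on the
      # trimmed mean as for degenerate plates
      out <- g
      out$log2_ratio <- -(g$fj - mean(g$fj, trim = 0.2))
      out$fj <- NULL
      return(out[, c("strain_id", "plate_id", "condition", "role",
                     "log2_ratio")])
    }
    normalize_plate(g, ...)
  })
  fits <- purrr::compact(purrr::map(normalized, attr, "mixture_fit"))
  out <- dplyr::bind_rows(normalized)
  attr(out, "mixture_fits") <- fits
  out
}

#' Diagnostics for per-plate mixture fits
#'
#' @param normalized Output of [normalize_screen()] (mixture method).
#' @return A tibble with one row per plate/condition:
#'   [glance()][generics::glance] of each `mixture_fit` plus its majority
#'   mean.
#' @export
mixture_diagnostics <- function(normalized) {
  fits <- attr(normalized, "mixture_fits")
  if (is.null(fits)) abort("No mixture fits attached; was `normalized` produced by normalize_screen()?")
  purrr::imap(fits, function(fit, key) {
    dplyr::mutate(glance(fit), plate = key,
                  majority_mean = fit$means[fit$majority_component],
                  .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Write normalized ratios as TSV
#'
#' @param normalized Tibble of normalized ratios.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(normalized, path) {
  readr::write_tsv(
    normalized[, c("strain_id", "plate_id", "condition", "log2_ratio")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Average replicate measurements per strain and condition
#'
#' Strains measured on several plates or runs (duplicate-run plates) are
#' combined by the arithmetic mean of their normalized values.
#'
#' @param normalized Tibble of normalized ratios.
#' @return A tibble `strain_id`, `condition`, `log2_ratio`, `n_measurements`.
#' @export
collapse_replicates <- function(normalized) {
  assert_columns(normalized, c("strain_id", "condition", "log2_ratio"))
  normalized |>
    dplyr::group_by(.data$strain_id, .data$condition) |>
    dplyr::summarise(
      n_measurements = dplyr::n(),
      log2_ratio = mean(.data$log2_ratio),
      .groups = "drop"
    ) |>
    dplyr::select("strain_id", "condition", "log2_ratio", "n_measurements")
}
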