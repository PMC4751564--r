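#' Flag constitutively de-repressed strains from the mock subscreen
#'
#' Strains whose control-normalized mock-stress (log-growth) value strictly
#' exceeds `threshold` express the reporter highly even without stress, so
#' their screen phenotype is condition-independent rather than a repression
#' defect.
#'
#' @param mock Tibble `strain_id`, `log2_ratio` of control-normalized mock
#'   subscreen values.
#' @param threshold Cutoff (log2 units, default 1.0; strict `>`).
#' @return Character vector of constitutive strain ids.
#' @export
flag_constitutive <- function(mock, threshold = 1.0) {
  v <- as_ratio_vector(mock)
  names(v)[v > threshold]
}

#' Classify assayed strains relative to TORC1 from the rapamycin subscreen
#'
#' Rapamycin inhibits TORC1 directly, bypassing everything upstream. A
#' strain that still fails to downregulate the reporter under rapamycin
#' (control-normalized value at or above `threshold`; `>=` by convention) is
#' missing a gene acting downstream of TORC1; assayed strains below the
#' cutoff act upstream of, or in parallel with, the TORC1 pathway.
#'
#' @param rap Tibble `strain_id`, `log2_ratio` of control-normalized
#'   rapamycin subscreen values.
#' @param threshold Cutoff (log2 units, default 1.0; `>=`).
#' @return A tibble `strain_id`, `torc1_class` with values
#'   `downstream_TORC1` / `upstream_or_parallel`.
#' @export
classify_torc1 <- function(rap, threshold = 1.0) {
  v <- as_ratio_vector(rap)
  tibble::tibble(
    strain_id = names(v),
    torc1_class = unname(ifelse(v >= threshold, "downstream_TORC1",
                                "upstream_or_parallel"))
  )
}

#' Assemble final hit classes
#'
#' Merges the mock and rapamycin subscreen calls into the hit-call table.
#' Precedence: `constitutive` over `downstream_TORC1` over
#' `upstream_or_parallel` (a strain already high in mock carries no
#' information about TORC1 epistasis). Confirmed hits never assayed in the
#' subscreens stay `unclassified`; unconfirmed strains stay `not_hit`.
#'
#' @param hit_calls Tibble from [confirm_hits()].
#' @param constitutive Character vector from [flag_constitutive()].
#' @param torc1 Tibble from [classify_torc1()].
#' @param mock,rap Optional subscreen value tibbles (`strain_id`,
#'   `log2_ratio`) used to fill the `mock_log2` / `rap_log2` columns.
#' @return The hit-call tibble with `final_class` (and subscreen values)
#'   filled in; every confirmed hit receives exactly one class.
#' @export
assemble_final_classes <- function(hit_calls, constitutive, torc1,
                                   mock = NULL, rap = NULL) {
  assert_columns(hit_calls, c("strain_id", "confirmed", "final_class"))
  assert_columns(torc1, c("strain_id", "torc1_class"))
  assayed <- union(torc1$strain_id,
                   c(if (!is.null(mock)) mock$strain_id else character(0)))
  known <- union(hit_calls$strain_id, assayed)
  stray <- setdiff(constitutive, known)
  if (length(stray) > 0) {
    abort(sprintf(
      "Constitutive strain(s) not among confirmed hits or assayed strains: %s",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  stray <- setdiff(torc1$strain_id, union(hit_calls$strain_id, assayed))
  if (length(stray) > 0) {
    abort(sprintf(
      "TORC1-classified strain(s) unknown to the hit table: %s",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  tmap <- setNames(torc1$torc1_class, torc1$strain_id)
  out <- hit_calls
  if (!is.null(mock)) {
    mv <- as_ratio_vector(mock)
    out$mock_log2 <- unname(mv[out$strain_id])
  }
  if (!is.null(rap)) {
    rv <- as_ratio_vector(rap)
    out$rap_log2 <- unname(rv[out$strain_id])
  }
  cls <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- out$strain_id[i]
    if (!out$confirmed[i]) {
      cls[i] <- "not_hit"
    } else if (s %in% constitutive) {
      cls[i] <- "constitutive"
    } else if (!is.na(tmap[s])) {
      cls[i] <- unname(tmap[s])
    } else {
      cls[i] <- "unclassified"
    }
  }
  out$final_class <- cls
  out
}

#' Write the final classification table as TSV
#'
#' @param hit_calls Classified hit-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_calls <- function(hit_calls, path) {
  readr::write_tsv(
    hit_calls[, c("strain_id", "primary_log2", "rescreen_log2",
                  "mock_log2", "rap_log2", "final_class")],
    path, progress = FALSE
  )
  invisible(path)
}
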