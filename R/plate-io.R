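#' Read plate-structured duplex qPCR wells from CSV
#'
#' Reads a well table with columns `plate_id, well, strain_id, condition,
#' role, ct_fam, ct_joe` and validates it: well coordinates must fall in the
#' 8 x 12 grid, `(plate_id, well)` must be unique, conditions must be one of
#' `KCl`, `mock`, `rapamycin`, and Ct values, when present, must be positive
#' and finite. Empty Ct cells are read as `NA` (failed amplification) and are
#' handled by [filter_wells()], not here.
#'
#' @param path Path to a CSV file.
#' @return A tibble of well records.
#' @export
read_wells <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  wells <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      strain_id = readr::col_character(),
      condition = readr::col_character(),
      role = readr::col_character(),
      ct_fam = readr::col_double(),
      ct_joe = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(wells)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed rows in %s (line %s): %s",
      path,
      paste(probs$row + 1L, collapse = ", "),  # +1 for header line
      paste(unique(probs$expected), collapse = "; ")
    ))
  }
  validate_wells(wells, where = path)
}

#' Validate a well table
#'
#' @param wells A data frame of well records.
#' @param where Label used in error messages.
#' @return The validated tibble (well coordinates zero-padded), invisibly
#'   usable in a pipe.
#' @export
validate_wells <- function(wells, where = "wells") {
  assert_columns(
    wells,
    c("plate_id", "well", "strain_id", "condition", "role", "ct_fam", "ct_joe"),
    where
  )
  wells <- tibble::as_tibble(wells)
  bad_well <- !well_is_valid(wells$well)
  if (any(bad_well)) {
    abort(sprintf(
      "%s: invalid well coordinate(s) outside the 8x12 grid: %s",
      where, paste(unique(wells$well[bad_well]), collapse = ", ")
    ))
  }
  wells$well <- well_canonical(wells$well)
  bad_cond <- !wells$condition %in% .conditions
  if (any(bad_cond)) {
    abort(sprintf(
      "%s: unknown condition label(s): %s",
      where, paste(unique(wells$condition[bad_cond]), collapse = ", ")
    ))
  }
  bad_role <- !wells$role %in% .roles
  if (any(bad_role)) {
    abort(sprintf(
      "%s: unknown role label(s): %s",
      where, paste(unique(wells$role[bad_role]), collapse = ", ")
    ))
  }
  key <- paste(wells$plate_id, wells$well, sep = "/")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf(
      "%s: duplicated (plate, well): %s",
      where, paste(unique(key[dup]), collapse = ", ")
    ))
  }
  for (ch in c("ct_fam", "ct_joe")) {
    v <- wells[[ch]]
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad)) {
      abort(sprintf("%s: non-positive or non-finite %s values.", where, ch))
    }
  }
  wells
}

#' Write wells to CSV
#'
#' @param wells A well tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  readr::write_csv(wells, path, progress = FALSE)
  invisible(path)
}

#' Filter wells on the late-amplification rule
#'
#' Removes wells in which either channel amplified after more than
#' `ct_cutoff` cycles (strict inequality: a Ct of exactly 28.0 is retained)
#' or in which either channel is missing entirely, and tallies what was
#' discarded. The operation is idempotent and never alters retained records.
#'
#' @param wells A well tibble (see [read_wells()]).
#' @param ct_cutoff Cycle cutoff (default 28).
#' @return A list of class `filtered_wells`: `wells` (retained tibble) and
#'   `report` (class `filter_report`: `n_input`, `n_retained`,
#'   `n_discarded_late_ct`, `n_discarded_missing`, `discarded_strains`,
#'   `discarded` tibble).
#' @export
#' @examples
#' scr <- simulate_screen(screen_config(n_strains = 96, seed = 1), "KCl")
#' flt <- filter_wells(scr$wells)
#' flt$report
filter_wells <- function(wells, ct_cutoff = 28) {
  assert_columns(wells, c("plate_id", "well", "strain_id", "ct_fam", "ct_joe"))
  missing <- is.na(wells$ct_fam) | is.na(wells$ct_joe)
  late <- !missing & (wells$ct_fam > ct_cutoff | wells$ct_joe > ct_cutoff)
  keep <- !missing & !late
  report <- structure(
    list(
      n_input = nrow(wells),
      n_retained = sum(keep),
      n_discarded_late_ct = sum(late),
      n_discarded_missing = sum(missing),
      discarded_strains = sort(unique(wells$strain_id[!keep])),
      ct_cutoff = ct_cutoff,
      discarded = wells[!keep, , drop = FALSE]
    ),
    class = "filter_report"
  )
  structure(
    list(wells = wells[keep, , drop = FALSE], report = report),
    class = "filtered_wells"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  %d wells in; %d retained; %d late-Ct (> %.1f cycles); %d missing\n",
              x$n_input, x$n_retained, x$n_discarded_late_ct,
              x$ct_cutoff, x$n_discarded_missing))
  cat(sprintf("  %d strain(s) affected\n", length(x$discarded_strains)))
  invisible(x)
}

#' @export
print.filtered_wells <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @rdname filter_wells
#' @param x A `filter_report`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_retained = x$n_retained,
    n_discarded_late_ct = x$n_discarded_late_ct,
    n_discarded_missing = x$n_discarded_missing,
    n_discarded_strains = length(x$discarded_strains)
  )
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` from [filter_wells()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    report[c("n_input", "n_retained", "n_discarded_late_ct",
             "n_discarded_missing", "ct_cutoff", "discarded_strains")],
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read / write gene-interaction edge lists
#'
#' Edge lists are 3-column TSV files (`gene_a`, `gene_b`, `evidence_class`).
#' Evidence labels are mapped onto the package's three classes with
#' [map_evidence_class()]; already-canonical labels pass through.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_a`, `gene_b`, `evidence_class`.
#' @export
read_interaction_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  edges <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_a = readr::col_character(),
      gene_b = readr::col_character(),
      evidence_class = readr::col_character()
    ),
    progress = FALSE
  )
  edges$evidence_class <- map_evidence_class(edges$evidence_class)
  edges
}

#' @rdname read_interaction_edges
#' @param edges An edge tibble.
#' @export
write_interaction_edges <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read a per-gene annotation table
#'
#' Two-column TSV (`gene`, `tag`); a gene may carry several tags on separate
#' rows (e.g. localization `nucleus` / `endomembrane_vacuole`, or special
#' tags such as `histone`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene`, `tag`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      tag = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Write / read the ground-truth strain table
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param path Output TSV path.
#' @return `path` (write) or the truth tibble (read).
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      strain_id = readr::col_character(),
      is_hit = readr::col_logical(),
      effect_kcl = readr::col_double(),
      is_downstream_torc1 = readr::col_logical(),
      is_constitutive = readr::col_logical(),
      true_kcl_level = readr::col_double(),
      true_mock_level = readr::col_double(),
      true_rap_level = readr::col_double()
    ),
    progress = FALSE
  )
}
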