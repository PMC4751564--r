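# Internal helpers shared across modules.

# Well coordinates of an 8 x 12 plate in row-major order: "A01" ... "H12".
plate_wells <- function(n_per_plate = 96L) {
  stopifnot(n_per_plate >= 1, n_per_plate <= 96)
  all <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  all[seq_len(n_per_plate)]
}

well_is_valid <- function(well) {
  grepl("^[A-H](0[1-9]|1[0-2]|[1-9])$", well)
}

# Canonical zero-padded form ("A1" -> "A01").
well_canonical <- function(well) {
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  sprintf("%s%02d", row, col)
}

# Run `code` under a local RNG stream so simulation functions are
# deterministic in `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stage offset, kept < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 977L + as.integer(offset)) %% 2147483587L
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Strain -> value lookup from a two-column tibble (strain_id, log2_ratio).
as_ratio_vector <- function(ratios, value_col = "log2_ratio") {
  assert_columns(ratios, c("strain_id", value_col), "ratios")
  setNames(ratios[[value_col]], ratios[["strain_id"]])
}
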