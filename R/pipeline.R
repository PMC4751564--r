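#' Study configuration
#'
#' Collects the thresholds and design constants of the full screen analysis:
#' primary calling at log2 > 1.0 (Z = 3.3 under the replicate-derived null),
#' rescreen selection at > 1.3 with 72 center-peak controls, confirmation at
#' > 1.0 against the second housekeeping gene, subscreen re-array of strains
#' > 1.4 onto at most four plates with 48 center-peak controls, constitutive
#' calling at mock > 1.0, downstream-of-TORC1 calling at rapamycin >= 1.0,
#' and a 10,000-draw connectivity permutation test.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param screen A [screen_config()]; by default built from `seed`.
#' @param primary_threshold,rescreen_threshold,confirmation_threshold
#'   Primary call, rescreen selection and confirmation cutoffs (log2).
#' @param subscreen_threshold Re-array cutoff for the mock/rapamycin
#'   subscreens (log2).
#' @param mock_threshold,rapamycin_threshold Subscreen classification
#'   cutoffs (log2).
#' @param n_rescreen_controls,n_subscreen_controls Center-peak control wells
#'   added to the rescreen / subscreen re-arrays.
#' @param max_subscreen_plates Plate budget of one subscreen run.
#' @param replicate_plates Number of library plates re-run to estimate the
#'   replicate error.
#' @param n_permutations Random gene sets for the connectivity test.
#' @param graph A [graph_config()] or `NULL` to derive one from the screen
#'   size at the default edge density.
#' @param out_dir Directory for stage artifacts (TSV/JSON/GraphML), or
#'   `NULL` to keep everything in memory.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         screen = NULL,
                         primary_threshold = 1.0,
                         rescreen_threshold = 1.3,
                         confirmation_threshold = 1.0,
                         subscreen_threshold = 1.4,
                         mock_threshold = 1.0,
                         rapamycin_threshold = 1.0,
                         n_rescreen_controls = 72,
                         n_subscreen_controls = 48,
                         max_subscreen_plates = 4,
                         replicate_plates = 6,
                         n_permutations = 10000,
                         graph = NULL,
                         out_dir = NULL) {
  thresholds <- c(primary = primary_threshold, rescreen = rescreen_threshold,
                  confirmation = confirmation_threshold,
                  subscreen = subscreen_threshold, mock = mock_threshold,
                  rapamycin = rapamycin_threshold)
  if (any(thresholds <= 0)) abort("All thresholds must be positive.")
  structure(
    list(
      seed = as.integer(seed),
      screen = screen %||% screen_config(seed = child_seed(seed, 101L)),
      primary_threshold = primary_threshold,
      rescreen_threshold = rescreen_threshold,
      confirmation_threshold = confirmation_threshold,
      subscreen_threshold = subscreen_threshold,
      mock_threshold = mock_threshold,
      rapamycin_threshold = rapamycin_threshold,
      n_rescreen_controls = as.integer(n_rescreen_controls),
      n_subscreen_controls = as.integer(n_subscreen_controls),
      max_subscreen_plates = as.integer(max_subscreen_plates),
      replicate_plates = as.integer(replicate_plates),
      n_permutations = as.integer(n_permutations),
      graph = graph,
      out_dir = out_dir
    ),
    class = "study_config"
  )
}

# Graph configuration matching the default edge density at an arbitrary
# screen size: background edges scale with the number of gene pairs,
# planted extra edges with the number of within-set pairs.
scaled_graph_config <- function(n_genes, planted_set_size, seed) {
  ref_pairs <- 4709 * 4708 / 2
  ref_set_pairs <- 440 * 439 / 2
  pairs <- n_genes * (n_genes - 1) / 2
  set_pairs <- planted_set_size * max(0, planted_set_size - 1) / 2
  graph_config(
    n_genes = n_genes,
    background_edges = max(0L, round(56500 * pairs / ref_pairs)),
    planted_set_size = planted_set_size,
    planted_extra_edges = min(round(584 * set_pairs / ref_set_pairs),
                              floor(set_pairs)),
    seed = seed
  )
}

#' Run the full synthetic study end to end
#'
#' Simulates the screen, filters late-amplifying wells, normalizes every
#' plate with the two-population mixture, estimates the replicate error on
#' re-run plates and fits the Gaussian null model, calls primary hits,
#' selects and confirms hits in the control-normalized rescreen, classifies
#' confirmed hits with the mock and rapamycin subscreens, and tests the
#' connectivity of the confirmed set against random gene sets of equal size.
#' Deterministic in `config$seed`. Stage progress is logged to standard
#' error; artifacts are written under `config$out_dir` when set.
#'
#' @param config A [study_config()].
#' @param quiet Suppress stage logging.
#' @return An object of class `study_report`; see [glance.study_report()].
#' @export
run_study <- function(config = study_config(), quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  scfg <- config$screen
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
  }

  # -- simulate ---------------------------------------------------------
  log_stage("simulate: %d strains (seed %d)", scfg$n_strains, scfg$seed)
  truth <- simulate_truth(scfg)
  wells <- simulate_wells(truth, scfg, condition = "KCl")

  # -- filter -----------------------------------------------------------
  flt <- filter_wells(wells)
  log_stage("filter: %d/%d wells retained (%d late, %d missing)",
            flt$report$n_retained, flt$report$n_input,
            flt$report$n_discarded_late_ct, flt$report$n_discarded_missing)

  # -- normalize --------------------------------------------------------
  normalized <- normalize_screen(flt$wells)
  ratios <- collapse_replicates(normalized) |>
    dplyr::filter(.data$condition == "KCl") |>
    dplyr::select("strain_id", "log2_ratio")
  log_stage("normalize: %d plates, %d strains",
            length(attr(normalized, "mixture_fits")), nrow(ratios))

  # -- replicate error model -------------------------------------------
  rep_strains <- truth$strain_id[
    seq_len(min(config$replicate_plates * scfg$n_per_plate, scfg$n_strains))
  ]
  rep_wells <- simulate_wells(truth, scfg, condition = "KCl",
                              strains = rep_strains, plate_prefix = "KCl_R2",
                              seed = child_seed(config$seed, 31L))
  rep_norm <- normalize_screen(filter_wells(rep_wells)$wells)
  rep_ratios <- collapse_replicates(rep_norm) |>
    dplyr::select("strain_id", "log2_ratio")
  stats <- replicate_concordance(
    dplyr::filter(ratios, .data$strain_id %in% rep_strains), rep_ratios
  )
  model <- fit_null_model(stats)
  log_stage("error model: r = %.3f, mean |diff| = %.3f over %d strains -> N(0, %.1f)",
            stats$pearson_r, stats$mean_abs_diff, stats$n_pairs, model$sd)

  # -- primary calling and rescreen ------------------------------------
  primary <- call_primary_hits(ratios, config$primary_threshold)
  selection <- select_for_rescreen(ratios, config$rescreen_threshold,
                                   n_controls = config$n_rescreen_controls,
                                   n_per_plate = scfg$n_per_plate)
  log_stage("primary: %d hits > %.1f; %d selected > %.1f for rescreen",
            nrow(primary), config$primary_threshold,
            nrow(selection$selected), config$rescreen_threshold)
  rescreen_wells <- simulate_rearray(
    truth, scfg, selection$selected$strain_id, selection$controls,
    condition = "KCl", plate_prefix = "rescreen",
    seed = child_seed(config$seed, 41L)
  )
  rescreen_ratios <- filter_wells(rescreen_wells)$wells |>
    normalize_screen(method = "controls") |>
    dplyr::filter(.data$role == "library") |>
    collapse_replicates() |>
    dplyr::select("strain_id", "log2_ratio")
  hit_calls <- confirm_hits(ratios, rescreen_ratios,
                            config$confirmation_threshold)
  confirmed <- hit_calls$strain_id[hit_calls$confirmed]
  confirmation_rate <- mean(hit_calls$confirmed)
  log_stage("confirm: %d/%d confirmed (%.1f%%)",
            length(confirmed), nrow(hit_calls), 100 * confirmation_rate)

  # -- epistasis subscreens --------------------------------------------
  capacity <- config$max_subscreen_plates * scfg$n_per_plate -
    config$n_subscreen_controls
  top <- call_primary_hits(ratios, config$subscreen_threshold)
  sub_strains <- head(top$strain_id, capacity)
  sub_controls <- select_center_controls(
    dplyr::filter(ratios, !.data$strain_id %in% sub_strains),
    config$n_subscreen_controls
  )
  subscreen_values <- function(cond, offset) {
    w <- simulate_rearray(truth, scfg, sub_strains, sub_controls,
                          condition = cond,
                          seed = child_seed(config$seed, offset))
    filter_wells(w)$wells |>
      normalize_screen(method = "controls") |>
      dplyr::filter(.data$role == "library") |>
      collapse_replicates() |>
      dplyr::select("strain_id", "log2_ratio")
  }
  mock_vals <- subscreen_values("mock", 51L)
  rap_vals <- subscreen_values("rapamycin", 52L)
  constitutive <- flag_constitutive(mock_vals, config$mock_threshold)
  torc1 <- classify_torc1(rap_vals, config$rapamycin_threshold)
  hit_calls <- assemble_final_classes(hit_calls, constitutive, torc1,
                                      mock = mock_vals, rap = rap_vals)
  class_counts <- table(hit_calls$final_class)
  log_stage("classify: %d subscreened; %d constitutive, %d downstream of TORC1",
            length(sub_strains), length(constitutive),
            sum(hit_calls$final_class == "downstream_TORC1"))

  # -- network ----------------------------------------------------------
  gcfg <- config$graph %||% scaled_graph_config(
    scfg$n_strains, length(confirmed), seed = child_seed(config$seed, 61L)
  )
  if (gcfg$planted_set_size != length(confirmed)) {
    gcfg <- graph_config(
      n_genes = gcfg$n_genes, background_edges = gcfg$background_edges,
      planted_set_size = length(confirmed),
      planted_extra_edges = min(
        gcfg$planted_extra_edges,
        length(confirmed) * (length(confirmed) - 1) %/% 2
      ),
      evidence_class_mix = gcfg$evidence_class_mix, seed = gcfg$seed
    )
  }
  sim_graph <- simulate_graph(gcfg, planted_genes = confirmed,
                              genes = truth$strain_id)
  perm <- permutation_test(
    sim_graph$edges, universe = truth$strain_id, observed_set = confirmed,
    n_permutations = config$n_permutations,
    seed = child_seed(config$seed, 71L)
  )
  annotations <- tibble::tibble(
    gene = hit_calls$strain_id[hit_calls$final_class == "downstream_TORC1"],
    tag = "downstream_TORC1"
  )
  graph <- build_graph(sim_graph$edges, hit_set = confirmed,
                       gene_universe = truth$strain_id,
                       annotations = annotations)
  comps <- component_stats(graph)
  log_stage("network: %d induced edges vs null mean %.1f (max %d); p = %.3g",
            perm$observed_edges, perm$null_mean, perm$null_max,
            perm$empirical_p)

  report <- structure(
    list(
      config = config,
      counts = list(
        n_strains = scfg$n_strains,
        n_wells = nrow(wells),
        n_retained_wells = flt$report$n_retained,
        n_primary_hits = nrow(primary),
        n_selected = nrow(selection$selected),
        n_confirmed = length(confirmed),
        n_subscreened = length(sub_strains),
        n_constitutive = sum(hit_calls$final_class == "constitutive"),
        n_downstream = sum(hit_calls$final_class == "downstream_TORC1"),
        n_upstream = sum(hit_calls$final_class == "upstream_or_parallel"),
        n_unclassified = sum(hit_calls$final_class == "unclassified" &
                               hit_calls$confirmed)
      ),
      confirmation_rate = confirmation_rate,
      filter_report = flt$report,
      replicate_stats = stats,
      null_model = model,
      z_score = z_score(config$primary_threshold, model),
      tail_probability = tail_probability(config$primary_threshold, model),
      permutation = perm,
      components = comps,
      hit_calls = hit_calls,
      ratios = ratios,
      truth = truth,
      graph = graph,
      edges = sim_graph$edges
    ),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) write_study_artifacts(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  c <- x$counts
  cat("<study_report>\n")
  cat(sprintf("  screen: %d strains; %d/%d wells retained\n",
              c$n_strains, c$n_retained_wells, c$n_wells))
  cat(sprintf("  replicates: r = %.3f, mean |diff| = %.3f -> null N(0, %.1f), Z = %.1f at %.1f\n",
              x$replicate_stats$pearson_r, x$replicate_stats$mean_abs_diff,
              x$null_model$sd, x$z_score, x$config$primary_threshold))
  cat(sprintf("  calls: %d primary > %.1f; %d selected; %d confirmed (%.1f%%)\n",
              c$n_primary_hits, x$config$primary_threshold, c$n_selected,
              c$n_confirmed, 100 * x$confirmation_rate))
  cat(sprintf("  classes: %d constitutive, %d downstream of TORC1, %d upstream/parallel, %d unclassified\n",
              c$n_constitutive, c$n_downstream, c$n_upstream, c$n_unclassified))
  cat(sprintf("  network: %d induced edges vs null mean %.1f (max %d), p = %.3g\n",
              x$permutation$observed_edges, x$permutation$null_mean,
              x$permutation$null_max, x$permutation$empirical_p))
  cat(sprintf("  components: major %d, isolated %d\n",
              x$components$major_component_size, x$components$isolated_count))
  invisible(x)
}

#' One-row summary of a study report
#'
#' @param x A `study_report` from [run_study()].
#' @param ... Unused.
#' @return A one-row tibble of stage counts and key statistics.
#' @export
glance.study_report <- function(x, ...) {
  tibble::as_tibble(x$counts) |>
    dplyr::mutate(
      confirmation_rate = x$confirmation_rate,
      pearson_r = x$replicate_stats$pearson_r,
      mean_abs_diff = x$replicate_stats$mean_abs_diff,
      null_sd = x$null_model$sd,
      z_score = x$z_score,
      tail_probability = x$tail_probability,
      observed_edges = x$permutation$observed_edges,
      perm_null_mean = x$permutation$null_mean,
      perm_null_max = x$permutation$null_max,
      empirical_p = x$permutation$empirical_p,
      major_component_size = x$components$major_component_size,
      isolated_count = x$components$isolated_count
    )
}

#' @rdname glance.study_report
#' @export
tidy.study_report <- function(x, ...) {
  x$hit_calls
}

#' Write all stage artifacts of a study
#'
#' Emits the well table (CSV), truth and hit-call tables (TSV), normalized
#' ratios (TSV), filter report / replicate stats / null model / permutation
#' summary (JSON), the edge list (TSV) and the hit graph (GraphML, SIF).
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_truth(report$truth, p("truth.tsv"))
  write_normalized(
    dplyr::mutate(report$ratios, plate_id = NA_character_, condition = "KCl"),
    p("normalized_kcl.tsv")
  )
  write_hit_calls(report$hit_calls, p("hit_calls.tsv"))
  write_filter_report(report$filter_report, p("filter_report.json"))
  jsonlite::write_json(
    list(
      replicate_stats = tidy(report$replicate_stats),
      null_model = tidy(report$null_model),
      z_score = report$z_score,
      tail_probability = report$tail_probability,
      counts = report$counts,
      confirmation_rate = report$confirmation_rate,
      permutation = glance(report$permutation),
      component_sizes = report$components$component_sizes
    ),
    p("study_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_interaction_edges(report$edges, p("edges.tsv"))
  export_graph(report$graph, p("hit_network.graphml"), "graphml")
  export_graph(report$graph, p("hit_network.sif"), "sif")
  invisible(dir)
}
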