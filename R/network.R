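#' Map interaction-evidence labels onto the three evidence classes
#'
#' BioGRID-style experimental-system names collapse onto three classes:
#' `affinity` (Affinity Capture-Luminescence/-MS/-RNA/-Western, Reconstituted
#' Complex), `interaction_screen` (Two-hybrid, Protein-Fragment
#' Complementation Assay), and `other` (everything else). Already-canonical
#' labels pass through unchanged.
#'
#' @param evidence Character vector of evidence labels.
#' @return Character vector over `affinity`, `interaction_screen`, `other`.
#' @export
map_evidence_class <- function(evidence) {
  key <- tolower(gsub("[^a-z]+", "_", tolower(evidence)))
  affinity <- c("affinity_capture_luminescence", "affinity_capture_ms",
                "affinity_capture_rna", "affinity_capture_western",
                "reconstituted_complex", "affinity")
  screen <- c("two_hybrid", "protein_fragment_complementation_assay",
              "interaction_screen", "pca")
  out <- rep("other", length(evidence))
  out[key %in% affinity] <- "affinity"
  out[key %in% screen] <- "interaction_screen"
  out
}

# Canonical unique unordered pairs: gene_a < gene_b, self-loops removed,
# duplicates merged by evidence precedence affinity > interaction_screen >
# other.
canonical_edges <- function(edges) {
  assert_columns(edges, c("gene_a", "gene_b"), "edges")
  if (nrow(edges) == 0) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          evidence_class = character(0)))
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  cls <- if ("evidence_class" %in% names(edges)) {
    map_evidence_class(edges$evidence_class[keep])
  } else {
    rep("other", sum(keep))
  }
  tbl <- tibble::tibble(gene_a = a[keep], gene_b = b[keep],
                        evidence_class = cls)
  if (nrow(tbl) == 0) return(tbl)
  tbl |>
    dplyr::mutate(
      rank = match(.data$evidence_class, .evidence_classes)
    ) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      evidence_class = .evidence_classes[min(.data$rank)],
      .groups = "drop"
    )
}

#' Build the evidence-typed interaction graph over a hit set
#'
#' Induces the interaction network on the hit set: self-loops are dropped,
#' duplicate pairs are merged with evidence precedence
#' `affinity > interaction_screen > other`, and every hit becomes a node
#' even if isolated. Optional reference nodes (e.g. a merged TORC1 node
#' standing for Tor1/Kog1/Lst8/Tco89) are added by rewiring their member
#' genes' edges onto the merged name; reference nodes are tagged
#' `is_reference` so they can be excluded from enrichment statistics.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`, `evidence_class`).
#' @param hit_set Character vector of hit genes (the induced node set).
#' @param gene_universe Optional character vector; hits outside it trigger a
#'   warning but are kept as isolated nodes.
#' @param annotations Optional tibble (`gene`, `tag`); tags
#'   `downstream_TORC1`, `nucleus`, `endomembrane_vacuole` and `histone`
#'   become node attributes (localization defaults to `other`).
#' @param reference_nodes Optional named list mapping a reference-node name
#'   to its member genes, e.g. `list(TORC1 = c("TOR1","KOG1","LST8","TCO89"))`.
#' @return An `igraph` object with node attributes `downstream_torc1`,
#'   `localization`, `histone`, `is_reference` and edge attribute
#'   `evidence_class`.
#' @export
build_graph <- function(edges, hit_set, gene_universe = NULL,
                        annotations = NULL, reference_nodes = NULL) {
  edges <- canonical_edges(edges)
  if (!is.null(gene_universe)) {
    unknown <- setdiff(hit_set, gene_universe)
    if (length(unknown) > 0) {
      warn(sprintf(
        "%d hit gene(s) not in the gene universe; kept as isolated nodes (e.g. %s)",
        length(unknown), paste(head(unknown, 3), collapse = ", ")
      ))
    }
  }
  nodes <- unique(hit_set)
  if (!is.null(reference_nodes)) {
    for (ref in names(reference_nodes)) {
      members <- reference_nodes[[ref]]
      edges$gene_a[edges$gene_a %in% members] <- ref
      edges$gene_b[edges$gene_b %in% members] <- ref
      nodes <- unique(c(setdiff(nodes, members), ref))
    }
    # rewiring can create self-loops / duplicates; canonicalize again
    edges <- canonical_edges(edges)
  }
  induced <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ]

  vertex_df <- data.frame(name = nodes, stringsAsFactors = FALSE)
  vertex_df$is_reference <- nodes %in% names(reference_nodes %||% list())
  vertex_df$downstream_torc1 <- rep(FALSE, length(nodes))
  vertex_df$localization <- rep("other", length(nodes))
  vertex_df$histone <- rep(FALSE, length(nodes))
  if (!is.null(annotations)) {
    assert_columns(annotations, c("gene", "tag"), "annotations")
    down <- annotations$gene[annotations$tag == "downstream_TORC1"]
    nuc <- annotations$gene[annotations$tag == "nucleus"]
    endo <- annotations$gene[annotations$tag == "endomembrane_vacuole"]
    hist <- annotations$gene[annotations$tag == "histone"]
    vertex_df$downstream_torc1 <- nodes %in% down
    vertex_df$localization[nodes %in% endo] <- "endomembrane_vacuole"
    vertex_df$localization[nodes %in% nuc] <- "nucleus"
    vertex_df$histone <- nodes %in% hist
  }
  igraph::graph_from_data_frame(
    as.data.frame(induced), directed = FALSE, vertices = vertex_df
  )
}

#' Count edges induced by a gene set
#'
#' Number of unique unordered gene pairs within `gene_set` that appear in
#' the edge list, excluding self-interactions.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`).
#' @param gene_set Character vector of genes.
#' @return Integer count.
#' @export
count_induced_edges <- function(edges, gene_set) {
  e <- canonical_edges(edges)
  sum(e$gene_a %in% gene_set & e$gene_b %in% gene_set)
}

#' Permutation test for induced-edge enrichment of a gene set
#'
#' Compares the number of interaction edges within an observed gene set to
#' the null distribution obtained by drawing `n_permutations` uniform random
#' sets of the same size (without replacement within a draw) from the gene
#' universe and counting their induced edges. The empirical p-value uses the
#' add-one convention `(exceedances + 1) / (n_permutations + 1)`, so it is
#' never zero; with 10,000 permutations the smallest reportable p is
#' 1/10001, i.e. just under 0.01%.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`).
#' @param universe Character vector: the gene universe sampled from (e.g.
#'   all screened genes).
#' @param observed_set Character vector: the gene set under test.
#' @param n_permutations Number of random sets (default 10000).
#' @param seed Integer seed for the draws.
#' @param set_size Size of the random sets (default `length(observed_set)`).
#' @param exclude Genes (e.g. merged reference nodes) removed from the
#'   observed set before counting.
#' @return An object of class `permutation_test_result`: `observed_edges`,
#'   `n_permutations`, `null_mean`, `null_sd`, `null_max`,
#'   `null_distribution` (named count table), `empirical_p`, `seed`,
#'   `set_size`, `universe_size`.
#' @export
permutation_test <- function(edges, universe, observed_set,
                             n_permutations = 10000, seed = 1L,
                             set_size = NULL, exclude = NULL) {
  observed_set <- setdiff(unique(observed_set), exclude)
  set_size <- set_size %||% length(observed_set)
  universe <- unique(universe)
  n_universe <- length(universe)
  if (set_size > n_universe) {
    abort("`set_size` exceeds the universe size.")
  }
  e <- canonical_edges(edges)
  observed <- sum(e$gene_a %in% observed_set & e$gene_b %in% observed_set)

  ia <- match(e$gene_a, universe)
  ib <- match(e$gene_b, universe)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      memb <- logical(n_universe)
      memb[sample.int(n_universe, set_size)] <- TRUE
      sum(memb[ia] & memb[ib])
    }, integer(1))
  })
  structure(
    list(
      observed_edges = observed,
      n_permutations = n_permutations,
      null_mean = mean(null_counts),
      null_sd = sd(null_counts),
      null_max = max(null_counts),
      null_distribution = table(null_counts),
      empirical_p = (sum(null_counts >= observed) + 1) / (n_permutations + 1),
      seed = as.integer(seed),
      set_size = set_size,
      universe_size = n_universe
    ),
    class = "permutation_test_result"
  )
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat("<permutation_test_result>\n")
  cat(sprintf("  observed induced edges: %d (set of %d genes from a %d-gene universe)\n",
              x$observed_edges, x$set_size, x$universe_size))
  cat(sprintf("  null over %d permutations: mean %.1f, sd %.1f, max %d\n",
              x$n_permutations, x$null_mean, x$null_sd, x$null_max))
  cat(sprintf("  empirical p = %.3g (add-one)\n", x$empirical_p))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `permutation_test_result`.
#' @param ... Unused.
#' @export
tidy.permutation_test_result <- function(x, ...) {
  tibble::tibble(
    induced_edges = as.integer(names(x$null_distribution)),
    n = as.integer(x$null_distribution)
  )
}

#' @rdname permutation_test
#' @export
glance.permutation_test_result <- function(x, ...) {
  tibble::tibble(
    observed_edges = x$observed_edges,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    null_max = x$null_max,
    empirical_p = x$empirical_p,
    n_permutations = x$n_permutations,
    set_size = x$set_size,
    universe_size = x$universe_size
  )
}

#' @rdname permutation_test
#' @param object A `permutation_test_result`.
#' @export
autoplot.permutation_test_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$induced_edges, y = .data$n)) +
    ggplot2::geom_col(fill = "grey60", width = 1) +
    ggplot2::geom_vline(xintercept = object$observed_edges,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "induced edge count", y = "permutations",
      title = "Induced-edge permutation null vs observed",
      subtitle = sprintf("observed %d; null mean %.1f; p = %.3g",
                         object$observed_edges, object$null_mean,
                         object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Remove promiscuous hub nodes and their private neighbors
#'
#' Deletes the given hub genes and, with them, any node all of whose edges
#' went to hubs (isolated nodes and nodes retaining at least one non-hub
#' edge are kept).
#'
#' @param graph An `igraph` from [build_graph()].
#' @param hub_genes Character vector of hub names (absent names ignored).
#' @return The pruned `igraph`.
#' @export
prune_hubs <- function(graph, hub_genes) {
  present <- intersect(hub_genes, igraph::V(graph)$name)
  if (length(present) == 0) return(graph)
  deg <- igraph::degree(graph)
  only_hub <- vapply(igraph::V(graph)$name, function(v) {
    if (v %in% present) return(FALSE)
    if (deg[[v]] == 0) return(FALSE)
    nbrs <- igraph::neighbors(graph, v)$name
    all(nbrs %in% present)
  }, logical(1))
  igraph::delete_vertices(graph, c(present, names(only_hub)[only_hub]))
}

#' Connected-component statistics
#'
#' @param graph An `igraph`.
#' @return A list: `major_component_size` (largest component),
#'   `isolated_count` (degree-0 nodes), `component_sizes` (decreasing),
#'   `n_nodes`.
#' @export
component_stats <- function(graph) {
  comps <- igraph::components(graph)
  sizes <- sort(as.integer(comps$csize), decreasing = TRUE)
  list(
    major_component_size = if (length(sizes) > 0) sizes[1] else 0L,
    isolated_count = sum(igraph::degree(graph) == 0),
    component_sizes = sizes,
    n_nodes = igraph::vcount(graph)
  )
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a hit set and an annotation set drawn from a common gene
#' universe -- the generic form of a GO-style enrichment test (the
#' annotation sets themselves are supplied by the caller).
#'
#' @param hit_set,annotation_set Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes.
#' @return The enrichment p-value.
#' @export
#' @examples
#' u <- letters[1:10]
#' hypergeometric_enrichment(letters[1:4], letters[c(1:4, 10)], u)  # 5/210
hypergeometric_enrichment <- function(hit_set, annotation_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  hit_set <- unique(hit_set)
  annotation_set <- unique(annotation_set)
  if (!all(hit_set %in% universe) || !all(annotation_set %in% universe)) {
    abort("`hit_set` and `annotation_set` must be subsets of `universe`.")
  }
  q <- length(intersect(hit_set, annotation_set))
  m <- length(annotation_set)
  n <- length(universe) - m
  k <- length(hit_set)
  phyper(q - 1, m, n, k, lower.tail = FALSE)
}

#' Export a graph as GraphML or SIF
#'
#' GraphML carries the node attributes (`downstream_torc1` for node-center
#' coloring, `localization` for border coloring, `is_reference`, `histone`)
#' and the `evidence_class` edge attribute; SIF writes one
#' `gene_a evidence_class gene_b` line per edge plus bare lines for isolated
#' nodes. Both import into standard graph viewers.
#'
#' @param graph An `igraph` from [build_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("Directory does not exist: %s", dir))
  if (format == "graphml") {
    g <- graph
    # logical attributes are not portable in GraphML; store as 0/1
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.logical(v)) g <- igraph::set_vertex_attr(g, a, value = as.integer(v))
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    lines <- character(0)
    if (nrow(el) > 0) {
      cls <- el$evidence_class %||% rep("other", nrow(el))
      lines <- sprintf("%s\t%s\t%s", el$from, cls, el$to)
    }
    isolated <- igraph::V(graph)$name[igraph::degree(graph) == 0]
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
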