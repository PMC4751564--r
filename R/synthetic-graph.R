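#' Configuration for the synthetic interaction-graph generator
#'
#' Parameters for simulating a BioGRID-like undirected protein-interaction
#' edge list with a planted, enriched gene set. Defaults are calibrated so
#' that a random 440-gene subset of the 4709-gene universe has an expected
#' induced edge count near 492 (the uniform-placement expectation
#' `background_edges * k(k-1) / (N(N-1))`), and the planted set carries ~584
#' extra within-set edges on top of that background, giving ~1076 induced
#' edges in total.
#'
#' @param n_genes Size of the gene universe (default 4709).
#' @param background_edges Number of background edges placed uniformly over
#'   unordered gene pairs (default 56500).
#' @param planted_set_size Size of the enriched gene set (default 440).
#' @param planted_extra_edges Extra edges placed uniformly within the planted
#'   set (default 584).
#' @param evidence_class_mix Named proportions over evidence classes
#'   `affinity`, `interaction_screen`, `other`; must sum to 1.
#' @param seed Integer seed.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(n_genes = 4709,
                         background_edges = 56500,
                         planted_set_size = 440,
                         planted_extra_edges = 584,
                         evidence_class_mix = c(affinity = 0.45,
                                                interaction_screen = 0.35,
                                                other = 0.20),
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    background_edges = as.integer(background_edges),
    planted_set_size = as.integer(planted_set_size),
    planted_extra_edges = as.integer(planted_extra_edges),
    evidence_class_mix = evidence_class_mix,
    seed = as.integer(seed)
  )
  n_pairs <- cfg$n_genes * (cfg$n_genes - 1) / 2
  if (cfg$background_edges > n_pairs) {
    abort("`background_edges` exceeds the number of available gene pairs.")
  }
  if (cfg$planted_set_size > cfg$n_genes) {
    abort("`planted_set_size` exceeds `n_genes`.")
  }
  k <- cfg$planted_set_size
  if (cfg$planted_extra_edges > k * (k - 1) / 2) {
    abort("`planted_extra_edges` exceeds the number of within-set pairs.")
  }
  mix <- cfg$evidence_class_mix
  if (is.null(names(mix)) || !setequal(names(mix), .evidence_classes) ||
      any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`evidence_class_mix` must be named proportions over affinity, interaction_screen, other summing to 1.")
  }
  structure(cfg, class = "graph_config")
}

# Uniform sample of `m` unordered pairs (no self-loops, no duplicates) from
# the `n`-gene universe, as a two-column integer matrix with col1 < col2.
# Enumerates when the pair space is small; otherwise rejection-samples.
sample_pairs <- function(n, m, exclude_keys = integer(0)) {
  n_pairs <- n * (n - 1) / 2
  if (m > n_pairs - length(exclude_keys)) {
    abort("Requested more edges than available pairs.")
  }
  if (m == 0) return(matrix(integer(0), ncol = 2))
  pair_key <- function(i, j) (i - 1) * n + j  # i < j, unique per pair
  if (n_pairs <= 2e6) {
    i <- rep.int(seq_len(n - 1), (n - 1):1)
    j <- sequence((n - 1):1, from = 2:n)
    keys <- pair_key(i, j)
    ok <- !(keys %in% exclude_keys)
    pick <- sample.int(sum(ok), m)
    cbind(i[ok][pick], j[ok][pick])
  } else {
    chosen <- integer(0)
    out_i <- integer(0); out_j <- integer(0)
    excl <- exclude_keys
    while (length(out_i) < m) {
      need <- m - length(out_i)
      a <- sample.int(n, ceiling(need * 1.2), replace = TRUE)
      b <- sample.int(n, ceiling(need * 1.2), replace = TRUE)
      i <- pmin(a, b); j <- pmax(a, b)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      keys <- pair_key(i, j)
      keep <- !duplicated(keys) & !(keys %in% excl)
      i <- i[keep]; j <- j[keep]; keys <- keys[keep]
      take <- seq_len(min(need, length(i)))
      out_i <- c(out_i, i[take]); out_j <- c(out_j, j[take])
      excl <- c(excl, keys[take])
    }
    cbind(out_i, out_j)
  }
}

#' Simulate an interaction graph with a planted enriched gene set
#'
#' Places `background_edges` uniformly at random over unordered gene pairs of
#' the universe (no self-loops, no duplicates), then adds
#' `planted_extra_edges` uniformly over pairs within `planted_genes` that are
#' not already edges. Each edge is tagged with an evidence class drawn from
#' `evidence_class_mix`.
#'
#' @param config A [graph_config()].
#' @param planted_genes Character vector of genes forming the enriched set;
#'   must have length `planted_set_size` and be a subset of `genes`. May be
#'   `NULL` when `planted_extra_edges` is 0.
#' @param genes Gene universe (default `gene00001 ...`).
#' @return A list of class `ribi_graph_sim`: `edges` (tibble `gene_a`,
#'   `gene_b`, `evidence_class`), `genes` (the universe), `planted`.
#' @export
#' @examples
#' cfg <- graph_config(n_genes = 50, background_edges = 100,
#'                     planted_set_size = 10, planted_extra_edges = 15)
#' g <- simulate_graph(cfg, planted_genes = sprintf("gene%05d", 1:10))
#' nrow(g$edges)
simulate_graph <- function(config, planted_genes = NULL, genes = NULL) {
  stopifnot(inherits(config, "graph_config"))
  genes <- genes %||% sprintf("gene%05d", seq_len(config$n_genes))
  if (length(genes) != config$n_genes) {
    abort("`genes` must have length `n_genes`.")
  }
  if (config$planted_extra_edges > 0 && is.null(planted_genes)) {
    abort("`planted_genes` is required when `planted_extra_edges` > 0.")
  }
  if (!is.null(planted_genes)) {
    if (!all(planted_genes %in% genes)) {
      abort("`planted_genes` must be a subset of the gene universe.")
    }
    if (length(planted_genes) != config$planted_set_size) {
      abort("`planted_genes` must have length `planted_set_size`.")
    }
  }
  with_seed(config$seed, {
    n <- config$n_genes
    bg <- sample_pairs(n, config$background_edges)
    planted_pairs <- matrix(integer(0), ncol = 2)
    if (config$planted_extra_edges > 0) {
      planted_idx <- sort(match(planted_genes, genes))
      k <- length(planted_idx)
      # enumerate within-set pairs in universe indexing, minus existing edges
      i <- rep.int(seq_len(k - 1), (k - 1):1)
      j <- sequence((k - 1):1, from = 2:k)
      wi <- planted_idx[i]; wj <- planted_idx[j]
      key <- (pmin(wi, wj) - 1) * n + pmax(wi, wj)
      bg_key <- (bg[, 1] - 1) * n + bg[, 2]
      free <- !(key %in% bg_key)
      if (config$planted_extra_edges > sum(free)) {
        abort("Not enough free within-set pairs for `planted_extra_edges`.")
      }
      pick <- sample.int(sum(free), config$planted_extra_edges)
      planted_pairs <- cbind(pmin(wi, wj)[free][pick], pmax(wi, wj)[free][pick])
    }
    pairs <- rbind(bg, planted_pairs)
    classes <- sample(names(config$evidence_class_mix), nrow(pairs),
                      replace = TRUE, prob = config$evidence_class_mix)
    edges <- tibble::tibble(
      gene_a = genes[pairs[, 1]],
      gene_b = genes[pairs[, 2]],
      evidence_class = classes
    )
    structure(
      list(edges = edges, genes = genes, planted = planted_genes,
           config = config),
      class = "ribi_graph_sim"
    )
  })
}

#' @export
print.ribi_graph_sim <- function(x, ...) {
  cat("<ribi_graph_sim>\n")
  cat(sprintf("  %d genes, %d edges (%d planted within a %d-gene set)\n",
              length(x$genes), nrow(x$edges), x$config$planted_extra_edges,
              x$config$planted_set_size))
  invisible(x)
}
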