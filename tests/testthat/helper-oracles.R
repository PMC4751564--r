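# Independent oracles (brute force / enumeration), deliberately naive.

# Best two-component mixture log-likelihood over a parameter grid.
grid_mixture_loglik <- function(x, res = 0.05,
                                mean_range = range(x),
                                sd_max = max(res, sd(x) * 1.5)) {
  mus <- seq(mean_range[1], mean_range[2], by = res)
  sds <- seq(res, sd_max, by = res)
  ws <- seq(0.05, 0.95, by = res)
  combos <- expand.grid(mu = mus, s = sds)
  D <- t(apply(combos, 1, function(p) dnorm(x, p[["mu"]], p[["s"]])))
  best <- -Inf
  for (w in ws) {
    A <- w * D
    B <- (1 - w) * D
    for (i in seq_len(nrow(D))) {
      ll <- rowSums(log(sweep(B, 2, A[i, ], "+")))
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

# Induced edge count by explicit double loop over all set pairs.
brute_induced_edges <- function(edges, gene_set) {
  seen <- character(0)
  count <- 0L
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (key %in% seen) next
    seen <- c(seen, key)
    if (a %in% gene_set && b %in% gene_set) count <- count + 1L
  }
  count
}

# Hub pruning by explicit neighbor scan on an edge data frame.
brute_prune <- function(nodes, edges, hubs) {
  nbrs <- function(v) {
    unique(c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v]))
  }
  drop <- intersect(hubs, nodes)
  for (v in setdiff(nodes, hubs)) {
    nv <- setdiff(nbrs(v), v)
    if (length(nv) > 0 && all(nv %in% hubs)) drop <- c(drop, v)
  }
  setdiff(nodes, drop)
}

# Connected components by hand-rolled BFS.
brute_components <- function(nodes, edges) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v]))
  })
  unvisited <- nodes
  sizes <- integer(0)
  while (length(unvisited) > 0) {
    queue <- unvisited[1]
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!v %in% unvisited) next
      unvisited <- setdiff(unvisited, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(adj[[v]], unvisited))
    }
    sizes <- c(sizes, length(comp))
  }
  sort(sizes, decreasing = TRUE)
}

# Upper-tail hypergeometric probability by direct combinatorial enumeration.
enum_hyper_upper <- function(q, m, n, k) {
  js <- q:min(m, k)
  js <- js[js >= max(0, k - n)]
  sum(choose(m, js) * choose(n, k - js)) / choose(m + n, k)
}
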