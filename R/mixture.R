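#' Fit a two-component 1-D Gaussian mixture by EM
#'
#' Fits the two-population model underlying plate normalization: most wells
#' on a library plate belong to a majority population of strains without an
#' expression defect, while a minority outlier population (strains failing
#' to repress the reporter) sits at lower F-J values. Component means,
#' free per-component variances (floored at `variance_floor`) and weights are
#' estimated by expectation-maximization from a deterministic quantile-based
#' initialization, so the fit is reproducible without a seed.
#'
#' Two deterministic starts are used (component means at the 25th/75th and at
#' the 5th/95th percentiles, equal weights, pooled SD) and the converged run
#' with the higher log-likelihood is kept; `n_restarts` adds optional random
#' restarts under `seed`. The fit is flagged `degenerate` when the component
#' means are closer than `separation_threshold` log2 units or the minority
#' weight exceeds `max_minority_weight`, in which case the plate shows no
#' resolvable outlier population and callers fall back to a trimmed mean.
#'
#' @param values Numeric vector of at least 8 log2 values (F-J values of one
#'   plate, in the normalization use).
#' @param variance_floor Lower bound on component variances (log2 units
#'   squared); prevents singular components.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param separation_threshold Minimum |mean difference| (log2 units) for a
#'   non-degenerate two-population fit.
#' @param max_minority_weight Largest minority weight still considered an
#'   outlier population.
#' @param n_restarts Number of additional random restarts (default 0).
#' @param seed Seed for random restarts; unused when `n_restarts = 0`.
#' @return An object of class `mixture_fit` with elements `weights`, `means`,
#'   `sds`, `log_likelihood`, `loglik_trace`, `n_iterations`, `converged`,
#'   `majority_component`, `degenerate`, `responsibilities` (n x 2 posterior
#'   matrix), and `values`.
#' @export
#' @examples
#' set.seed(7)
#' x <- c(rnorm(90, 0, 0.3), rnorm(6, 3, 0.3))
#' fit <- fit_mixture_em(x)
#' tidy(fit)
fit_mixture_em <- function(values,
                           variance_floor = 1e-3,
                           max_iter = 500L,
                           tol = 1e-8,
                           separation_threshold = 0.5,
                           max_minority_weight = 0.4,
                           n_restarts = 0L,
                           seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 8 || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must hold at least 8 finite values.")
  }
  n <- length(values)

  if (sd(values) == 0) {
    # all values identical: one effective component at that value
    sds <- rep(sqrt(variance_floor), 2)
    ll <- sum(dnorm(values, values[1], sds[1], log = TRUE))
    resp <- matrix(0.5, n, 2)
    return(new_mixture_fit(
      weights = c(0.5, 0.5), means = rep(values[1], 2), sds = sds,
      log_likelihood = ll, loglik_trace = ll, n_iterations = 0L,
      converged = TRUE, degenerate = TRUE, responsibilities = resp,
      values = values,
      separation_threshold = separation_threshold,
      max_minority_weight = max_minority_weight
    ))
  }

  pooled_sd <- max(sd(values), sqrt(variance_floor))
  inits <- list(
    list(means = unname(quantile(values, c(0.25, 0.75))),
         sds = rep(pooled_sd, 2), weights = c(0.5, 0.5)),
    list(means = unname(quantile(values, c(0.05, 0.95))),
         sds = rep(pooled_sd, 2), weights = c(0.5, 0.5)),
    gap_split_init(values, pooled_sd, variance_floor)
  )
  if (n_restarts > 0) {
    extra <- with_seed(seed %||% 1L, {
      purrr::map(seq_len(n_restarts), function(i) {
        list(means = sort(sample(values, 2)),
             sds = rep(pooled_sd, 2), weights = c(0.5, 0.5))
      })
    })
    inits <- c(inits, extra)
  }

  runs <- purrr::map(inits, function(init) {
    em_run(values, init, variance_floor, max_iter, tol)
  })
  best <- runs[[which.max(purrr::map_dbl(runs, "log_likelihood"))]]

  degenerate <- abs(diff(best$means)) < separation_threshold ||
    min(best$weights) > max_minority_weight
  new_mixture_fit(
    weights = best$weights, means = best$means, sds = best$sds,
    log_likelihood = best$log_likelihood, loglik_trace = best$loglik_trace,
    n_iterations = best$n_iterations, converged = best$converged,
    degenerate = degenerate, responsibilities = best$responsibilities,
    values = values,
    separation_threshold = separation_threshold,
    max_minority_weight = max_minority_weight
  )
}

# Deterministic 1-D cluster seed: split the sorted values at their largest
# adjacent gap and initialize each component from its side of the split.
# Catches small, well-separated outlier populations that sit outside the
# quantile-based starts.
gap_split_init <- function(x, pooled_sd, variance_floor) {
  xs <- sort(x)
  gaps <- diff(xs)
  cut <- which.max(gaps)
  lo <- xs[seq_len(cut)]
  hi <- xs[-seq_len(cut)]
  sd_floor <- sqrt(variance_floor)
  list(
    means = c(mean(lo), mean(hi)),
    sds = pmax(c(if (length(lo) > 1) sd(lo) else 0,
                 if (length(hi) > 1) sd(hi) else 0),
               max(sd_floor, pooled_sd / 4)),
    weights = c(length(lo), length(hi)) / length(x)
  )
}

# One EM run from a fixed initialization. The parameter update is accepted
# only if it does not decrease the log-likelihood (variance flooring can in
# principle break the EM monotonicity guarantee), so the trace is
# non-decreasing by construction.
em_run <- function(x, init, variance_floor, max_iter, tol) {
  n <- length(x)
  w <- init$weights; mu <- init$means; s <- init$sds
  loglik <- function(w, mu, s) {
    sum(log(w[1] * dnorm(x, mu[1], s[1]) + w[2] * dnorm(x, mu[2], s[2])))
  }
  ll <- loglik(w, mu, s)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0.5, n, 2)
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    resp <- cbind(r1, 1 - r1)
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    new_w <- nk / n
    new_mu <- c(sum(resp[, 1] * x), sum(resp[, 2] * x)) / nk
    new_var <- c(sum(resp[, 1] * (x - new_mu[1])^2),
                 sum(resp[, 2] * (x - new_mu[2])^2)) / nk
    new_s <- sqrt(pmax(new_var, variance_floor))
    new_ll <- loglik(new_w, new_mu, new_s)
    if (new_ll < ll - 1e-10) break  # flooring artefact: keep previous state
    w <- new_w; mu <- new_mu; s <- new_s
    gain <- new_ll - ll
    ll <- new_ll
    trace <- c(trace, ll)
    if (gain < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    weights = unname(w), means = unname(mu), sds = unname(s),
    log_likelihood = ll, loglik_trace = trace, n_iterations = iter,
    converged = converged, responsibilities = unname(resp)
  )
}

new_mixture_fit <- function(weights, means, sds, log_likelihood, loglik_trace,
                            n_iterations, converged, degenerate,
                            responsibilities, values,
                            separation_threshold, max_minority_weight) {
  # majority component: higher weight; ties go to the higher-mean component
  # (lower reporter expression = no defect)
  if (abs(weights[1] - weights[2]) < 1e-12) {
    majority <- which.max(means)
  } else {
    majority <- which.max(weights)
  }
  structure(
    list(
      weights = weights, means = means, sds = sds,
      log_likelihood = log_likelihood, loglik_trace = loglik_trace,
      n_iterations = n_iterations, converged = converged,
      majority_component = majority, degenerate = degenerate,
      responsibilities = responsibilities, values = values, n = length(values),
      separation_threshold = separation_threshold,
      max_minority_weight = max_minority_weight
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>\n")
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.3f, mean %+.3f, sd %.3f%s\n",
                k, x$weights[k], x$means[k], x$sds[k],
                if (k == x$majority_component) "  (majority)" else ""))
  }
  cat(sprintf("  log-likelihood %.3f after %d iteration(s); %s%s\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "not converged",
              if (x$degenerate) "; DEGENERATE (no outlier population)" else ""))
  invisible(x)
}

#' @rdname fit_mixture_em
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    component = 1:2,
    weight = x$weights,
    mean = x$means,
    sd = x$sds,
    majority = 1:2 == x$majority_component
  )
}

#' @rdname fit_mixture_em
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    n_iterations = x$n_iterations,
    converged = x$converged,
    degenerate = x$degenerate,
    majority_component = x$majority_component,
    n = x$n
  )
}

#' @rdname fit_mixture_em
#' @param object A `mixture_fit`.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  df <- tibble::tibble(value = object$values)
  grid <- seq(min(object$values) - 1, max(object$values) + 1, length.out = 400)
  dens <- tibble::tibble(
    value = rep(grid, 2),
    component = factor(rep(1:2, each = length(grid))),
    density = c(
      object$weights[1] * dnorm(grid, object$means[1], object$sds[1]),
      object$weights[2] * dnorm(grid, object$means[2], object$sds[2])
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "F-J value (log2)", y = "density",
      title = "Two-population mixture fit",
      subtitle = sprintf("majority component %d; %s",
                         object$majority_component,
                         if (object$degenerate) "degenerate" else "separated")
    ) +
    ggplot2::theme_minimal()
}
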