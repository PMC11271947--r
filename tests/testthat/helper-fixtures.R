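# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately brute-force (loops, grids, fine-grid integration) and never
# call the code paths they check.

small_config <- function(seed = 42, ...) {
  synthetic_config(n_patients = 200, n_providers = 80, n_charts = 200,
                   seed = seed, ...)
}

patient_catalog <- function(catalog = default_catalog()) {
  catalog[catalog$source %in% c("patient survey", "registry"), ]
}

# tiny indicator matrix from an explicit value matrix
toy_matrix <- function(values, sub_domain = "accessibility",
                       unit_level = "patient") {
  colnames(values) <- paste0("ind_", seq_len(ncol(values)))
  doms <- phc_domains()
  dom <- names(doms)[vapply(doms, function(s) sub_domain %in% s, logical(1))]
  mapping <- tibble::tibble(
    indicator_id = colnames(values),
    sub_domain = sub_domain,
    domain = dom
  )
  indicator_matrix(values, mapping, unit_level = unit_level)
}

# brute-force Cronbach's alpha by direct variance computation in a loop
alpha_oracle <- function(X) {
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  iv <- 0
  for (i in seq_len(k)) iv <- iv + stats::var(X[, i])
  tot <- stats::var(rowSums(X))
  k / (k - 1) * (1 - iv / tot)
}

# fine-grid integration of int f(theta) phi(theta) dtheta
grid_integrate <- function(f, lower = -10, upper = 10, n = 20001) {
  th <- seq(lower, upper, length.out = n)
  h <- th[2] - th[1]
  sum(f(th) * stats::dnorm(th)) * h
}

# marginal log-likelihood of dichotomous Rasch data on a theta grid,
# independent of the package's EM path. `nodes`/`weights` default to a dense
# trapezoid grid against the normal density; passing Gauss-Hermite nodes
# reproduces the quadrature likelihood definition exactly.
loglik_grid_oracle <- function(Y, b, nodes = NULL, weights = NULL) {
  if (is.null(nodes)) {
    nodes <- seq(-10, 10, length.out = 4001)
    weights <- stats::dnorm(nodes) * (nodes[2] - nodes[1])
  }
  P <- stats::plogis(outer(nodes, b, "-"))
  ll <- 0
  for (j in seq_len(nrow(Y))) {
    lik <- rep(1, length(nodes))
    for (i in seq_len(ncol(Y))) {
      if (!is.na(Y[j, i])) {
        lik <- lik * if (Y[j, i] == 1) P[, i] else 1 - P[, i]
      }
    }
    ll <- ll + log(sum(lik * weights))
  }
  ll
}

# brute-force coarse-to-fine grid search over two item difficulties
# maximising the quadrature marginal likelihood (21 Gauss-Hermite nodes,
# obtained directly from pracma, matching the model's likelihood definition
# but not its estimation path). Response patterns are aggregated first.
grid_search_two_items <- function(Y) {
  gh <- pracma::gaussHermite(21)
  nodes <- sqrt(2) * gh$x
  weights <- gh$w / sqrt(pi)
  pat <- unique(Y)
  cnt <- integer(nrow(pat))
  for (r in seq_len(nrow(pat))) {
    cnt[r] <- sum(apply(Y, 1, function(row) all(row == pat[r, ])))
  }
  ll_pat <- function(b) {
    P <- stats::plogis(outer(nodes, b, "-"))
    tot <- 0
    for (r in seq_len(nrow(pat))) {
      lik <- rep(1, length(nodes))
      for (i in seq_len(ncol(pat))) {
        lik <- lik * if (pat[r, i] == 1) P[, i] else 1 - P[, i]
      }
      tot <- tot + cnt[r] * log(sum(lik * weights))
    }
    tot
  }
  best <- c(0, 0)
  span <- 2.5
  step <- 0.25
  for (round in 1:4) {
    g1 <- seq(best[1] - span, best[1] + span, by = step)
    g2 <- seq(best[2] - span, best[2] + span, by = step)
    val <- matrix(NA_real_, length(g1), length(g2))
    for (a in seq_along(g1)) for (b2 in seq_along(g2)) {
      val[a, b2] <- ll_pat(c(g1[a], g2[b2]))
    }
    ix <- which(val == max(val), arr.ind = TRUE)[1, ]
    best <- c(g1[ix[1]], g2[ix[2]])
    span <- step * 2
    step <- step / 10
  }
  best
}

# construct an n x k data matrix whose sample covariance equals `target`
# exactly (whiten the sample, re-colour with the target Cholesky factor)
data_with_exact_cov <- function(n, target, seed = 1) {
  set.seed(seed)
  k <- ncol(target)
  X <- matrix(stats::rnorm(n * k), n, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- solve(chol(stats::cov(X)))
  X %*% W %*% chol(target)
}
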