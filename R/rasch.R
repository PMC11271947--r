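# Dichotomous Rasch model (one-parameter logistic IRT).
#
# Model: P(Y_ij = 1 | theta_j) = exp(theta_j - b_i) / (1 + exp(theta_j - b_i)),
# theta_j ~ N(0, 1). Persons differ only in ability theta, items only in
# difficulty b; equivalently logit P = theta - b.
#
# Item difficulties are estimated by marginal maximum likelihood: theta is
# integrated out under its fixed standard-normal prior by Gauss-Hermite
# quadrature and the marginal likelihood is maximised with an EM algorithm
# (Bock-Aitkin). The prior is part of the model, not estimated, so the
# difficulty scale is identified without centring constraints and all-0 /
# all-1 respondents need no ad hoc corrections. Person abilities are scored
# by the posterior mean (EAP), and abilities map to [0, 1] quality scores via
# the test characteristic curve divided by the item count.

#' Rasch response probability
#'
#' `P(Y = 1 | theta, b) = plogis(theta - b)`, computed overflow-safely;
#' `qlogis()` of the result recovers `theta - b`.
#'
#' @param theta Ability (logit scale), vectorised.
#' @param b Item difficulty (logit scale), vectorised.
#' @return Probability in (0, 1).
#' @export
rasch_prob <- function(theta, b) {
  if (!all(is.finite(theta)) || !all(is.finite(b))) {
    stop("theta and b must be finite", call. = FALSE)
  }
  stats::plogis(theta - b)
}

# Gauss-Hermite nodes/weights transformed for integration against the
# standard-normal density: int f(t) phi(t) dt ~ sum w_k f(t_k).
gauss_hermite_normal <- function(n_nodes) {
  gh <- pracma::gaussHermite(n_nodes)
  list(nodes = sqrt(2) * gh$x, weights = gh$w / sqrt(pi))
}

# Per-person log-likelihood at each quadrature node. Y: n x I matrix with NA
# for missing; returns n x K matrix. Missing cells contribute nothing.
node_loglik <- function(Y, b, nodes) {
  obs <- !is.na(Y)
  Y0 <- Y
  Y0[!obs] <- 0
  # log P and log(1-P) as K x I, via log-sigmoid for stability
  eta <- outer(nodes, b, "-")
  logp <- -log1p(exp(-eta))
  logq <- -log1p(exp(eta))
  Y0 %*% t(logp) + (obs - Y0) %*% t(logq)
}

#' Fit the Rasch model by marginal maximum likelihood
#'
#' EM (Bock-Aitkin) estimation of item difficulties with the ability
#' integrated out under the fixed `N(0, 1)` prior using Gauss-Hermite
#' quadrature. Items with zero observed variance (all 0 or all 1, after
#' removing missing cells) are dropped before fitting and recorded in
#' `dropped_items`; the marginal log-likelihood is non-decreasing across EM
#' iterations and non-convergence at the iteration cap is flagged, never
#' silent.
#'
#' @param matrix An [indicator_matrix()] restricted to one instrument, or a
#'   plain 0/1 matrix (NA = missing) with named columns.
#' @param n_nodes Gauss-Hermite node count (default 21).
#' @param tol Convergence tolerance on `max |delta b|` (default 1e-6).
#' @param max_iter EM iteration cap (default 500).
#' @return An object of class `rasch_fit`: `item_ids`, `difficulties`,
#'   `ability_estimates` (EAP per unit), `quadrature`, `log_likelihood`,
#'   `convergence`, `dropped_items`, plus the training responses.
#' @export
fit_rasch_mml <- function(matrix, n_nodes = 21, tol = 1e-6, max_iter = 500) {
  if (inherits(matrix, "indicator_matrix")) {
    Y <- matrix$values
    unit_ids <- matrix$unit_ids
  } else {
    Y <- as.matrix(matrix)
    unit_ids <- rownames(Y)
    if (is.null(unit_ids)) unit_ids <- as.character(seq_len(nrow(Y)))
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("item_", seq_len(ncol(Y)))
  obs_vals <- Y[!is.na(Y)]
  if (length(obs_vals) == 0 || !all(obs_vals %in% c(0, 1))) {
    stop("responses must be 0/1 with NA for missing", call. = FALSE)
  }

  col_mean <- colMeans(Y, na.rm = TRUE)
  zero_var <- is.nan(col_mean) | col_mean == 0 | col_mean == 1
  dropped <- tibble::tibble(
    item_id = colnames(Y)[zero_var],
    reason = ifelse(is.nan(col_mean[zero_var]), "all missing",
                    "zero variance"))
  Y <- Y[, !zero_var, drop = FALSE]
  if (ncol(Y) < 2) {
    stop("fewer than 2 retained items: model unidentifiable", call. = FALSE)
  }
  if (nrow(Y) < 2) stop("need at least 2 units", call. = FALSE)

  quad <- gauss_hermite_normal(n_nodes)
  nodes <- quad$nodes
  w <- quad$weights
  obs <- !is.na(Y)
  Y0 <- Y
  Y0[!obs] <- 0

  # start at marginal logits
  b <- -stats::qlogis(colMeans(Y, na.rm = TRUE))
  ll_trace <- numeric(0)
  converged <- FALSE
  delta <- Inf
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    ll_jk <- node_loglik(Y, b, nodes)
    mx <- apply(ll_jk, 1, max)
    lik <- exp(ll_jk - mx)
    marg <- as.vector(lik %*% w)
    ll <- sum(log(marg) + mx)
    ll_trace <- c(ll_trace, ll)
    post <- lik * rep(w, each = nrow(lik)) / marg  # n x K posterior weights

    # expected counts per item x node
    r_ik <- t(Y0) %*% post     # endorsements
    n_ik <- t(obs * 1) %*% post  # respondents

    # M-step: per item, solve sum_k n_ik sigma(t_k - b) = sum_k r_ik (Newton)
    b_new <- b
    r_i <- rowSums(r_ik)
    for (step in 1:10) {
      P <- stats::plogis(outer(-b_new, nodes, "+"))  # I x K
      f <- rowSums(n_ik * P) - r_i
      fp <- -rowSums(n_ik * P * (1 - P))
      upd <- f / fp
      upd[!is.finite(upd)] <- 0
      b_new <- b_new - upd
      if (max(abs(upd)) < 1e-10) break
    }
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  # final log-likelihood at the converged difficulties
  ll_jk <- node_loglik(Y, b, nodes)
  mx <- apply(ll_jk, 1, max)
  marg <- as.vector(exp(ll_jk - mx) %*% w)
  ll_final <- sum(log(marg) + mx)
  if (!converged) {
    warning("Rasch EM did not converge in ", max_iter,
            " iterations (max |delta b| = ", signif(delta, 3), ")",
            call. = FALSE)
  }

  fit <- structure(
    list(item_ids = colnames(Y),
         difficulties = stats::setNames(as.vector(b), colnames(Y)),
         quadrature = list(n_nodes = n_nodes, nodes = nodes, weights = w),
         log_likelihood = ll_final,
         ll_trace = ll_trace,
         convergence = list(iterations = iter, max_delta = delta,
                            converged = converged, tol = tol),
         dropped_items = dropped,
         unit_ids = unit_ids,
         responses = Y),
    class = "rasch_fit")
  fit$ability_estimates <- eap_theta(fit, Y)
  fit
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "<rasch_fit> %d items, %d units; logLik %.2f; %s in %d EM iterations\n",
    length(x$difficulties), nrow(x$responses), x$log_likelihood,
    if (x$convergence$converged) "converged" else "NOT converged",
    x$convergence$iterations))
  if (nrow(x$dropped_items) > 0) {
    cat("dropped:", paste(x$dropped_items$item_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Expected-a-posteriori ability score
#'
#' Posterior mean of theta under the standard-normal prior and the fitted
#' difficulties, by the fit's quadrature. Units with identical observed
#' response patterns get identical scores; a unit with all responses missing
#' gets `NA`.
#'
#' @param fit A `rasch_fit`.
#' @param responses A response vector for one unit, or a units x items matrix
#'   (columns matching the fit's retained items).
#' @return Numeric ability estimate(s), logit scale.
#' @export
eap_theta <- function(fit, responses) {
  if (is.null(dim(responses))) {
    responses <- matrix(responses, nrow = 1,
                        dimnames = list(NULL, fit$item_ids))
  }
  Y <- as.matrix(responses)[, fit$item_ids, drop = FALSE]
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  ll_jk <- node_loglik(Y, fit$difficulties, nodes)
  mx <- apply(ll_jk, 1, max)
  lik <- exp(ll_jk - mx)
  num <- as.vector(lik %*% (w * nodes))
  den <- as.vector(lik %*% w)
  out <- num / den
  out[rowSums(!is.na(Y)) == 0] <- NA_real_
  out
}

#' Map an ability to a quality score on [0, 1]
#'
#' The expected proportion of retained items endorsed at ability theta (the
#' test characteristic curve divided by the item count): strictly increasing
#' in theta with limits 0 and 1.
#'
#' @param fit A `rasch_fit`.
#' @param theta Ability value(s), logit scale (NA passes through).
#' @return Quality score(s) in `[0, 1]`.
#' @export
map_score <- function(fit, theta) {
  if (length(fit$difficulties) < 1) {
    stop("fit retained no items", call. = FALSE)
  }
  vapply(theta, function(t) {
    if (is.na(t)) return(NA_real_)
    mean(rasch_prob(t, fit$difficulties))
  }, numeric(1))
}

#' Marginal log-likelihood of a response matrix under a fit
#'
#' Quadrature approximation of
#' `sum_j log int prod_i P^y (1-P)^(1-y) phi(theta) dtheta`; on the training
#' matrix this equals the value stored at convergence. An empty response set
#' contributes 0 (empty product).
#'
#' @param fit A `rasch_fit`.
#' @param matrix Response matrix (columns matching the fit's items) or an
#'   [indicator_matrix()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(fit, matrix) {
  Y <- if (inherits(matrix, "indicator_matrix")) matrix$values else
    as.matrix(matrix)
  if (nrow(Y) == 0) return(0)
  if (is.null(colnames(Y))) {
    if (ncol(Y) != length(fit$item_ids)) {
      stop("response matrix not conformable with fit", call. = FALSE)
    }
    colnames(Y) <- fit$item_ids
  }
  if (!all(fit$item_ids %in% colnames(Y))) {
    stop("response matrix not conformable with fit", call. = FALSE)
  }
  Y <- Y[, fit$item_ids, drop = FALSE]
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  ll_jk <- node_loglik(Y, fit$difficulties, nodes)
  mx <- apply(ll_jk, 1, max)
  sum(log(as.vector(exp(ll_jk - mx) %*% w)) + mx)
}

#' Rasch-based quality scores for one instrument
#'
#' Convenience wrapper: fit the model on an instrument's indicator matrix,
#' EAP-score every unit and map abilities to `[0, 1]`.
#'
#' @param matrix An [indicator_matrix()] restricted to one instrument.
#' @param ... Passed to [fit_rasch_mml()].
#' @return Tibble `unit_id`, `theta`, `score`, plus the fit as attribute
#'   `"fit"`.
#' @export
rasch_scores <- function(matrix, ...) {
  fit <- fit_rasch_mml(matrix, ...)
  out <- tibble::tibble(
    unit_id = fit$unit_ids,
    theta = fit$ability_estimates,
    score = map_score(fit, fit$ability_estimates)
  )
  attr(out, "fit") <- fit
  out
}

#' @export
tidy.rasch_fit <- function(x, ...) {
  tibble::tibble(item_id = x$item_ids,
                 difficulty = unname(x$difficulties))
}

#' @export
glance.rasch_fit <- function(x, ...) {
  tibble::tibble(
    n_items = length(x$difficulties),
    n_units = nrow(x$responses),
    n_dropped = nrow(x$dropped_items),
    log_likelihood = x$log_likelihood,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged,
    n_nodes = x$quadrature$n_nodes
  )
}

#' Plot item characteristic curves and the score mapping
#'
#' @param object A `rasch_fit`.
#' @param ... Unused.
#' @return A ggplot object: per-item logistic curves (grey) and the test
#'   characteristic curve / item count (the ability-to-score mapping, black).
#' @export
autoplot.rasch_fit <- function(object, ...) {
  theta <- seq(-4, 4, length.out = 161)
  icc <- purrr::map_dfr(seq_along(object$difficulties), function(i) {
    tibble::tibble(item_id = object$item_ids[i], theta = theta,
                   p = rasch_prob(theta, object$difficulties[i]))
  })
  tcc <- tibble::tibble(theta = theta, p = map_score(object, theta))
  ggplot2::ggplot(icc, ggplot2::aes(.data$theta, .data$p,
                                    group = .data$item_id)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_line(data = tcc, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::labs(x = expression(theta), y = "P(endorse)",
                  caption = "grey: item characteristic curves; black: score mapping") +
    ggplot2::theme_minimal()
}

#' Serialize a Rasch fit to JSON
#'
#' @param fit A `rasch_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rasch_fit <- function(fit, path) {
  jsonlite::write_json(
    list(item_ids = fit$item_ids,
         difficulties = unname(fit$difficulties),
         log_likelihood = fit$log_likelihood,
         convergence = fit$convergence,
         quadrature = list(n_nodes = fit$quadrature$n_nodes),
         dropped_items = fit$dropped_items),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
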