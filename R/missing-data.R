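# Multiple imputation by chained equations (MICE) for item nonresponse, and
# Rubin's rules for pooling estimates across completed datasets.
#
# Per-column conditional models: binary columns by logistic regression with
# an approximate-posterior draw of the coefficients before predicting;
# categorical columns by multinomial regression refit on a bootstrap resample
# (the standard approximation to a posterior draw); continuous columns by
# predictive mean matching (k = 5 donors) after a posterior draw of the
# linear-model coefficients. Degenerate fits (separation, non-convergence)
# fall back to empirical draws from the observed margin, which keeps the
# procedure proper-in-expectation under MCAR.

draw_binary_column <- function(y, X_obs, X_mis) {
  fit <- suppressWarnings(stats::glm.fit(X_obs, y,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  ok <- all(!is.na(beta) & abs(beta) < 15) && isTRUE(fit$converged)
  if (!ok) {
    return(stats::rbinom(nrow(X_mis), 1, mean(y)))
  }
  # approximate posterior N(beta_hat, (X'WX)^-1)
  w <- fit$weights
  XtWX <- crossprod(X_obs * sqrt(w))
  V <- try(solve(XtWX), silent = TRUE)
  if (inherits(V, "try-error")) {
    return(stats::rbinom(nrow(X_mis), 1, mean(y)))
  }
  bstar <- beta + as.vector(t(chol(V)) %*% stats::rnorm(length(beta)))
  p <- stats::plogis(as.vector(X_mis %*% bstar))
  stats::rbinom(nrow(X_mis), 1, p)
}

draw_pmm_column <- function(y, X_obs, X_mis, k = 5) {
  qrX <- qr(X_obs)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  res <- y - as.vector(X_obs %*% beta)
  df <- max(1, nrow(X_obs) - qrX$rank)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)
  Ri <- try(solve(R[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE]),
            silent = TRUE)
  bstar <- beta
  if (!inherits(Ri, "try-error")) {
    pert <- Ri %*% stats::rnorm(qrX$rank) * sqrt(sigma2)
    bstar[qrX$pivot[seq_len(qrX$rank)]] <-
      beta[qrX$pivot[seq_len(qrX$rank)]] + as.vector(pert)
  }
  pred_obs <- as.vector(X_obs %*% bstar)
  pred_mis <- as.vector(X_mis %*% bstar)
  vapply(pred_mis, function(pm) {
    donors <- order(abs(pred_obs - pm))[seq_len(min(k, length(pred_obs)))]
    y[sample(donors, 1)]
  }, numeric(1))
}

draw_categorical_column <- function(y, X_obs, X_mis) {
  boot <- sample.int(length(y), replace = TRUE)
  dat <- data.frame(.y = factor(y[boot]), X_obs[boot, -1, drop = FALSE])
  fit <- try(suppressMessages(
    nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(sample(y, nrow(X_mis), replace = TRUE))
  }
  nd <- data.frame(X_mis[, -1, drop = FALSE])
  names(nd) <- names(dat)[-1]
  p <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-level case
  levs <- levels(dat$.y)
  apply(p, 1, function(pr) sample(levs, 1, prob = pr))
}

build_design <- function(predictors) {
  if (ncol(predictors) == 0) {
    return(matrix(1, nrow(predictors), 1))
  }
  stats::model.matrix(~ ., data = predictors)
}

impute_once <- function(data, col_types, covariates, cycles,
                        predictor_sets) {
  miss <- lapply(data, is.na)
  target_cols <- names(data)[vapply(miss, any, logical(1))]
  # initial fill: random draws from the observed margin
  for (cl in target_cols) {
    obs <- data[[cl]][!miss[[cl]]]
    data[[cl]][miss[[cl]]] <- sample(obs, sum(miss[[cl]]), replace = TRUE)
  }
  for (cyc in seq_len(cycles)) {
    for (cl in target_cols) {
      m <- miss[[cl]]
      preds <- predictor_sets[[cl]]
      pred_df <- dplyr::bind_cols(
        covariates,
        data[setdiff(preds, names(covariates))]
      )
      X <- build_design(pred_df)
      y_obs <- data[[cl]][!m]
      X_obs <- X[!m, , drop = FALSE]
      X_mis <- X[m, , drop = FALSE]
      data[[cl]][m] <- switch(
        col_types[[cl]],
        binary = draw_binary_column(y_obs, X_obs, X_mis),
        categorical = draw_categorical_column(y_obs, X_obs, X_mis),
        continuous = draw_pmm_column(y_obs, X_obs, X_mis))
    }
  }
  data
}

#' Multiple imputation by chained equations
#'
#' Fills masked cells of an indicator matrix m times by chained per-column
#' conditional draws. Each column's imputation model conditions on the unit
#' covariates plus the other indicators of the same sub-domain (preserving
#' the within-scale correlation that the summative scores depend on).
#' Observed cells are never altered; deterministic given `seed`.
#'
#' @param matrix An [indicator_matrix()] with missing cells, or a data frame
#'   (then `col_types` may name `"binary"`, `"categorical"`, `"continuous"`
#'   per column; binary is inferred for 0/1 columns).
#' @param covariates Optional fully observed covariate data frame aligned
#'   with the rows.
#' @param m Number of completed datasets (default 10).
#' @param cycles Chained-equation cycles per dataset (default 10).
#' @param seed Integer seed.
#' @return An object of class `imputation_set`: list with `m`, `completed`
#'   (list of completed matrices/data frames), `col_models`, `seed`.
#' @export
mice_impute <- function(matrix, covariates = NULL, m = 10, cycles = 10,
                        seed = 1L) {
  stopifnot(m >= 1, cycles >= 1)
  is_im <- inherits(matrix, "indicator_matrix")
  data <- if (is_im) {
    tibble::as_tibble(matrix$values)
  } else {
    tibble::as_tibble(matrix)
  }
  fully_missing <- names(data)[vapply(data, function(x) all(is.na(x)),
                                      logical(1))]
  if (length(fully_missing) > 0) {
    stop("column(s) fully missing, cannot impute: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }
  col_types <- vapply(data, function(x) {
    v <- x[!is.na(x)]
    if (is.numeric(x) && all(v %in% c(0, 1))) "binary"
    else if (is.numeric(x)) "continuous"
    else "categorical"
  }, character(1))

  covariates <- if (is.null(covariates)) {
    tibble::tibble(.rows = nrow(data))
  } else {
    tibble::as_tibble(covariates)
  }
  if (anyNA(covariates)) {
    stop("imputation covariates must be fully observed", call. = FALSE)
  }

  # predictors per column: covariates + same-sub-domain siblings (for
  # indicator matrices) or all other columns (plain data frames)
  predictor_sets <- if (is_im) {
    stats::setNames(lapply(names(data), function(cl) {
      sub <- matrix$mapping$sub_domain[matrix$mapping$indicator_id == cl]
      sibs <- matrix$mapping$indicator_id[matrix$mapping$sub_domain == sub]
      c(names(covariates), setdiff(sibs, cl))
    }), names(data))
  } else {
    stats::setNames(lapply(names(data), function(cl) {
      c(names(covariates), setdiff(names(data), cl))
    }), names(data))
  }

  set.seed(as.integer(seed))
  any_missing <- anyNA(data)
  completed <- lapply(seq_len(m), function(i) {
    comp <- if (any_missing) {
      impute_once(data, col_types, covariates, cycles, predictor_sets)
    } else data
    if (is_im) {
      vals <- as.matrix(comp)
      rownames(vals) <- matrix$unit_ids
      indicator_matrix(vals, matrix$mapping, unit_ids = matrix$unit_ids,
                       unit_level = matrix$unit_level, truth = matrix$truth)
    } else comp
  })
  structure(
    list(m = m, completed = completed,
         col_models = tibble::tibble(
           column = names(col_types),
           model = dplyr::recode(unname(col_types),
                                 binary = "logistic posterior draw",
                                 categorical = "bootstrap multinomial",
                                 continuous = "predictive mean matching"),
           missing_rate = vapply(data, function(x) mean(is.na(x)),
                                 numeric(1))),
         cycles = cycles, seed = as.integer(seed)),
    class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed datasets (%d cycles)\n",
              x$m, x$cycles))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `Q_bar = mean(estimates)`; within-variance `W_bar = mean(variances)`;
#' between-variance `B = var(estimates)`; total `T = W_bar + (1 + 1/m) B`;
#' degrees of freedom `df = (m - 1) (1 + W_bar / ((1 + 1/m) B))^2`. With
#' `m = 1`, `B` is undefined and is reported as 0 with infinite df.
#'
#' @param estimates Per-imputation point estimates (length m).
#' @param variances Per-imputation squared standard errors (length m).
#' @return Tibble of class `pooled_estimate`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `m`.
#' @export
pool_estimates <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length", call. = FALSE)
  }
  m <- length(estimates)
  if (m < 1) stop("need at least one imputation", call. = FALSE)
  qbar <- mean(estimates)
  wbar <- mean(variances)
  if (m == 1) {
    out <- tibble::tibble(estimate = qbar, within_var = wbar,
                          between_var = 0, total_var = wbar, df = Inf, m = m)
  } else {
    B <- stats::var(estimates)
    total <- wbar + (1 + 1 / m) * B
    df <- if (B == 0) Inf else
      (m - 1) * (1 + wbar / ((1 + 1 / m) * B))^2
    out <- tibble::tibble(estimate = qbar, within_var = wbar,
                          between_var = B, total_var = total, df = df, m = m)
  }
  class(out) <- c("pooled_estimate", class(out))
  out
}

#' Pool per-imputation sub-domain means
#'
#' Scores every completed matrix with [score_quality()], then pools each
#' measure's aggregate mean and its naive sampling variance across
#' imputations.
#'
#' @param imputations An `imputation_set` of indicator matrices.
#' @return Tibble: `measure`, `estimate`, `total_var`, `ci_low`, `ci_high`.
#' @export
pool_scores <- function(imputations) {
  per_imp <- purrr::map(imputations$completed, function(im) {
    sc <- score_quality(im)
    agg <- summarize_quality(sc)
    agg$var <- purrr::map_dbl(agg$measure, function(ms) {
      v <- sc[[ms]]
      stats::var(v, na.rm = TRUE) / sum(!is.na(v))
    })
    agg
  })
  measures <- per_imp[[1]]$measure
  purrr::map_dfr(measures, function(ms) {
    est <- purrr::map_dbl(per_imp, ~ .x$mean_score[.x$measure == ms])
    va <- purrr::map_dbl(per_imp, ~ .x$var[.x$measure == ms])
    p <- pool_estimates(est, va)
    tcrit <- if (is.finite(p$df)) stats::qt(0.975, p$df) else
      stats::qnorm(0.975)
    tibble::tibble(measure = ms, estimate = p$estimate,
                   total_var = p$total_var,
                   ci_low = p$estimate - tcrit * sqrt(p$total_var),
                   ci_high = p$estimate + tcrit * sqrt(p$total_var))
  })
}
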