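# Subgroup score distributions and the provider-competence regression, with
# cluster-robust variance at the town level: CR1 sandwich (small-sample
# factor G/(G-1)) and a t reference distribution with G-1 degrees of freedom.

cr1_vcov <- function(fit, cluster) {
  sandwich::vcovCL(fit, cluster = cluster, type = "HC0", cadjust = TRUE)
}

#' Subgroup means with cluster-robust confidence intervals
#'
#' Per-level mean of a score with a CR1 cluster-robust standard error
#' (clusters = towns), 95% CI from a t distribution with G-1 df, and a
#' cluster-robust Wald p-value for the comparison against the reference
#' (first) level. Levels with no units are omitted with a message; a level
#' represented in fewer than 2 clusters is flagged degenerate (SE reported
#' as NA).
#'
#' @param scores Data frame with the score, the covariate and cluster labels.
#' @param score Name of the score column.
#' @param covariate Name of the grouping covariate.
#' @param cluster Name of the cluster-label column (default `"town"`).
#' @param ref Reference level; default the first observed level.
#' @return Tibble of class `subgroup_summary`: `dimension`, `level`, `n`,
#'   `n_clusters`, `mean`, `se`, `ci_low`, `ci_high`, `p_vs_ref`,
#'   `degenerate`.
#' @export
subgroup_means <- function(scores, score, covariate, cluster = "town",
                           ref = NULL) {
  stopifnot(all(c(score, covariate, cluster) %in% names(scores)))
  d <- scores[!is.na(scores[[score]]) & !is.na(scores[[covariate]]), ]
  if (anyNA(d[[cluster]])) {
    stop("every unit needs a cluster label", call. = FALSE)
  }
  all_levels <- if (is.factor(scores[[covariate]]))
    levels(scores[[covariate]]) else unique(as.character(d[[covariate]]))
  empty <- setdiff(all_levels, unique(as.character(d[[covariate]])))
  if (length(empty) > 0) {
    message("omitting level(s) with no observations: ",
            paste(empty, collapse = ", "))
    all_levels <- setdiff(all_levels, empty)
  }
  if (is.null(ref)) ref <- all_levels[1]
  lev <- factor(as.character(d[[covariate]]),
                levels = c(ref, setdiff(all_levels, ref)))

  y <- d[[score]]
  cl <- as.character(d[[cluster]])

  # cell means with CR1 SEs via a no-intercept regression on the levels
  fit <- stats::lm(y ~ 0 + lev)
  V <- cr1_vcov(fit, cl)
  G <- dplyr::n_distinct(cl)
  tcrit <- stats::qt(0.975, df = G - 1)

  per_level <- purrr::map_dfr(seq_along(levels(lev)), function(i) {
    l <- levels(lev)[i]
    in_l <- lev == l
    g_l <- dplyr::n_distinct(cl[in_l])
    se <- sqrt(V[i, i])
    degenerate <- g_l < 2 || se == 0
    tibble::tibble(
      dimension = covariate, level = l, n = sum(in_l), n_clusters = g_l,
      mean = unname(stats::coef(fit)[i]),
      se = if (degenerate) NA_real_ else se,
      ci_low = if (degenerate) NA_real_ else
        unname(stats::coef(fit)[i]) - tcrit * se,
      ci_high = if (degenerate) NA_real_ else
        unname(stats::coef(fit)[i]) + tcrit * se,
      degenerate = degenerate
    )
  })

  # pairwise comparison vs reference, cluster-robust Wald t with G-1 df
  fit2 <- stats::lm(y ~ lev)
  V2 <- cr1_vcov(fit2, cl)
  ct <- lmtest::coeftest(fit2, vcov. = V2, df = G - 1)
  pvals <- c(NA_real_, ct[-1, 4])
  per_level$p_vs_ref <- pvals[seq_len(nrow(per_level))]
  class(per_level) <- c("subgroup_summary", class(per_level))
  per_level
}

#' Cluster-robust two-group comparison of a score
#'
#' Wald test of the mean difference between two covariate levels with CR1
#' cluster-robust variance and a t reference with G-1 df. Identical score
#' vectors give p = 1; a level present in fewer than 2 clusters declines the
#' test with a reason.
#'
#' @inheritParams subgroup_means
#' @param levels The two levels to compare (default: first two observed).
#' @return Tibble: `level_a`, `level_b`, `diff`, `se`, `statistic`, `df`,
#'   `p_value` (or a declined row with `reason`).
#' @export
subgroup_test <- function(scores, score, covariate, cluster = "town",
                          levels = NULL) {
  d <- scores[!is.na(scores[[score]]) & !is.na(scores[[covariate]]), ]
  lv <- unique(as.character(d[[covariate]]))
  if (is.null(levels)) levels <- lv[1:2]
  d <- d[as.character(d[[covariate]]) %in% levels, ]
  cl <- as.character(d[[cluster]])
  f <- factor(as.character(d[[covariate]]), levels = levels)
  for (l in levels) {
    if (dplyr::n_distinct(cl[f == l]) < 2) {
      return(tibble::tibble(level_a = levels[1], level_b = levels[2],
                            diff = NA_real_, se = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_,
                            reason = paste0("level '", l,
                                            "' in < 2 clusters")))
    }
  }
  y <- d[[score]]
  fit <- stats::lm(y ~ f)
  est <- unname(stats::coef(fit)[2])
  G <- dplyr::n_distinct(cl)
  # a difference at floating-point noise level is an exact tie
  if (abs(est) < .Machine$double.eps^0.5 * max(1, stats::sd(y))) est <- 0
  V <- cr1_vcov(fit, cl)
  se <- sqrt(V[2, 2])
  stat <- if (est == 0) 0 else est / se
  p <- 2 * stats::pt(-abs(stat), df = G - 1)
  tibble::tibble(level_a = levels[1], level_b = levels[2], diff = est,
                 se = se, statistic = stat, df = G - 1, p_value = p,
                 reason = NA_character_)
}

#' Joint Wald test across all levels of a covariate
#'
#' Cluster-robust Wald chi-square-style F test that all non-reference level
#' effects are zero, with (L-1, G-1) reference.
#'
#' @inheritParams subgroup_means
#' @return Tibble: `dimension`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
subgroup_joint_test <- function(scores, score, covariate, cluster = "town") {
  d <- scores[!is.na(scores[[score]]) & !is.na(scores[[covariate]]), ]
  cl <- as.character(d[[cluster]])
  f <- factor(as.character(d[[covariate]]))
  fit <- stats::lm(d[[score]] ~ f)
  V <- cr1_vcov(fit, cl)
  idx <- seq(2, length(stats::coef(fit)))
  beta <- stats::coef(fit)[idx]
  W <- as.vector(t(beta) %*% solve(V[idx, idx]) %*% beta) / length(idx)
  G <- dplyr::n_distinct(cl)
  tibble::tibble(dimension = covariate, statistic = W,
                 df1 = length(idx), df2 = G - 1,
                 p_value = stats::pf(W, length(idx), G - 1,
                                     lower.tail = FALSE))
}

provider_model_terms <- function(model_id) {
  base <- "facility_level"
  switch(model_id,
         model1 = base,
         model2 = c(base, "gender", "education"),
         model3 = c(base, "gender", "education", "permanent_post",
                    "passed_licensing_exam", "job_title",
                    "administrative_role", "job_satisfaction"),
         stop("model_id must be model1, model2 or model3", call. = FALSE))
}

#' Provider-competence regression
#'
#' OLS of log provider competence on provider characteristics, in three
#' nested specifications: model1 = workplace only; model2 adds gender and
#' education; model3 adds permanent post, licensing exam, job title,
#' administrative role and job satisfaction. Reference levels: village
#' clinic, female, college-or-above, none/not-satisfied for the binaries.
#' Standard errors are CR1 cluster-robust at the town level with t(G-1)
#' inference; facility-level response-rate weights (inverse response rate)
#' are optional. Perfectly collinear terms are dropped with a warning.
#'
#' @param providers Provider table (see [generate_providers()]) with cluster
#'   labels and characteristics.
#' @param competence Per-provider quality score strictly in (0, 1), aligned
#'   with `providers` rows (e.g. `rasch_scores()$score`).
#' @param model_id `"model1"`, `"model2"` or `"model3"`.
#' @param cluster Cluster column name (default `"town"`).
#' @param weights Optional `"response_rate"` to weight by inverse facility
#'   response rate, or a numeric vector.
#' @param response_rates Named facility-level response rates used when
#'   `weights = "response_rate"`.
#' @return Object of class `phc_regression`: tidy coefficient table plus fit
#'   metadata.
#' @export
fit_provider_regression <- function(providers, competence,
                                    model_id = "model3", cluster = "town",
                                    weights = NULL,
                                    response_rates = c(
                                      "village clinic" = 0.899,
                                      "township health centre" = 0.842,
                                      "county hospital" = 0.940)) {
  stopifnot(length(competence) == nrow(providers))
  if (any(is.na(competence)) || any(competence <= 0 | competence >= 1)) {
    stop("competence scores must lie strictly in (0, 1)", call. = FALSE)
  }
  terms <- provider_model_terms(model_id)
  d <- tibble::as_tibble(providers)[, c(terms, cluster)]
  d$log_competence <- log(competence)
  d$facility_level <- factor(d$facility_level,
                             levels = c("village clinic",
                                        "township health centre",
                                        "county hospital"))
  if ("gender" %in% terms) {
    d$gender <- factor(d$gender, levels = c("female", "male"))
  }
  if ("education" %in% terms) {
    d$education <- factor(d$education,
                          levels = c("college or above",
                                     "high school or below"))
  }
  if ("job_satisfaction" %in% terms) {
    d$job_satisfaction <- factor(d$job_satisfaction,
                                 levels = c("not satisfied", "satisfied"))
  }
  w <- NULL
  if (identical(weights, "response_rate")) {
    w <- 1 / unname(response_rates[as.character(providers$facility_level)])
  } else if (is.numeric(weights)) {
    w <- weights
  }
  fml <- stats::as.formula(paste("log_competence ~",
                                 paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d, weights = w)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0) {
    warning("dropped perfectly collinear term(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
  }
  cl <- as.character(d[[cluster]])
  G <- dplyr::n_distinct(cl)
  keep <- !is.na(stats::coef(fit))
  V <- cr1_vcov(fit, cl)
  beta <- stats::coef(fit)[keep]
  se <- sqrt(diag(V))
  tcrit <- stats::qt(0.975, df = G - 1)
  tab <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    ci_low = unname(beta - tcrit * se),
    ci_high = unname(beta + tcrit * se),
    statistic = unname(beta / se),
    p_value = unname(2 * stats::pt(-abs(beta / se), df = G - 1))
  )
  structure(
    list(terms = tab, model_id = model_id, cluster_level = cluster,
         n = nrow(d), n_clusters = G, weighted = !is.null(w),
         dropped_terms = aliased, fit = fit,
         small_g_caveat = G < 30),
    class = "phc_regression")
}

#' @export
print.phc_regression <- function(x, ...) {
  cat(sprintf(
    "<phc_regression> %s: log(competence), n = %d, %d clusters%s%s\n",
    x$model_id, x$n, x$n_clusters,
    if (x$weighted) ", response-rate weighted" else "",
    if (x$small_g_caveat) " [few clusters: t(G-1) inference]" else ""))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.phc_regression <- function(x, ...) x$terms

#' @export
glance.phc_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(model_id = x$model_id, n = x$n, n_clusters = x$n_clusters,
                 r_squared = s$r.squared, sigma = s$sigma,
                 weighted = x$weighted,
                 n_dropped_terms = length(x$dropped_terms))
}

#' Plot subgroup score distributions
#'
#' Point-range plot of subgroup means with their cluster-robust 95% CIs,
#' faceted by covariate dimension.
#'
#' @param summaries A `subgroup_summary` tibble (rows from one or more calls
#'   to [subgroup_means()], row-bound).
#' @return A ggplot object.
#' @export
plot_subgroups <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$mean, y = .data$level)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::geom_vline(xintercept = 0.7, linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dimension),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "quality score (95% cluster-robust CI)", y = NULL) +
    ggplot2::theme_minimal()
}
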