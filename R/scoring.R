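# Arithmetic-mean quality scores on [0, 1]: per-unit sub-domain scores (mean
# of non-missing indicators), equal-weight domain scores, and the favourable
# flag (strictly above 0.7).

#' Favourability threshold flag
#'
#' Quality scores strictly above 0.7 are considered favourable (optimal);
#' "above" is read strictly, so exactly 0.7 is not favourable.
#'
#' @param score Numeric vector of scores in `[0, 1]` (NA allowed).
#' @return Logical vector.
#' @export
favourable <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) {
    stop("scores must lie in [0, 1]; got ",
         paste(utils::head(score[bad], 3), collapse = ", "), call. = FALSE)
  }
  score > 0.7
}

#' Per-unit sub-domain score by the arithmetic mean
#'
#' For each unit, the mean of its non-missing indicator values in the
#' sub-domain. A unit with every cell missing gets `NA` (flagged as
#' undefined), never 0.
#'
#' @param matrix An [indicator_matrix()].
#' @param sub_domain Sub-domain name (one of the 13).
#' @return Named numeric vector of per-unit scores.
#' @export
subdomain_score <- function(matrix, sub_domain) {
  if (!sub_domain %in% matrix$mapping$sub_domain) {
    stop("sub-domain not present in matrix: ", sub_domain, call. = FALSE)
  }
  keep <- matrix$mapping$sub_domain == sub_domain
  vals <- matrix$values[, keep, drop = FALSE]
  score <- rowMeans(vals, na.rm = TRUE)
  score[is.nan(score)] <- NA_real_
  stats::setNames(score, matrix$unit_ids)
}

#' Equal-weight domain score from sub-domain scores
#'
#' The domain score is the equal-weight arithmetic mean of its sub-domain
#' scores; with the reported PHC-system sub-domain levels
#' `{0.887, 0.781, 0.489, 0.714}` this reproduces the 0.718 domain total, and
#' with the user-experience levels `{0.933, 0.657, 0.936, 0.382}` it
#' reproduces 0.727 (3 d.p.). Undefined (`NA`) constituent scores make the
#' domain score undefined.
#'
#' @param subdomain_scores Numeric vector (aggregate) or matrix/data frame
#'   (per-unit, sub-domains in columns) of sub-domain scores.
#' @return Numeric scalar or per-unit vector.
#' @export
domain_score <- function(subdomain_scores) {
  if (is.data.frame(subdomain_scores)) {
    subdomain_scores <- as.matrix(subdomain_scores)
  }
  if (is.matrix(subdomain_scores)) {
    if (ncol(subdomain_scores) == 0) {
      stop("empty sub-domain set", call. = FALSE)
    }
    return(rowMeans(subdomain_scores))
  }
  if (length(subdomain_scores) == 0) {
    stop("empty sub-domain set", call. = FALSE)
  }
  mean(subdomain_scores)
}

#' Per-unit quality score table
#'
#' Computes every mean-scored sub-domain present in the matrix, plus the
#' domain scores whose constituent sub-domains are all present: the PHC
#' system and user experience domains get equal-weight means of their
#' sub-domain scores; clinical care is reported by sub-domains only (its
#' parts come from disparate sources and instruments).
#'
#' @param matrix An [indicator_matrix()].
#' @param sub_domains Sub-domains to score; defaults to the mean-scored ones
#'   present in the matrix.
#' @return A tibble of class `phc_scores`: `unit_id` then one column per
#'   sub-domain/domain score.
#' @export
score_quality <- function(matrix, sub_domains = NULL) {
  present <- unique(matrix$mapping$sub_domain)
  if (is.null(sub_domains)) {
    sub_domains <- intersect(mean_scored_subdomains(), present)
  }
  out <- tibble::tibble(unit_id = matrix$unit_ids)
  for (sd in sub_domains) {
    out[[sd]] <- unname(subdomain_score(matrix, sd))
  }
  for (dom in c("PHC system", "user experience")) {
    subs <- phc_domains()[[dom]]
    if (all(subs %in% names(out))) {
      out[[dom]] <- domain_score(out[, subs])
    }
  }
  class(out) <- c("phc_scores", class(out))
  out
}

#' Aggregate quality summary
#'
#' Sample means of per-unit scores (over units with a defined score), with
#' the number of contributing units and the favourability flag.
#'
#' @param scores A `phc_scores` tibble from [score_quality()], or any tibble
#'   of per-unit scores with a `unit_id` column.
#' @return Tibble with `measure`, `domain`, `n`, `mean_score`, `favourable`.
#' @export
summarize_quality <- function(scores) {
  cols <- setdiff(names(scores), "unit_id")
  purrr::map_dfr(cols, function(cl) {
    v <- scores[[cl]]
    tibble::tibble(
      measure = cl,
      domain = if (cl %in% phc_subdomains()) subdomain_to_domain(cl) else cl,
      n = sum(!is.na(v)),
      mean_score = mean(v, na.rm = TRUE),
      favourable = favourable(mean(v, na.rm = TRUE))
    )
  })
}

#' @export
glance.phc_scores <- function(x, ...) {
  agg <- summarize_quality(x)
  tibble::tibble(
    n_units = nrow(x),
    n_measures = nrow(agg),
    n_favourable = sum(agg$favourable),
    min_score = min(agg$mean_score),
    max_score = max(agg$mean_score)
  )
}

#' Plot aggregate quality scores
#'
#' Bar chart of aggregate sub-domain (and domain) scores grouped by domain,
#' with the 0.7 favourability threshold marked.
#'
#' @param object A `phc_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phc_scores <- function(object, ...) {
  agg <- summarize_quality(object)
  agg$measure <- factor(agg$measure, levels = rev(agg$measure))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$mean_score, y = .data$measure,
                                    fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.7, linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "quality score (0 = lowest, 1 = highest)", y = NULL,
                  fill = "domain",
                  caption = "dashed line: favourability threshold 0.7") +
    ggplot2::theme_minimal()
}
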