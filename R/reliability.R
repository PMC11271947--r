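# Internal-consistency reliability of summative scales via Cronbach's alpha.

#' Cronbach's alpha for a summative scale
#'
#' `alpha = k/(k-1) * (1 - sum var(item_i) / var(total))`, with sample
#' variances (denominator n-1) computed on listwise-complete units. Computed
#' pre-imputation by default in the pipeline, with the complete-case n
#' reported.
#'
#' @param matrix An [indicator_matrix()] (optionally restricted via
#'   `domain`/`sub_domains`) or a plain numeric matrix, items in columns.
#' @param domain Optional domain name; keeps that domain's columns.
#' @param sub_domains Optional sub-domain names; keeps those columns.
#' @return Tibble of class `reliability_result`: `domain`, `alpha`,
#'   `k_items`, `n_units`.
#' @export
cronbach_alpha <- function(matrix, domain = NULL, sub_domains = NULL) {
  label <- domain %||% "scale"
  if (inherits(matrix, "indicator_matrix")) {
    keep <- rep(TRUE, ncol(matrix$values))
    if (!is.null(domain)) keep <- keep & matrix$mapping$domain == domain
    if (!is.null(sub_domains)) {
      keep <- keep & matrix$mapping$sub_domain %in% sub_domains
    }
    if (!any(keep)) stop("no items selected", call. = FALSE)
    X <- matrix$values[, keep, drop = FALSE]
  } else {
    X <- as.matrix(matrix)
  }
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  n <- nrow(X)
  if (k < 2) stop("Cronbach's alpha needs >= 2 items", call. = FALSE)
  if (n < 2) stop("fewer than 2 complete cases", call. = FALSE)
  item_var <- apply(X, 2, stats::var)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0 || all(item_var == 0)) {
    stop("zero total-score variance: reliability undefined", call. = FALSE)
  }
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  out <- tibble::tibble(domain = label, alpha = alpha,
                        k_items = k, n_units = n)
  class(out) <- c("reliability_result", class(out))
  out
}

#' Reliability of the summative quality domains
#'
#' Runs [cronbach_alpha()] for each requested domain of the matrix
#' (by default the summative constructs: the PHC-system and user-experience
#' domains on patient matrices, provider competence on provider matrices).
#'
#' @param matrix An [indicator_matrix()].
#' @param domains Domains to assess; defaults by unit level.
#' @return A `reliability_result` tibble, one row per domain.
#' @export
domain_reliability <- function(matrix, domains = NULL) {
  if (is.null(domains)) {
    domains <- switch(matrix$unit_level,
                      patient = c("PHC system", "user experience"),
                      provider = "clinical care",
                      chart = "clinical care")
  }
  out <- purrr::map_dfr(domains, function(d) {
    res <- try(cronbach_alpha(matrix, domain = d), silent = TRUE)
    if (inherits(res, "try-error")) {
      tibble::tibble(domain = d, alpha = NA_real_, k_items = NA_integer_,
                     n_units = NA_integer_)
    } else res
  })
  class(out) <- c("reliability_result", class(out))
  out
}
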