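# IndicatorMatrix: units x binary indicators with a missingness mask and the
# indicator -> sub-domain -> domain mapping. Missing cells are NA in `values`;
# when missingness was injected synthetically the pre-masking truth is kept in
# the `truth` attribute for recovery testing.

#' Construct an indicator matrix
#'
#' @param values Numeric matrix of 0/1 with `NA` for missing cells; columns
#'   named by indicator id.
#' @param mapping Tibble with columns `indicator_id`, `sub_domain`, `domain`
#'   covering every column of `values`.
#' @param unit_ids Unit identifiers (row names); patients, providers or charts.
#' @param unit_level One of `"patient"`, `"provider"`, `"chart"`.
#' @param truth Optional pre-masking value matrix (same shape), kept for
#'   recovery testing after synthetic missingness injection.
#' @return An object of class `indicator_matrix`.
#' @export
indicator_matrix <- function(values, mapping, unit_ids = rownames(values),
                             unit_level = c("patient", "provider", "chart"),
                             truth = NULL) {
  unit_level <- match.arg(unit_level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obs <- values[!is.na(values)]
  if (length(obs) > 0 && !all(obs %in% c(0, 1))) {
    stop("observed indicator values must be 0 or 1", call. = FALSE)
  }
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(nrow(values)))
  mapping <- tibble::as_tibble(mapping)
  uncovered <- setdiff(colnames(values), mapping$indicator_id)
  if (length(uncovered) > 0) {
    stop("mapping does not cover columns: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  mapping <- mapping[match(colnames(values), mapping$indicator_id), ]
  rownames(values) <- unit_ids
  structure(
    list(values = values, mapping = mapping,
         unit_ids = as.character(unit_ids), unit_level = unit_level,
         truth = truth),
    class = "indicator_matrix"
  )
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf(
    "<indicator_matrix> %d %ss x %d indicators (%d sub-domains, %.1f%% missing)\n",
    nrow(x$values), x$unit_level, ncol(x$values),
    dplyr::n_distinct(x$mapping$sub_domain),
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

#' Missingness mask of an indicator matrix
#'
#' @param matrix An `indicator_matrix`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(matrix) is.na(matrix$values)

#' Restrict an indicator matrix to selected sub-domains
#'
#' @param matrix An `indicator_matrix`.
#' @param sub_domains Character vector of sub-domain names.
#' @return An `indicator_matrix` with only the matching columns.
#' @export
restrict_subdomain <- function(matrix, sub_domains) {
  unknown <- setdiff(sub_domains, phc_subdomains())
  if (length(unknown) > 0) {
    stop("unknown sub-domain(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- matrix$mapping$sub_domain %in% sub_domains
  if (!any(keep)) {
    stop("no indicators mapped to: ", paste(sub_domains, collapse = ", "),
         call. = FALSE)
  }
  indicator_matrix(matrix$values[, keep, drop = FALSE],
                   matrix$mapping[keep, ],
                   unit_ids = matrix$unit_ids,
                   unit_level = matrix$unit_level,
                   truth = if (!is.null(matrix$truth))
                     matrix$truth[, keep, drop = FALSE])
}

#' Tidy an indicator matrix into long form
#'
#' @param x An `indicator_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (unit, indicator) cell: `unit_id`,
#'   `indicator_id`, `sub_domain`, `domain`, `value` (NA if missing).
#' @export
tidy.indicator_matrix <- function(x, ...) {
  tibble::tibble(
    unit_id = rep(x$unit_ids, times = ncol(x$values)),
    indicator_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  ) |>
    dplyr::left_join(
      x$mapping[, c("indicator_id", "sub_domain", "domain")],
      by = "indicator_id"
    )
}

apply_rule <- function(raw, rule_type, rule_arg, rule_dir) {
  out <- switch(
    rule_type,
    identity = {
      v <- suppressWarnings(as.numeric(raw))
      bad <- !is.na(v) & !(v %in% c(0, 1))
      if (any(bad)) {
        stop("identity rule saw non-binary values: ",
             paste(utils::head(unique(v[bad]), 3), collapse = ", "),
             call. = FALSE)
      }
      v
    },
    set = {
      members <- trimws(strsplit(rule_arg, ",")[[1]])
      ifelse(is.na(raw) | raw == "", NA_real_,
             as.numeric(as.character(raw) %in% members))
    },
    threshold = {
      v <- suppressWarnings(as.numeric(raw))
      cut <- as.numeric(rule_arg)
      if (identical(rule_dir, "le")) as.numeric(v <= cut)
      else as.numeric(v >= cut)
    },
    stop("unknown rule type: ", rule_type, call. = FALSE)
  )
  out
}

#' Binarize raw records into an indicator matrix
#'
#' Applies each catalogue entry's binarization rule to the matching column of
#' `records`. Unanswered raw values (NA or empty string) become masked cells,
#' never silently 0. Catalogue indicators whose source column is absent from
#' `records` can either raise an error (default) or be kept as all-missing
#' columns (`allow_absent = TRUE`), so that a single catalogue can be applied
#' source-by-source.
#'
#' @param records Data frame of raw responses, one row per unit, with an id
#'   column (first column ending in `_id` by default).
#' @param catalog A `phc_catalog` (see [load_catalog()]).
#' @param unit_level `"patient"`, `"provider"` or `"chart"`.
#' @param id_col Name of the unit-id column; guessed if `NULL`.
#' @param allow_absent Keep catalogue indicators missing from `records` as
#'   all-NA columns instead of erroring.
#' @return An `indicator_matrix`.
#' @export
binarize <- function(records, catalog,
                     unit_level = c("patient", "provider", "chart"),
                     id_col = NULL, allow_absent = FALSE) {
  unit_level <- match.arg(unit_level)
  records <- tibble::as_tibble(records)
  if (is.null(id_col)) {
    id_col <- grep("_id$", names(records), value = TRUE)[1]
    if (is.na(id_col)) stop("no unit id column found", call. = FALSE)
  }
  absent <- setdiff(catalog$indicator_id, names(records))
  if (length(absent) > 0 && !allow_absent) {
    stop("catalogue indicators absent from records: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  cols <- lapply(seq_len(nrow(catalog)), function(i) {
    id <- catalog$indicator_id[i]
    if (id %in% absent) return(rep(NA_real_, n))
    raw <- records[[id]]
    if (is.character(raw)) raw[raw == ""] <- NA_character_
    apply_rule(raw, catalog$rule_type[i], catalog$rule_arg[i],
               catalog$rule_dir[i])
  })
  values <- do.call(cbind, cols)
  colnames(values) <- catalog$indicator_id
  indicator_matrix(values, catalog, unit_ids = records[[id_col]],
                   unit_level = unit_level)
}

#' Write / read an indicator matrix as delimited text
#'
#' The matrix is serialized as a headered CSV (missing cells as empty fields)
#' plus a sidecar `<path>.mapping.csv` holding the indicator -> sub-domain ->
#' domain mapping; the pair round-trips losslessly through
#' [read_indicator_matrix()].
#'
#' @param matrix An `indicator_matrix`.
#' @param path Output CSV path.
#' @return `path` invisibly, or the re-read `indicator_matrix`.
#' @export
write_indicator_matrix <- function(matrix, path) {
  tab <- tibble::as_tibble(matrix$values)
  tab <- dplyr::bind_cols(
    tibble::tibble(unit_id = matrix$unit_ids,
                   unit_level = matrix$unit_level), tab)
  readr::write_csv(tab, path, na = "")
  readr::write_csv(matrix$mapping, paste0(path, ".mapping.csv"), na = "")
  invisible(path)
}

#' @rdname write_indicator_matrix
#' @export
read_indicator_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           unit_id = readr::col_character(),
                           unit_level = readr::col_character(),
                           .default = readr::col_double()))
  mapping <- readr::read_csv(paste0(path, ".mapping.csv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               .default = readr::col_character()))
  values <- as.matrix(tab[, setdiff(names(tab), c("unit_id", "unit_level"))])
  indicator_matrix(values, mapping, unit_ids = tab$unit_id,
                   unit_level = tab$unit_level[1])
}
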