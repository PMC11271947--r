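# Indicator catalogue: the three-domain / thirteen-sub-domain framework and the
# binarization rule attached to each indicator.

#' Quality framework constants
#'
#' The framework groups binary quality indicators into 13 sub-domains under
#' 3 domains. `phc_domains()` returns the domain -> sub-domain map;
#' `phc_subdomains()` returns the 13 sub-domain names.
#'
#' @return `phc_domains()`: a named list of character vectors.
#'   `phc_subdomains()`: a character vector of length 13.
#' @export
phc_domains <- function() {
  list(
    "PHC system" = c("accessibility", "comprehensiveness", "continuity",
                     "coordination"),
    "clinical care" = c("assessment", "diagnosis", "treatment",
                        "disease management", "provider competence"),
    "user experience" = c("shared decision-making", "family-centeredness",
                          "information sharing",
                          "respect for patient preferences")
  )
}

#' @rdname phc_domains
#' @export
phc_subdomains <- function() unname(unlist(phc_domains()))

#' @rdname phc_domains
#' @export
phc_sources <- function() {
  c("patient survey", "provider survey", "chart abstraction", "registry")
}

# Sub-domains scored by the arithmetic mean vs. by the Rasch model.
mean_scored_subdomains <- function() {
  c("accessibility", "comprehensiveness", "continuity", "coordination",
    "disease management", "shared decision-making", "family-centeredness",
    "information sharing", "respect for patient preferences")
}

rasch_scored_subdomains <- function() {
  c("assessment", "diagnosis", "treatment", "provider competence")
}

subdomain_to_domain <- function(sub_domain) {
  map <- phc_domains()
  lut <- stats::setNames(
    rep(names(map), lengths(map)), unlist(map)
  )
  unname(lut[sub_domain])
}

#' Load and validate an indicator catalogue
#'
#' An indicator catalogue lists every binary quality indicator, the sub-domain
#' and domain it belongs to, the data source it is collected from, and the
#' binarization rule that turns the raw response into 0/1. Catalogues are
#' configuration, not code: the bundled default (see [default_catalog()]) is a
#' documented stand-in instrument, and users can supply their own as YAML,
#' JSON, or a data frame.
#'
#' Rules are one of:
#' * `identity` — raw value already 0/1;
#' * `set` — 1 iff the raw value is in `rule_arg` (comma-separated categories);
#' * `threshold` — 1 iff the numeric raw value is `>=` (`rule_dir = "ge"`) or
#'   `<=` (`rule_dir = "le"`) the numeric `rule_arg`.
#'
#' @param document Path to a YAML/JSON catalogue file, or a data frame with
#'   columns `indicator_id`, `sub_domain`, `source`, `rule_type` and
#'   optionally `rule_arg`, `rule_dir`.
#' @return A tibble of class `phc_catalog` with one row per indicator and a
#'   `domain` column derived from the framework map.
#' @export
load_catalog <- function(document) {
  if (is.character(document) && length(document) == 1) {
    if (!file.exists(document)) {
      stop("catalogue file not found: ", document, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(document))
    entries <- if (ext == "json") {
      jsonlite::fromJSON(document, simplifyDataFrame = TRUE)
    } else {
      raw <- yaml::read_yaml(document)
      dplyr::bind_rows(lapply(raw$indicators, tibble::as_tibble))
    }
    entries <- tibble::as_tibble(entries)
  } else if (is.data.frame(document)) {
    entries <- tibble::as_tibble(document)
  } else {
    stop("catalogue document must be a file path or a data frame",
         call. = FALSE)
  }

  required <- c("indicator_id", "sub_domain", "source", "rule_type")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"rule_arg" %in% names(entries)) entries$rule_arg <- NA_character_
  if (!"rule_dir" %in% names(entries)) entries$rule_dir <- NA_character_
  entries$rule_arg <- as.character(entries$rule_arg)

  bad_sub <- setdiff(unique(entries$sub_domain), phc_subdomains())
  if (length(bad_sub) > 0) {
    stop("unknown sub-domain(s) in catalogue: ",
         paste(bad_sub, collapse = ", "),
         " (offending entries: ",
         paste(entries$indicator_id[entries$sub_domain %in% bad_sub],
               collapse = ", "), ")", call. = FALSE)
  }
  dup <- entries$indicator_id[duplicated(entries$indicator_id)]
  if (length(dup) > 0) {
    stop("duplicate indicator_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_src <- setdiff(unique(entries$source), phc_sources())
  if (length(bad_src) > 0) {
    stop("unknown source(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  bad_rule <- setdiff(unique(entries$rule_type),
                      c("identity", "set", "threshold"))
  if (length(bad_rule) > 0) {
    stop("unknown rule_type(s): ", paste(bad_rule, collapse = ", "),
         call. = FALSE)
  }
  thr <- entries$rule_type == "threshold"
  if (any(thr) && anyNA(suppressWarnings(as.numeric(entries$rule_arg[thr])))) {
    stop("threshold rules need a numeric rule_arg", call. = FALSE)
  }

  entries$domain <- subdomain_to_domain(entries$sub_domain)
  entries$method <- ifelse(entries$sub_domain %in% rasch_scored_subdomains(),
                           "rasch", "mean")
  out <- entries[, c("indicator_id", "sub_domain", "domain", "source",
                     "method", "rule_type", "rule_arg", "rule_dir")]
  class(out) <- c("phc_catalog", class(out))
  out
}

#' The bundled default indicator catalogue
#'
#' A stand-in instrument with 4-12 indicators per sub-domain, named after the
#' framework's definitional clauses (e.g. continuity covers relational,
#' informational and management continuity; disease management includes a
#' registry-derived follow-up-frequency indicator with threshold 4
#' visits/year). It is explicitly a configurable stand-in, not a
#' reconstruction of any fielded questionnaire.
#'
#' @return A `phc_catalog` tibble (70 indicators across all 13 sub-domains).
#' @export
default_catalog <- function() {
  ind <- function(ids, sub, src, type = "identity", arg = NA, dir = NA) {
    tibble::tibble(indicator_id = ids, sub_domain = sub, source = src,
                   rule_type = type, rule_arg = as.character(arg),
                   rule_dir = as.character(dir))
  }
  pat <- "patient survey"
  entries <- dplyr::bind_rows(
    ind(c("acc_travel_under_30min", "acc_cost_affordable",
          "acc_drugs_available", "acc_appointment_easy",
          "acc_service_hours_adequate"), "accessibility", pat),
    ind(c("comp_health_education", "comp_preventive_care",
          "comp_common_disease_treatment", "comp_referral_available",
          "comp_health_management", "comp_vaccination_services"),
        "comprehensiveness", pat),
    ind(c("cont_usual_provider", "cont_provider_knows_history",
          "cont_records_transferred", "cont_followup_same_provider",
          "cont_longterm_relationship"), "continuity", pat),
    ind(c("coord_family_doctor_contract", "coord_health_record_established",
          "coord_info_shared_across_facilities", "coord_referral_coordinated"),
        "coordination", pat),
    ind(c("dm_personal_risk_assessed", "dm_prevention_plan",
          "dm_followup_adequate_survey"), "disease management", pat),
    ind("dm_registry_followups_per_year", "disease management", "registry",
        type = "threshold", arg = 4, dir = "ge"),
    ind(c("sdm_opinion_included", "sdm_options_discussed",
          "sdm_plan_agreed"), "shared decision-making", pat),
    ind("sdm_treatment_choice_offered", "shared decision-making", pat,
        type = "set", arg = "yes"),
    ind(c("fam_history_inquired", "fam_member_health_asked",
          "fam_involved_in_plan", "fam_support_discussed"),
        "family-centeredness", pat),
    ind("info_records_access", "information sharing", pat,
        type = "set", arg = "yes"),
    ind(c("info_results_explained", "info_medication_explained",
          "info_condition_explained"), "information sharing", pat),
    ind(c("resp_privacy_respected", "resp_time_for_questions",
          "resp_choices_valued", "resp_treated_with_dignity"),
        "respect for patient preferences", pat),
    ind(sprintf("vig_%02d", 1:12), "provider competence", "provider survey"),
    ind(sprintf("chart_assess_%02d", 1:6), "assessment", "chart abstraction"),
    ind(sprintf("chart_diag_%02d", 1:6), "diagnosis", "chart abstraction"),
    ind(sprintf("chart_treat_%02d", 1:6), "treatment", "chart abstraction")
  )
  load_catalog(entries)
}

#' Write a catalogue to YAML
#'
#' @param catalog A `phc_catalog` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    e <- as.list(catalog[i, c("indicator_id", "sub_domain", "source",
                              "rule_type", "rule_arg", "rule_dir")])
    e[!vapply(e, function(x) is.na(x) || identical(x, "NA"), logical(1))]
  })
  yaml::write_yaml(list(indicators = rows), path)
  invisible(path)
}
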