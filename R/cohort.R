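# Turning report sets into the binary indicator dataset used by all
# statistics: one row per report, 0/1 event, drug-exposure and cancer-site
# columns, plus sex/age/year covariates.

#' Define a named set of matching terms
#'
#' Term sets play the role of the MedDRA preferred-term lists that define a
#' case (e.g. the hyponatremia PTs) or an underlying disease (e.g. lung
#' cancer). Matching is exact at the whole-term level — no substring
#' matching, so "hyponatraemic coma" does not match a set listing only
#' "Hyponatraemia" — and case-insensitive by default.
#'
#' @param name Label for the set.
#' @param terms Non-empty character vector of terms.
#' @param match_mode `"ci_exact"` (case-insensitive exact, default) or
#'   `"exact"`.
#' @return An object of class `term_set`.
#' @export
term_set <- function(name, terms, match_mode = c("ci_exact", "exact")) {
  match_mode <- match.arg(match_mode)
  terms <- trimws(as.character(terms))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) pv_error("term set must contain at least one term",
                               "pvsignal_config_error")
  structure(list(name = name, terms = unique(terms), match_mode = match_mode),
            class = "term_set")
}

.as_term_set <- function(x, name = "terms") {
  if (inherits(x, "term_set")) x else term_set(name, x)
}

.match_terms <- function(x, ts) {
  if (ts$match_mode == "ci_exact")
    tolower(trimws(x)) %in% tolower(ts$terms)
  else trimws(x) %in% ts$terms
}

#' Normalize a drug name
#'
#' Lower-cases, trims, collapses internal whitespace, and optionally maps
#' synonyms to a canonical name.
#'
#' @param x Character vector of drug names.
#' @param synonyms Optional named character vector `c(synonym = canonical)`;
#'   applied after case folding.
#' @return Character vector of normalized names.
#' @export
normalize_drug <- function(x, synonyms = NULL) {
  x <- gsub("[[:space:]]+", " ", tolower(trimws(x)))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(trimws(names(synonyms)))
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- tolower(trimws(unname(synonyms[hit[!is.na(hit)]])))
  }
  x
}

#' Flag reports mentioning a target adverse event
#'
#' @param records A `report_set`.
#' @param event_terms A [term_set()] (or character vector) of event preferred
#'   terms.
#' @return Integer 0/1 vector aligned with the reports in `records`.
#' @export
flag_event <- function(records, event_terms) {
  stopifnot(inherits(records, "report_set"))
  ts <- .as_term_set(event_terms, "event")
  hit_ids <- records$events$case_id[.match_terms(records$events$term, ts)]
  as.integer(records$demo$case_id %in% hit_ids)
}

#' Flag reports with suspected exposure to a drug
#'
#' Only drug entries carrying the "suspected" involvement code count as
#' exposure; concomitant and interaction entries never do.
#'
#' @param records A `report_set`.
#' @param drug_names Character vector of drug names (normalized internally).
#' @param synonyms Optional synonym map passed to [normalize_drug()].
#' @return Integer 0/1 vector aligned with the reports in `records`.
#' @export
flag_exposure <- function(records, drug_names, synonyms = NULL) {
  stopifnot(inherits(records, "report_set"))
  wanted <- normalize_drug(drug_names, synonyms)
  d <- records$drugs
  hit <- d$involvement == "suspected" &
    normalize_drug(d$drug_name, synonyms) %in% wanted
  as.integer(records$demo$case_id %in% d$case_id[hit])
}

#' Flag reports whose medical history matches a cancer-site term set
#'
#' @param records A `report_set`.
#' @param cancer_terms A [term_set()] (or character vector) of condition
#'   terms.
#' @return Integer 0/1 vector aligned with the reports in `records`.
#' @export
flag_cancer <- function(records, cancer_terms) {
  stopifnot(inherits(records, "report_set"))
  ts <- .as_term_set(cancer_terms, "cancer")
  hit_ids <- records$conditions$case_id[.match_terms(records$conditions$condition, ts)]
  as.integer(records$demo$case_id %in% hit_ids)
}

#' Build the analysis dataset of binary indicators
#'
#' One row per report with the case/non-case indicator, one 0/1 exposure
#' column per drug label, one 0/1 column per cancer site, and the covariates
#' `sex_female`, `age_ge60` (age band 60s or above) and `reporting_year`.
#'
#' @param records A `report_set`, already filtered by [filter_valid()].
#' @param event_terms [term_set()] defining the case.
#' @param drug_panel Named list: drug label -> character vector of drug names
#'   counted as that exposure.
#' @param cancer_panels Named list: cancer label -> [term_set()] or character
#'   vector of condition terms. May be empty.
#' @param synonyms Optional drug-name synonym map.
#' @return A data frame of class `analysis_dataset` with attributes
#'   `drug_labels` and `cancer_labels`.
#' @export
build_dataset <- function(records, event_terms, drug_panel,
                          cancer_panels = list(), synonyms = NULL) {
  stopifnot(inherits(records, "report_set"))
  if (!length(drug_panel))
    pv_error("drug panel is empty", "pvsignal_config_error")
  if (is.null(names(drug_panel)) || any(!nzchar(names(drug_panel))))
    pv_error("drug panel entries must be named", "pvsignal_config_error")

  ds <- data.frame(
    case_id = records$demo$case_id,
    event = flag_event(records, event_terms),
    sex_female = as.integer(records$demo$sex == "female"),
    age_ge60 = as.integer(.band_decade(records$demo$age_band) >= 60L),
    reporting_year = records$demo$reporting_year,
    stringsAsFactors = FALSE
  )
  reserved <- names(ds)
  labels <- c(names(drug_panel), names(cancer_panels))
  clash <- intersect(labels, reserved)
  if (length(clash))
    pv_error(paste0("panel label collides with a reserved column: ",
                    paste(clash, collapse = ", ")), "pvsignal_config_error")
  if (anyDuplicated(labels))
    pv_error("duplicate panel labels", "pvsignal_config_error")

  for (lab in names(drug_panel))
    ds[[lab]] <- flag_exposure(records, drug_panel[[lab]], synonyms)
  for (lab in names(cancer_panels))
    ds[[lab]] <- flag_cancer(records, cancer_panels[[lab]])

  structure(ds,
            drug_labels = names(drug_panel),
            cancer_labels = names(cancer_panels),
            class = c("analysis_dataset", "data.frame"))
}

#' Drug labels / cancer labels of an analysis dataset
#' @param dataset An `analysis_dataset`.
#' @return Character vector of labels.
#' @export
drug_labels <- function(dataset) attr(dataset, "drug_labels")

#' @rdname drug_labels
#' @export
cancer_labels <- function(dataset) attr(dataset, "cancer_labels")

#' Select drugs by case-count threshold
#'
#' Returns the drug labels whose number of case reports (rows with both the
#' exposure and the event indicator set) strictly exceeds `min_cases`,
#' sorted by descending case count. With the default threshold of 10 this is
#' the panel-inclusion rule "more than 10 reports" of the target event.
#'
#' @param dataset An `analysis_dataset`.
#' @param min_cases Non-negative integer threshold (strict inequality).
#' @return Character vector of drug labels.
#' @export
select_drugs <- function(dataset, min_cases = 10L) {
  stopifnot(inherits(dataset, "analysis_dataset"), min_cases >= 0)
  labs <- drug_labels(dataset)
  if (!length(labs) || !nrow(dataset)) return(character())
  counts <- vapply(labs, function(l) sum(dataset[[l]] == 1L & dataset$event == 1L),
                   integer(1))
  keep <- counts > min_cases
  names(sort(counts[keep], decreasing = TRUE))
}
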