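#' Re-inclusion misclassification scenario
#'
#' The survey frame excluded persons who did not meet the (pre-1995) asthma
#' definition but had a single asthma physician claim — 5.9% of the eligible
#' persons without asthma. This scenario asks what the agreement would have
#' been had they been recruited at the same rate as other non-asthma persons:
#' hypothetical respondents (administrative status negative) are added to the
#' table, a fraction `report_fraction` of them assumed to self-report asthma
#' (1 is the worst case, 0.5 the intermediate scenario), carrying the
#' non-asthma-stratum design weights with proportional allocation across the
#' two non-asthma strata.
#'
#' @param tab Baseline `agreement_table` built from the survey.
#' @param design `design_weights` table; non-asthma strata are identified by
#'   the `"/Asthma-"` suffix of the stratum label.
#' @param excluded_fraction Fraction of eligible non-asthma persons excluded
#'   for a single claim (study value 0.059).
#' @param report_fraction Fraction of re-included persons assumed to
#'   self-report asthma, in `[0, 1]`.
#' @return List: `kappa` ([estimate_ci()]), `table` (the augmented
#'   `agreement_table`), `n_reincluded`.
#' @export
reinclusion_scenario <- function(tab, design, excluded_fraction = 0.059,
                                 report_fraction = 1) {
  check_table(tab)
  stopifnot(inherits(design, "design_weights"))
  if (report_fraction < 0 || report_fraction > 1) {
    stop("report_fraction must be in [0, 1]", call. = FALSE)
  }
  if (excluded_fraction < 0 || excluded_fraction >= 1) {
    stop("excluded_fraction must be in [0, 1)", call. = FALSE)
  }
  non_asthma <- design[grepl("/Asthma-$", design$stratum), , drop = FALSE]
  if (nrow(non_asthma) == 0) {
    stop("design has no non-asthma stratum (label suffix '/Asthma-')",
         call. = FALSE)
  }
  n_frame <- sum(non_asthma$n_survey)
  # Excluded persons were excluded_fraction of the eligible pool, so per
  # retained frame member there are ef/(1-ef) of them; rounded to whole
  # hypothetical respondents, allocated proportionally to realized stratum
  # sizes.
  n_add_total <- round(excluded_fraction / (1 - excluded_fraction) * n_frame)
  alloc <- non_asthma$n_survey / n_frame
  n_add <- round(n_add_total * alloc)
  n_yes <- round(n_add * report_fraction)
  n_no <- n_add - n_yes

  # Rebuild the baseline cell masses on the absolute weighted scale (total
  # weighted mass of the survey = sum over strata of n_survey * weight), then
  # add the hypothetical persons: admin negative, self yes -> cell c,
  # self no -> cell d, each carrying its stratum weight.
  w_abs_total <- sum(design$n_survey * design$weight)
  mass <- c(a = tab$p_a, b = tab$p_b, c = tab$p_c, d = tab$p_d) * w_abs_total
  mass[["c"]] <- mass[["c"]] + sum(non_asthma$weight * n_yes)
  mass[["d"]] <- mass[["d"]] + sum(non_asthma$weight * n_no)
  props <- mass / sum(mass)
  new_tab <- structure(list(
    a = tab$a, b = tab$b, c = tab$c + sum(n_yes), d = tab$d + sum(n_no),
    p_a = props[["a"]], p_b = props[["b"]], p_c = props[["c"]],
    p_d = props[["d"]],
    n_actual = tab$n_actual + sum(n_add)), class = "agreement_table")
  list(kappa = cohen_kappa(new_tab), table = new_tab,
       n_reincluded = sum(n_add))
}

#' Exclude persons with health-coverage interruptions
#'
#' Removes persons having at least one insurance-coverage gap intersecting
#' the checkable period (coverage information exists for 1983--1994 only), so
#' that agreement can be recomputed free of the concern that out-of-province
#' care depressed their claims.
#'
#' @param persons Person tibble.
#' @param gaps Tibble with `person_id`, `gap_start`, `gap_end` (`Date`s).
#' @param period_start,period_end The checkable period.
#' @return `persons` restricted to those without intersecting gaps; the
#'   excluded ids are in the `excluded_ids` attribute.
#' @export
exclude_coverage_gaps <- function(persons, gaps,
                                  period_start = as.Date("1983-01-01"),
                                  period_end = as.Date("1994-12-31")) {
  if (nrow(gaps) == 0) {
    attr(persons, "excluded_ids") <- character()
    return(persons)
  }
  hit <- gaps$gap_start <= period_end & gaps$gap_end >= period_start
  flagged <- unique(gaps$person_id[hit])
  out <- persons[!persons$person_id %in% flagged, , drop = FALSE]
  attr(out, "excluded_ids") <- intersect(flagged, persons$person_id)
  out
}

DURATION_BINS <- c("0-5", "6-10", "11-20", ">=21")
AGE_BINS <- c("8-11", "12-17", ">=18")

# Integer age at an event date, anchored at the cohort's mid-year birthday
# (all members born in the same calendar year; exact birthdates synthetic).
age_at <- function(date, birth_year) {
  floor(as.numeric(date - as.Date(paste0(birth_year, "-07-01"))) / 365.25)
}

#' Percent agreement stratified by asthma service history
#'
#' Restricted to persons with at least one asthma-related health service who
#' are positive by either source, computes weighted percent agreement within
#' bins of: age at first asthma service, age at last service, duration
#' between first and last service, or any hospitalization. Empty bins are
#' reported with `n = 0` and `NA` agreement, never 0%.
#'
#' @param data Tibble with columns `admin`, `self` (logicals), `n_claims`,
#'   `n_hospitalizations`, `first_service_date`, `last_service_date`,
#'   `birth_year`, and optionally `weight`.
#' @param stratifier One of `"age_at_first"`, `"age_at_last"`, `"duration"`,
#'   `"any_hospitalization"`.
#' @return Tibble with `bin`, `n`, `pct_agreement`.
#' @export
stratified_agreement <- function(data,
                                 stratifier = c("age_at_first", "age_at_last",
                                                "duration",
                                                "any_hospitalization")) {
  stratifier <- match.arg(stratifier)
  w <- data$weight %||% rep(1, nrow(data))
  keep <- (data$n_claims + data$n_hospitalizations) >= 1 &
    !is.na(data$self) & (data$admin | data$self)
  d <- data[keep, , drop = FALSE]
  w <- w[keep]
  bin <- switch(stratifier,
    age_at_first = cut(age_at(d$first_service_date, d$birth_year),
                       c(-Inf, 11, 17, Inf), labels = AGE_BINS),
    age_at_last = cut(age_at(d$last_service_date, d$birth_year),
                      c(-Inf, 11, 17, Inf), labels = AGE_BINS),
    duration = cut(floor(as.numeric(
      d$last_service_date - d$first_service_date) / 365.25),
      c(-Inf, 5, 10, 20, Inf), labels = DURATION_BINS),
    any_hospitalization = factor(
      ifelse(d$n_hospitalizations >= 1, "yes", "no"), levels = c("yes", "no"))
  )
  agree <- d$admin == d$self
  out <- lapply(levels(bin), function(b) {
    i <- which(bin == b)
    tibble::tibble(
      bin = b, n = length(i),
      pct_agreement = if (length(i) == 0) NA_real_ else
        100 * sum(w[i] * agree[i]) / sum(w[i]))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "subset_n") <- nrow(d)
  res
}
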