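STRATUM_LEVELS <- c("BCG+/Asthma+", "BCG+/Asthma-",
                    "BCG-/Asthma+", "BCG-/Asthma-")

#' Assign the sampling stratum
#'
#' The survey drew near-equal numbers from the four strata formed by crossing
#' BCG vaccination with childhood asthma status (the pre-1995 claims
#' definition). Vectorized; missing inputs are an error because stratum
#' membership must be known for every cohort member.
#'
#' @param bcg Logical: BCG-vaccinated.
#' @param childhood_asthma Logical: met the pre-1995 asthma definition.
#' @return Factor with levels `"BCG+/Asthma+"`, `"BCG+/Asthma-"`,
#'   `"BCG-/Asthma+"`, `"BCG-/Asthma-"`.
#' @export
#' @examples
#' assign_stratum(c(TRUE, FALSE), c(TRUE, TRUE))
assign_stratum <- function(bcg, childhood_asthma) {
  if (anyNA(bcg) || anyNA(childhood_asthma)) {
    stop("stratum assignment requires non-missing bcg and childhood_asthma",
         call. = FALSE)
  }
  lab <- paste0(ifelse(bcg, "BCG+", "BCG-"), "/",
                ifelse(childhood_asthma, "Asthma+", "Asthma-"))
  factor(lab, levels = STRATUM_LEVELS)
}

#' Inverse-probability design weights from stratum counts
#'
#' Under the balanced stratified design the selection probability in stratum
#' *s* is `n_survey[s] / n_cohort[s]`; each survey respondent carries its
#' inverse, `n_cohort[s] / n_survey[s]`, so that weight totals reproduce the
#' cohort size.
#'
#' @param cohort_counts,survey_counts Named numeric vectors (names are stratum
#'   labels) or tibbles with columns `stratum` and `n`; the two must cover the
#'   same strata.
#' @return A tibble (class `design_weights`) with columns `stratum`,
#'   `n_cohort`, `n_survey`, `weight`.
#' @export
#' @examples
#' compute_weights(c(A = 1000, B = 9000), c(A = 400, B = 420))
compute_weights <- function(cohort_counts, survey_counts) {
  as_counts <- function(x, what) {
    if (is.data.frame(x)) x <- setNames(x$n, as.character(x$stratum))
    if (is.null(names(x)) || any(names(x) == "")) {
      stop(what, " counts must be named by stratum", call. = FALSE)
    }
    x
  }
  nc <- as_counts(cohort_counts, "cohort")
  ns <- as_counts(survey_counts, "survey")
  if (!setequal(names(nc), names(ns))) {
    stop("cohort and survey counts cover different strata", call. = FALSE)
  }
  ns <- ns[names(nc)]
  if (any(ns < 1)) {
    stop("weight undefined: zero survey count in stratum ",
         paste(names(ns)[ns < 1], collapse = ", "), call. = FALSE)
  }
  if (any(ns > nc)) {
    stop("inconsistent design: survey count exceeds cohort count in stratum ",
         paste(names(ns)[ns > nc], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(stratum = names(nc), n_cohort = unname(nc),
                        n_survey = unname(ns),
                        weight = unname(nc) / unname(ns))
  class(out) <- c("design_weights", class(out))
  out
}

#' Per-person weights from a design table
#'
#' @param design A [compute_weights()] table.
#' @param strata Character/factor vector of per-person stratum labels.
#' @return Numeric weight per person.
#' @export
person_weights <- function(design, strata) {
  strata <- as.character(strata)
  unknown <- setdiff(unique(strata), design$stratum)
  if (length(unknown) > 0) {
    stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  setNames(design$weight, design$stratum)[strata]
}

#' Read a design table, re-deriving the weights
#'
#' Expects columns `stratum`, `n_cohort`, `n_survey` and optionally `weight`.
#' The weight is always recomputed as `n_cohort / n_survey`; a stored weight
#' column that disagrees beyond 1e-6 relative error raises an error.
#'
#' @param path Path to a CSV/TSV design table.
#' @return A `design_weights` tibble.
#' @export
read_design <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("stratum", "n_cohort", "n_survey"), path)
  out <- compute_weights(
    setNames(as.numeric(df$n_cohort), df$stratum),
    setNames(as.numeric(df$n_survey), df$stratum))
  if ("weight" %in% names(df)) {
    stored <- as.numeric(df$weight)
    if (any(abs(stored - out$weight) > 1e-6 * pmax(1, out$weight))) {
      stop(sprintf("file '%s': stored weight disagrees with n_cohort/n_survey",
                   path), call. = FALSE)
    }
  }
  out
}
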