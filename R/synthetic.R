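LATENT_CLASSES <- c("never", "transient_childhood", "persistent",
                    "adult_onset")

default_covariate_specs <- function() {
  # Cohort-representative categorical marginals (design-corrected survey
  # distributions); the trailing element of each prob vector is the missing
  # fraction. Values on the percent scale; normalized at draw time.
  list(
    sex = list(levels = c("male", "female"),
               probs = c(44.0, 56.0), missing = 0),
    language = list(levels = c("French", "English"),
                    probs = c(93.5, 6.5), missing = 0),
    parental_birthplace = list(
      levels = c("in_quebec", "outside_quebec", "in_and_outside"),
      probs = c(83.4, 7.4, 4.9), missing = 4.3),
    area_of_residence = list(
      levels = c("all_urban", "all_rural", "urban_and_rural"),
      probs = c(58.8, 10.4, 30.1), missing = 0.7),
    family_income = list(
      levels = c("q1", "q2", "q3", "q4"),
      probs = c(9.1, 28.9, 37.2, 23.5), missing = 1.3),
    material_deprivation = list(
      levels = c("1", "2", "3", "4", "5"),
      probs = c(9.0, 22.9, 28.1, 23.5, 5.5), missing = 11.1),
    social_deprivation = list(
      levels = c("1", "2", "3", "4", "5"),
      probs = c(8.3, 29.7, 26.0, 21.0, 3.9), missing = 11.0),
    maternal_education = list(
      levels = c("elementary", "secondary", "college", "university"),
      probs = c(27.5, 36.2, 13.3, 13.4), missing = 9.7),
    paternal_education = list(
      levels = c("elementary", "secondary", "college", "university"),
      probs = c(30.5, 28.8, 9.3, 19.2), missing = 12.2),
    parental_asthma = list(levels = c("no", "yes"),
                           probs = c(78.5, 15.5), missing = 6.0))
}

#' Configuration of the synthetic birth cohort
#'
#' Parametrizes a seedable generator emulating a 1974 provincial birth cohort
#' with physician claims observable 1983--2012, hospitalizations 1987--2012,
#' a 2012 telephone survey, and a four-stratum balanced sampling design
#' (BCG x childhood asthma). Asthma histories follow four latent classes
#' (never / transient childhood / persistent / adult onset) with yearly claim
#' and hospitalization rates while the disease is active; self-report
#' sensitivity increases with disease duration and with any hospitalization
#' (logistic link), emulating the observed accuracy gradients. A fraction of
#' never-asthma persons carries a single stray asthma claim in 1983--1994 —
#' the group the original sampling frame excluded.
#'
#' @param n_cohort Cohort size.
#' @param class_probs Named probabilities of the four latent classes
#'   (must sum to 1).
#' @param claim_rate Mean asthma claims per active disease-year, per class.
#' @param claim_frailty_shape Shape of the per-person gamma frailty (mean 1)
#'   multiplying the claim rate, giving realistic overdispersion in
#'   healthcare utilization; smaller values spread claims more unevenly.
#' @param hosp_rate Asthma hospitalizations per active disease-year, per
#'   class.
#' @param self_report Coefficients of the reporting model for diseased
#'   persons: `plogis(intercept + per_year * duration_years +
#'   hosp_bonus * any_hospitalization)`.
#' @param false_positive_prob Probability a never-asthma person reports ever
#'   asthma.
#' @param physician_confirm_prob,physician_confirm_fp Probability of
#'   confirming physician diagnosis given an ever-yes report, for truly
#'   diseased and false-positive reporters respectively.
#' @param ever_missing_prob,physician_missing_prob Item-missingness rates of
#'   the two survey questions.
#' @param never_single_claim_prob Probability a never-asthma person has one
#'   stray asthma claim in 1983--1994 (study: such persons were 5.9% of
#'   eligible non-asthma persons).
#' @param noise_claim_rate Non-asthma (pneumonia-coded) claims per year, all
#'   persons, to exercise diagnosis filtering.
#' @param bcg_prob BCG vaccination probability.
#' @param participation Survey participation probability (study: 0.56).
#' @param coverage_gap_prob Probability of one insurance-coverage gap during
#'   1983--1994 (study: 2%).
#' @param allergy_prob Probability of >=1 allergy-related health service,
#'   named for concordant and discordant persons (discordance between the
#'   30-year administrative definition and self-report raises it, giving the
#'   determinant analysis a signal with OR < 1).
#' @param covariates Covariate specification list (see
#'   `claimsagree:::default_covariate_specs`).
#' @param seed Integer RNG seed; required.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_cohort = 80000,
                          class_probs = c(never = 0.80,
                                          transient_childhood = 0.11,
                                          persistent = 0.06,
                                          adult_onset = 0.03),
                          claim_rate = c(transient_childhood = 1.8,
                                         persistent = 0.8,
                                         adult_onset = 0.7),
                          hosp_rate = c(transient_childhood = 0.03,
                                        persistent = 0.02,
                                        adult_onset = 0.01),
                          claim_frailty_shape = 0.7,
                          self_report = c(intercept = 0.9, per_year = 0.12,
                                          hosp_bonus = 1.2),
                          false_positive_prob = 0.04,
                          physician_confirm_prob = 0.95,
                          physician_confirm_fp = 0.5,
                          ever_missing_prob = 0.0018,
                          physician_missing_prob = 0.0012,
                          never_single_claim_prob = 0.059,
                          noise_claim_rate = 0.02,
                          bcg_prob = 0.5,
                          participation = 0.56,
                          coverage_gap_prob = 0.02,
                          allergy_prob = c(concordant = 0.43,
                                           discordant = 0.70),
                          covariates = default_covariate_specs(),
                          seed = 1974L) {
  cfg <- list(n_cohort = n_cohort, class_probs = class_probs,
              claim_rate = claim_rate, hosp_rate = hosp_rate,
              claim_frailty_shape = claim_frailty_shape,
              self_report = self_report,
              false_positive_prob = false_positive_prob,
              physician_confirm_prob = physician_confirm_prob,
              physician_confirm_fp = physician_confirm_fp,
              ever_missing_prob = ever_missing_prob,
              physician_missing_prob = physician_missing_prob,
              never_single_claim_prob = never_single_claim_prob,
              noise_claim_rate = noise_claim_rate, bcg_prob = bcg_prob,
              participation = participation,
              coverage_gap_prob = coverage_gap_prob,
              allergy_prob = allergy_prob, covariates = covariates,
              seed = as.integer(seed))
  probs <- c(cfg$false_positive_prob, cfg$physician_confirm_prob,
             cfg$physician_confirm_fp, cfg$ever_missing_prob,
             cfg$physician_missing_prob, cfg$never_single_claim_prob,
             cfg$bcg_prob, cfg$participation, cfg$coverage_gap_prob,
             cfg$allergy_prob, cfg$class_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-9) {
    stop("cohort_config: class_probs must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$class_probs), LATENT_CLASSES)) {
    stop("cohort_config: class_probs must be named ",
         paste(LATENT_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (n_cohort < 1) stop("cohort_config: n_cohort must be positive",
                         call. = FALSE)
  if (is.na(cfg$seed)) stop("cohort_config: seed is required", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

draw_covariate <- function(n, spec) {
  p <- c(spec$probs, spec$missing)
  lev <- c(spec$levels, NA)
  out <- sample(lev, n, replace = TRUE, prob = p / sum(p))
  out
}

#' Generate a synthetic cohort
#'
#' Draws the full person-level cohort with events, self-reports, covariates,
#' coverage gaps and retained ground truth, deterministically for a given
#' config (including its seed). Physician claims are confined to 1983 onward
#' and hospitalizations to 1987 onward; all events end at each person's
#' interview date in 2012.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_dataset` list: `persons` (covariates, `bcg`,
#'   `interview_date`), `events`, `self_reports`, `gaps`, `truth`
#'   (latent class, disease duration, hospitalization flag, and the 30-year
#'   administrative status), and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_cohort = 500, seed = 7))
#' nrow(cohort$persons)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cohort
  birth_anchor <- as.Date("1974-07-01")
  person_id <- sprintf("p%06d", seq_len(n))
  interview_date <- as.Date("2012-01-01") + sample.int(365, n, TRUE) - 1L

  cls <- sample(LATENT_CLASSES, n, TRUE, prob = config$class_probs)
  bcg <- stats::runif(n) < config$bcg_prob

  # Active disease window in years of age
  onset <- rep(NA_real_, n)
  resol <- rep(NA_real_, n)
  tr <- cls == "transient_childhood"
  pe <- cls == "persistent"
  ad <- cls == "adult_onset"
  onset[tr] <- stats::runif(sum(tr), 1, 6)
  resol[tr] <- stats::runif(sum(tr), 8, 18)
  onset[pe] <- stats::runif(sum(pe), 1, 8)
  onset[ad] <- stats::runif(sum(ad), 18, 35)
  age_at_interview <- as.numeric(interview_date - birth_anchor) / 365.25
  resol[pe | ad] <- age_at_interview[pe | ad]

  active_start <- birth_anchor + round(onset * 365.25)
  active_end <- birth_anchor + round(resol * 365.25)
  active_end <- pmin(active_end, interview_date, na.rm = FALSE)

  rate_of <- function(rates) {
    out <- rep(0, n)
    for (k in names(rates)) out[cls == k] <- rates[[k]]
    out
  }

  window_events <- function(win_start, rate, kind_label) {
    lo <- pmax(active_start, win_start)
    hi <- active_end
    yrs <- pmax(0, as.numeric(hi - lo) / 365.25)
    yrs[is.na(yrs)] <- 0
    m <- stats::rpois(n, rate * yrs)
    idx <- rep(seq_len(n), m)
    offs <- stats::runif(length(idx)) * as.numeric(hi - lo)[idx]
    tibble::tibble(person_id = person_id[idx],
                   date = lo[idx] + round(offs), kind = kind_label)
  }

  frailty <- stats::rgamma(n, shape = config$claim_frailty_shape,
                           rate = config$claim_frailty_shape)
  claims <- window_events(CLAIMS_ERA_START,
                          frailty * rate_of(config$claim_rate),
                          "physician_claim")
  hosps <- window_events(HOSP_ERA_START, rate_of(config$hosp_rate),
                         "hospitalization")

  # Stray single asthma claim (1983-1994) among never-asthma persons: the
  # subgroup the original sampling frame excluded.
  nv <- which(cls == "never")
  stray_ids <- nv[stats::runif(length(nv)) < config$never_single_claim_prob]
  stray <- tibble::tibble(
    person_id = person_id[stray_ids],
    date = CLAIMS_ERA_START +
      sample.int(as.integer(as.Date("1994-12-31") - CLAIMS_ERA_START) + 1L,
                 length(stray_ids), TRUE) - 1L,
    kind = "physician_claim")

  asthma_ev <- dplyr::bind_rows(claims, hosps, stray)
  asthma_ev$code_system <- as.character(ifelse(
    asthma_ev$kind == "hospitalization" & asthma_ev$date >= ICD10_HOSP_START,
    "ICD10", "ICD9"))
  asthma_ev$code <- as.character(ifelse(
    asthma_ev$code_system == "ICD10",
    sample(c("J45", "J450"), nrow(asthma_ev), TRUE),
    sample(c("493", "4930"), nrow(asthma_ev), TRUE)))

  # Non-asthma noise claims (pneumonia rubric) over the whole claims era
  noise_yrs <- pmax(0, as.numeric(interview_date - CLAIMS_ERA_START) / 365.25)
  m_noise <- stats::rpois(n, config$noise_claim_rate * noise_yrs)
  nidx <- rep(seq_len(n), m_noise)
  noise <- tibble::tibble(
    person_id = person_id[nidx],
    date = CLAIMS_ERA_START +
      round(stats::runif(length(nidx)) *
              as.numeric(interview_date - CLAIMS_ERA_START)[nidx]),
    kind = "physician_claim", code_system = "ICD9", code = "486")

  events <- dplyr::bind_rows(asthma_ev, noise) |>
    dplyr::arrange(.data$person_id, .data$date, .data$kind) |>
    dplyr::select("person_id", "date", "kind", "code", "code_system")

  # Realized asthma service history (after per-day normalization)
  norm <- normalize_events(
    events[suppressWarnings(is_asthma_event(events)), , drop = FALSE])
  hist <- norm |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_service = if (dplyr::n() == 0) as.Date(NA) else
                       min(.data$date),
                     last_service = if (dplyr::n() == 0) as.Date(NA) else
                       max(.data$date),
                     any_hosp = any(.data$kind == "hospitalization"),
                     .groups = "drop")
  ord <- match(person_id, hist$person_id)
  duration <- ifelse(is.na(ord), 0, as.numeric(
    hist$last_service[ord] - hist$first_service[ord]) / 365.25)
  any_hosp <- !is.na(ord) & hist$any_hosp[ord] %in% TRUE

  # Self-report model
  diseased <- cls != "never"
  p_report <- ifelse(
    diseased,
    stats::plogis(config$self_report[["intercept"]] +
                    config$self_report[["per_year"]] * duration +
                    config$self_report[["hosp_bonus"]] * any_hosp),
    config$false_positive_prob)
  ever <- stats::runif(n) < p_report
  p_phys <- ifelse(diseased, config$physician_confirm_prob,
                   config$physician_confirm_fp)
  # Skip logic: the physician item is only asked after an ever-yes answer, so
  # it is FALSE (never diagnosed) for ever-no respondents and missing exactly
  # when the ever item is missing or the item itself went unanswered.
  phys <- ever & (stats::runif(n) < p_phys)
  ever[stats::runif(n) < config$ever_missing_prob] <- NA
  phys[is.na(ever)] <- NA
  phys[ever %in% TRUE &
         stats::runif(n) < config$physician_missing_prob] <- NA

  persons <- tibble::tibble(person_id = person_id, birth_year = 1974L,
                            interview_date = interview_date, bcg = bcg)
  for (v in names(config$covariates)) {
    persons[[v]] <- draw_covariate(n, config$covariates[[v]])
  }

  # Allergy-services indicator depends on concordance between the 30-year
  # administrative definition and self-report, so that discordance is
  # detectable as a determinant (direction: OR < 1 for >=1 service).
  admin30 <- classify_cohort(norm, persons, algorithm_spec(30),
                             normalized = TRUE)
  conc <- dplyr::coalesce(admin30$status == ever, TRUE)
  p_allergy <- ifelse(conc, config$allergy_prob[["concordant"]],
                      config$allergy_prob[["discordant"]])
  persons$allergy_services <- ifelse(stats::runif(n) < p_allergy, "1+", "0")

  # Coverage gaps during the checkable 1983-1994 period
  gap_ids <- which(stats::runif(n) < config$coverage_gap_prob)
  gap_start <- as.Date("1983-01-01") +
    sample.int(3650, length(gap_ids), TRUE)
  gaps <- tibble::tibble(
    person_id = person_id[gap_ids], gap_start = gap_start,
    gap_end = gap_start + sample(90:720, length(gap_ids), TRUE))

  self_reports <- tibble::tibble(person_id = person_id, ever_asthma = ever,
                                 physician_diagnosed = phys)
  truth <- tibble::tibble(person_id = person_id, latent_class = cls,
                          duration_years = duration,
                          any_hospitalization = any_hosp,
                          admin_status_30y = admin30$status)
  structure(list(persons = persons, events = events,
                 self_reports = self_reports, gaps = gaps, truth = truth,
                 config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d persons, %d events, seed %d\n",
    nrow(x$persons), nrow(x$events), x$config$seed))
  print(table(x$truth$latent_class))
  invisible(x)
}

#' Draw the stratified balanced survey sample
#'
#' Assigns every cohort member to one of the four design strata using the
#' pre-1995 sampling definition of childhood asthma (any two asthma claims or
#' one hospitalization up to the end of 1994), optionally removes
#' single-claim non-asthma persons from the frame (as the original sampling
#' did), thins by the participation rate, and draws a near-equal number of
#' participants per stratum. Weights are the inverse realized selection
#' probabilities computed from the full-cohort stratum counts.
#'
#' @param cohort A `cohort_dataset`.
#' @param per_stratum_target Participants targeted per stratum (study:
#'   about 411, for 1643 in total).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param exclude_single_claim Apply the single-claim exclusion to the frame.
#' @param childhood Optional precomputed result of classifying the cohort
#'   under the pre-1995 sampling definition (as returned by
#'   [classify_cohort()]); avoids re-classification when drawing many
#'   surveys from one cohort.
#' @return A `survey_sample` list: `persons` (id, stratum, weight,
#'   childhood_asthma), `design` (a `design_weights` table), and
#'   `excluded_single_claim` (ids removed from the frame).
#' @export
sample_survey <- function(cohort, per_stratum_target = 411, seed = NULL,
                          exclude_single_claim = TRUE, childhood = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(childhood)) {
    sampling_spec <- algorithm_spec(Inf,
                                    lookback_end = as.Date("1994-12-31"))
    childhood <- classify_cohort(cohort$events, cohort$persons,
                                 sampling_spec)
  }
  stratum <- assign_stratum(cohort$persons$bcg, childhood$status)

  single_claim <- !childhood$status & childhood$n_claims == 1 &
    childhood$n_hospitalizations == 0
  excluded_ids <- cohort$persons$person_id[single_claim]
  in_frame <- if (exclude_single_claim) !single_claim else
    rep(TRUE, nrow(cohort$persons))

  cohort_counts <- table(stratum)
  participates <- stats::runif(nrow(cohort$persons)) < cohort$config$participation
  chosen <- integer(0)
  for (s in STRATUM_LEVELS) {
    pool <- which(in_frame & participates & stratum == s)
    take <- min(per_stratum_target, length(pool))
    if (take < per_stratum_target) {
      warning(sprintf(
        "stratum %s smaller than target (%d < %d); capped", s, take,
        per_stratum_target), call. = FALSE)
    }
    chosen <- c(chosen, sample(pool, take))
  }
  survey_counts <- table(factor(stratum[chosen], levels = STRATUM_LEVELS))
  design <- compute_weights(
    setNames(as.numeric(cohort_counts), names(cohort_counts)),
    setNames(as.numeric(survey_counts), names(survey_counts)))
  w_chosen <- person_weights(design, stratum[chosen])
  persons <- tibble::tibble(
    person_id = cohort$persons$person_id[chosen],
    stratum = as.character(stratum[chosen]),
    childhood_asthma = childhood$status[chosen],
    weight = w_chosen)
  structure(list(persons = persons, design = design,
                 excluded_single_claim = excluded_ids),
            class = "survey_sample")
}
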