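TABLE4_CANDIDATES <- c("sex", "language", "parental_birthplace",
                       "area_of_residence", "family_income",
                       "material_deprivation", "social_deprivation",
                       "maternal_education", "paternal_education",
                       "parental_asthma", "allergy_services")

#' End-to-end run configuration
#'
#' @param seed Integer seed driving every random draw of the run (required).
#' @param n_cohort Synthetic cohort size.
#' @param per_stratum Survey participants targeted per stratum.
#' @param algorithms Window lengths (years) of the ascertainment algorithms;
#'   must be non-empty.
#' @param m_imputations Imputations for the determinant model.
#' @param run_sensitivity Include the sensitivity analyses.
#' @param outdir Output directory for CSV tables and the manifest, or `NULL`
#'   to return tables without writing.
#' @param cohort_overrides Named list of [cohort_config()] arguments to
#'   override.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed, n_cohort = 20000, per_stratum = 411,
                       algorithms = c(1, 2, 3, 5, 30), m_imputations = 20,
                       run_sensitivity = TRUE, outdir = NULL,
                       cohort_overrides = list()) {
  if (missing(seed) || is.na(as.integer(seed))) {
    stop("run_config: a seed is required when generating data",
         call. = FALSE)
  }
  if (length(algorithms) == 0) {
    stop("run_config: at least one algorithm window is required",
         call. = FALSE)
  }
  stopifnot(all(algorithms > 0))
  structure(list(seed = as.integer(seed), n_cohort = n_cohort,
                 per_stratum = per_stratum, algorithms = algorithms,
                 m_imputations = m_imputations,
                 run_sensitivity = run_sensitivity, outdir = outdir,
                 cohort_overrides = cohort_overrides),
            class = "run_config")
}

#' Assemble the person-level analysis dataset
#'
#' Joins survey persons with administrative status under each algorithm,
#' self-report items, covariates and design weights.
#'
#' @param cohort A `cohort_dataset`.
#' @param survey A `survey_sample`.
#' @param algorithms Window lengths in years.
#' @return List: `data` (one row per survey person: weights, per-algorithm
#'   status columns `admin_k<k>`, self-report, covariates, service history),
#'   `design`.
#' @export
build_analysis_data <- function(cohort, survey,
                                algorithms = c(1, 2, 3, 5, 30)) {
  sp <- survey$persons
  persons <- cohort$persons[match(sp$person_id, cohort$persons$person_id), ]
  ev <- cohort$events[cohort$events$person_id %in% sp$person_id, ]
  norm <- normalize_events(
    ev[suppressWarnings(is_asthma_event(ev)), , drop = FALSE])
  base <- NULL
  status_cols <- list()
  for (k in algorithms) {
    res <- classify_cohort(norm, persons, algorithm_spec(k),
                           normalized = TRUE)
    status_cols[[paste0("admin_k", k)]] <- res$status
    if (is.null(base)) base <- res
  }
  sr <- cohort$self_reports[match(sp$person_id,
                                  cohort$self_reports$person_id), ]
  out <- tibble::tibble(
    person_id = sp$person_id, stratum = sp$stratum, weight = sp$weight,
    birth_year = persons$birth_year,
    interview_date = persons$interview_date,
    n_claims = base$n_claims,
    n_hospitalizations = base$n_hospitalizations,
    first_service_date = base$first_service_date,
    last_service_date = base$last_service_date,
    ever_asthma = sr$ever_asthma,
    physician_diagnosed = sr$physician_diagnosed)
  for (nm in names(status_cols)) out[[nm]] <- status_cols[[nm]]
  for (v in c(TABLE4_CANDIDATES)) out[[v]] <- persons[[v]]
  list(data = out, design = survey$design)
}

covariate_table <- function(data, weights, vars = TABLE4_CANDIDATES) {
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    lev <- c(sort(unique(x[!is.na(x)])), if (anyNA(x)) "(missing)")
    xx <- ifelse(is.na(x), "(missing)", x)
    for (l in lev) {
      i <- xx == l
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = l, n = sum(i),
        pct_survey = 100 * mean(i),
        pct_corrected = 100 * sum(weights[i]) / sum(weights))
    }
  }
  dplyr::bind_rows(rows)
}

prevalence_table <- function(data, algorithms) {
  rows <- list()
  for (k in algorithms) {
    p <- prevalence(data[[paste0("admin_k", k)]], data$weight)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(source = sprintf(
        ">=2 claims within %s year(s) or >=1 hospitalization", format(k))),
      p)
  }
  for (item in c("ever_asthma", "physician_diagnosed")) {
    p <- prevalence(data[[item]], data$weight)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(source = paste0("self-report: ", item)), p)
  }
  dplyr::bind_rows(rows)
}

determinant_tables <- function(data, m, outcome_col = "agreement") {
  cand <- TABLE4_CANDIDATES
  model_data <- data[!is.na(data[[outcome_col]]), ]
  w <- model_data$weight
  # Selection runs on a single completed dataset; the retained model is then
  # pooled over all m imputations of the raw data.
  completed <- impute_categorical(model_data, cand, outcome_col, "stratum",
                                  w)
  sel <- purposeful_selection(completed, outcome_col, cand, w)
  retained <- sel$trace$variable[sel$trace$retained]
  final_formula <- stats::reformulate(
    if (length(retained)) retained else "1", response = outcome_col)
  pooled <- impute_and_pool(model_data, final_formula, w, "stratum",
                            outcome = outcome_col, m = m)
  long <- dplyr::bind_rows(
    lapply(names(sel$univariable), function(v) {
      if (is.null(sel$univariable[[v]])) return(NULL)
      dplyr::mutate(sel$univariable[[v]]$or_table, model = "univariable",
                    variable = v)
    }),
    if (!is.null(sel$initial)) {
      dplyr::mutate(sel$initial$or_table, model = "initial",
                    variable = NA_character_)
    },
    dplyr::mutate(pooled$or_table, model = "final",
                  variable = NA_character_))
  list(trace = sel$trace, selection = sel, pooled = pooled,
       table = long[long$term != "(Intercept)", ])
}

sensitivity_tables <- function(data, design, outcome_admin = "admin_k30") {
  base_tab <- build_table(data[[outcome_admin]], data$ever_asthma,
                          data$weight)
  worst <- reinclusion_scenario(base_tab, design, report_fraction = 1)
  inter <- reinclusion_scenario(base_tab, design, report_fraction = 0.5)
  strat <- lapply(
    c(age_at_first = "age_at_first", age_at_last = "age_at_last",
      duration = "duration", any_hospitalization = "any_hospitalization"),
    function(s) {
      stratified_agreement(
        dplyr::mutate(data, admin = .data[[outcome_admin]],
                      self = .data$physician_diagnosed), s)
    })
  scenarios <- tibble::tibble(
    scenario = c("baseline", "reinclusion_intermediate",
                 "reinclusion_worst_case"),
    kappa = c(cohen_kappa(base_tab)$estimate, inter$kappa$estimate,
              worst$kappa$estimate),
    kappa_lo = c(cohen_kappa(base_tab)$lower, inter$kappa$lower,
                 worst$kappa$lower),
    kappa_hi = c(cohen_kappa(base_tab)$upper, inter$kappa$upper,
                 worst$kappa$upper))
  list(scenarios = scenarios, stratified = strat)
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Generates a cohort, draws the stratified survey, applies every configured
#' ascertainment algorithm, and produces the study's table set: covariate
#' distributions (weighted and unweighted), prevalence per algorithm (crude
#' and design-corrected), the agreement grid (each algorithm against both
#' self-report items), the determinants-of-agreement models, and the
#' sensitivity analyses. Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `table1`, `table2`, `table3`, `table4`,
#'   `sensitivity`, `cohort`, `survey`, `analysis`, `manifest`. When
#'   `config$outdir` is set the tables are also written as CSV plus a JSON
#'   manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cc_args <- utils::modifyList(list(n_cohort = config$n_cohort,
                                    seed = config$seed),
                               config$cohort_overrides)
  cohort <- generate_cohort(do.call(cohort_config, cc_args))
  survey <- sample_survey(cohort, per_stratum_target = config$per_stratum)
  ad <- build_analysis_data(cohort, survey, config$algorithms)
  data <- ad$data

  kmax <- paste0("admin_k", max(config$algorithms))
  data$agreement <- agreement_outcome(data[[kmax]], data$physician_diagnosed)

  table1 <- covariate_table(data, data$weight)
  table2 <- prevalence_table(data, config$algorithms)
  table3 <- agreement_summary(
    setNames(lapply(config$algorithms,
                    function(k) data[[paste0("admin_k", k)]]),
             paste0("k", config$algorithms)),
    data, data$weight)
  det <- determinant_tables(data, config$m_imputations)
  sens <- if (config$run_sensitivity) {
    s <- sensitivity_tables(data, ad$design, kmax)
    gapless <- exclude_coverage_gaps(data[, c("person_id")], cohort$gaps)
    keep <- data$person_id %in% gapless$person_id
    s$coverage_gap_exclusion <- tibble::tibble(
      n_excluded = sum(!keep),
      kappa_after = cohen_kappa(build_table(
        data[[kmax]][keep], data$ever_asthma[keep],
        data$weight[keep]))$estimate)
    s
  }

  manifest <- list(seed = config$seed, n_cohort = config$n_cohort,
                   per_stratum = config$per_stratum,
                   algorithms = config$algorithms,
                   m_imputations = config$m_imputations,
                   n_survey = nrow(data),
                   config_hash = rlang::hash(
                     config[setdiff(names(config), "outdir")]),
                   package_version =
                     as.character(utils::packageVersion("claimsagree")))

  out <- list(table1 = table1, table2 = table2, table3 = table3,
              table4 = det$table, determinants = det,
              sensitivity = sens, cohort = cohort, survey = survey,
              analysis = data, manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(config$outdir, name), row.names = FALSE)
    }
    wr(table1, "table1_characteristics.csv")
    wr(table2, "table2_prevalence.csv")
    wr(table3, "table3_agreement.csv")
    wr(det$table, "table4_determinants.csv")
    wr(det$trace, "table4_selection_trace.csv")
    if (!is.null(sens)) {
      wr(sens$scenarios, "sensitivity_reinclusion.csv")
      wr(dplyr::bind_rows(sens$stratified, .id = "stratifier"),
         "sensitivity_stratified.csv")
      wr(sens$coverage_gap_exclusion, "sensitivity_coverage_gaps.csv")
    }
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
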