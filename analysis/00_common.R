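# Shared settings for the analysis drivers. Each numbered script regenerates
# the same synthetic cohort (generation is deterministic and takes seconds),
# so no intermediate data files need to be stored.

suppressMessages(library(claimsagree))
suppressMessages(library(dplyr))

ANALYSIS_SEED <- 1974L
N_COHORT <- 20000L     # scaled-down stand-in for the ~81,000-person cohort
PER_STRATUM <- 411L    # gives ~1,644 survey participants, as in the study
RESULTS_DIR <- "results"

dir.create(RESULTS_DIR, showWarnings = FALSE)

load_study <- function() {
  cohort <- generate_cohort(cohort_config(n_cohort = N_COHORT,
                                          seed = ANALYSIS_SEED))
  survey <- sample_survey(cohort, per_stratum_target = PER_STRATUM)
  ad <- build_analysis_data(cohort, survey)
  list(cohort = cohort, survey = survey, data = ad$data,
       design = ad$design)
}

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
}
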