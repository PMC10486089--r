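# Generate the synthetic birth cohort and its stratified survey sample, and
# summarise what the generator produced: latent disease classes, event
# volumes, the four design strata and their weights, and the
# covariate distributions of the survey sample (study-style Table 1).

source("analysis/00_common.R")

st <- load_study()
cohort <- st$cohort

message(sprintf("cohort: %d persons, %d events (%d asthma-coded)",
                nrow(cohort$persons), nrow(cohort$events),
                sum(suppressWarnings(is_asthma_event(cohort$events)))))
message("latent classes: ",
        paste(names(table(cohort$truth$latent_class)),
              table(cohort$truth$latent_class), collapse = ", "))

save_table(as.data.frame(table(class = cohort$truth$latent_class)),
           "cohort_latent_classes.csv")
save_table(st$design, "design_weights.csv")

message(sprintf("survey: %d participants; weights %.2f-%.2f",
                nrow(st$data), min(st$data$weight), max(st$data$weight)))
message(sprintf("single-claim non-asthma persons excluded from the frame: %d",
                length(st$survey$excluded_single_claim)))

# Survey covariate distributions, unweighted and design-corrected
tab1 <- claimsagree:::covariate_table(st$data, st$data$weight)
save_table(tab1, "table1_characteristics.csv")
message("covariate table written; corrected percentages re-weight the ",
        "balanced sample back to the cohort")
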