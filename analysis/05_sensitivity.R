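# Sensitivity analyses: (1) re-inclusion of the single-claim non-asthma
# persons the sampling frame excluded, under worst-case and intermediate
# self-report assumptions; (2) exclusion of persons with health-insurance
# coverage gaps in 1983-1994; (3) percent agreement stratified by asthma
# service history (age at first/last service, duration, hospitalization).

source("analysis/00_common.R")

st <- load_study()
d <- st$data
d$agreement <- agreement_outcome(d$admin_k30, d$physician_diagnosed)

sens <- claimsagree:::sensitivity_tables(d, st$design)
save_table(sens$scenarios, "sensitivity_reinclusion.csv")
message("re-inclusion scenarios (kappa, 30-year definition vs ever asthma):")
for (i in seq_len(nrow(sens$scenarios))) {
  message(sprintf("  %-26s kappa %.2f (%.2f-%.2f)",
                  sens$scenarios$scenario[i], sens$scenarios$kappa[i],
                  sens$scenarios$kappa_lo[i], sens$scenarios$kappa_hi[i]))
}

gapless <- exclude_coverage_gaps(d[, "person_id"], st$cohort$gaps)
keep <- d$person_id %in% gapless$person_id
tab_gap <- build_table(d$admin_k30[keep], d$ever_asthma[keep],
                       d$weight[keep])
message(sprintf(
  "coverage gaps: %d of %d participants excluded; kappa %.2f after exclusion",
  sum(!keep), nrow(d), cohen_kappa(tab_gap)$estimate))
save_table(tibble::tibble(n_excluded = sum(!keep),
                          kappa_after = cohen_kappa(tab_gap)$estimate),
           "sensitivity_coverage_gaps.csv")

strat <- bind_rows(lapply(
  c("age_at_first", "age_at_last", "duration", "any_hospitalization"),
  function(s) {
    out <- stratified_agreement(
      mutate(d, admin = admin_k30, self = physician_diagnosed), s)
    mutate(out, stratifier = s, .before = 1)
  }))
save_table(strat, "sensitivity_stratified.csv")
message("agreement by service history (positives by either source):")
for (i in seq_len(nrow(strat))) {
  message(sprintf("  %-20s %-6s n=%-4d %s", strat$stratifier[i],
                  strat$bin[i], strat$n[i],
                  ifelse(is.na(strat$pct_agreement[i]), "(empty)",
                         sprintf("%.0f%%", strat$pct_agreement[i]))))
}
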