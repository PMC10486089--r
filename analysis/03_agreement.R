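# Weighted agreement between each claims-based definition and both
# self-report items: percent agreement, Cohen's kappa, and positive/negative
# agreement with 95% CIs (study-style Table 3: 5 algorithms x 2 items).

source("analysis/00_common.R")

st <- load_study()
d <- st$data

algos <- c(1, 2, 3, 5, 30)
table3 <- agreement_summary(
  setNames(lapply(algos, function(k) d[[paste0("admin_k", k)]]),
           paste0("k", algos)),
  d, d$weight)
save_table(table3, "table3_agreement.csv")

message("agreement with self-report (weighted):")
for (i in seq_len(nrow(table3))) {
  message(sprintf(
    "  %-4s vs %-20s agree %.1f%%  kappa %.2f (%.2f-%.2f, %s)  Ppos %.2f  Pneg %.2f",
    table3$algorithm[i], table3$self_item[i], table3$agreement_pct[i],
    table3$kappa[i], table3$kappa_lo[i], table3$kappa_hi[i],
    table3$kappa_band[i], table3$ppos[i], table3$pneg[i]))
}
best <- table3[which.max(table3$kappa), ]
message(sprintf("strongest agreement: %s vs %s (kappa %.2f)",
                best$algorithm, best$self_item, best$kappa))
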