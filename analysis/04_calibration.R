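#!/usr/bin/env Rscript
# Statistical validation of the machinery on simulated cohorts:
#   (1) TDT type-I error under null transmission (tau = 0.5), 2,000
#       replicates of 89 trios;
#   (2) recovery of a known case-enrichment odds ratio (2.0 for
#       cB01/tA01) through the complete GCN -> haplotype -> association
#       pipeline at 2,000 families.

library(kirhap)

set.seed(104729)
n_rep <- 2000
ps <- vapply(seq_len(n_rep), function(i) {
  trios <- simulate_trios(simulation_config(n_families = 89))
  tdt_from_trios(trios, "C1k")$p_value
}, numeric(1))
rate <- mean(ps <= 0.05)
se3 <- 3 * sqrt(0.05 * 0.95 / n_rep)
cat(sprintf("TDT null rejection rate at alpha 0.05: %.4f (band %.4f-%.4f)\n",
            rate, 0.05 - se3, 0.05 + se3))

set.seed(104730)
cfg <- simulation_config(n_families = 2000, case_enrichment_or = 2.0,
                         risk_target = "cB01/tA01")
trios <- simulate_trios(cfg)
tabs <- cohort_tables(trios)
pool <- simulate_control_pool(simulation_config(), 9024)
calls <- complete_calls(haplotype_cohort(tabs$gcn), tabs$ped)
det <- calls[calls$determined, ]
tal <- table(c(det$call1, det$call2))
rec <- haplotype_association_table(setNames(as.numeric(tal), names(tal)),
                                   pool, "cB01/tA01")
se <- sqrt(1 / rec$table$a + 1 / rec$table$b + 1 / rec$table$c +
             1 / rec$table$d)
cat(sprintf("Recovered enrichment OR: %.3f (target 2.0, 3 SE band %.3f-%.3f)\n",
            rec$odds_ratio, 2 * exp(-3 * se), 2 * exp(3 * se)))
cat(sprintf("Complete haplotypes determined for %.1f%% of probands\n",
            100 * nrow(det) / nrow(tabs$ped)))

dir.create("results", showWarnings = FALSE)
write.table(
  data.frame(quantity = c("tdt_null_rejection_rate",
                          "recovered_enrichment_or",
                          "pct_determined"),
             value = c(rate, rec$odds_ratio,
                       100 * nrow(det) / nrow(tabs$ped))),
  "results/calibration.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
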