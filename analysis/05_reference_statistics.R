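#!/usr/bin/env Rscript
# Recompute the reference cohort's printed statistics from its published
# summary counts: omnibus chi-squares for behaviors and comorbidity, the
# residual-category composition, and the follow-up remission/migration
# arithmetic. These are the package's reproduction targets.
library(edclassify)
dir.create("results", showWarnings = FALSE)

beh <- ref_behavior_counts()
rows <- lapply(rownames(beh$yes), function(b) {
  res <- behavior_chi_square(beh$yes[b, ], beh$group_n,
                             omit = beh$omit[[b]])
  data.frame(variable = b, chi2 = round(res$statistic, 2), df = res$df,
             N = res$N, cramers_v = round(res$effect, 3))
})
com <- ref_comorbidity_counts()
rows2 <- lapply(rownames(com$yes), function(d) {
  res <- behavior_chi_square(com$yes[d, ], com$group_n)
  data.frame(variable = d, chi2 = round(res$statistic, 2), df = res$df,
             N = res$N, cramers_v = round(res$effect, 3))
})
tab <- rbind(do.call(rbind, rows), do.call(rbind, rows2))
write.csv(tab, "results/reference_chi2.csv", row.names = FALSE)
print(tab, row.names = FALSE)

d <- ref_diagnosis_distribution()
comp <- osfed_composition(stats::setNames(as.list(d$n), d$label))
cat(sprintf("PD: %.1f%% of cohort; %.0f%% of residual group;",
            comp$pd_pct_cohort, round_half_up(comp$pd_pct_osfed)),
    sprintf("PD+AAN+SubBED %.0f%% of residual group\n",
            round_half_up(comp$named_pct_osfed)))

cx <- as_crossover_table(ref_crossover_counts())
rr <- remission_rates(cx)
print(rr, row.names = FALSE, digits = 3)
mig <- migration_summary(cx)
cat(sprintf(
  "migration excluding UFED/AAN: mean %.0f%%, range %.0f%% to %.0f%%\n",
  round_half_up(mig$mean_pct), round_half_up(mig$min_pct),
  round_half_up(mig$max_pct)))
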