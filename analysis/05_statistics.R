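#!/usr/bin/env Rscript
# Group comparisons on the quantified tables: two-sample t test of
# stiff-vs-soft internalization AUC and a one-way ANOVA with Tukey pairwise
# comparisons across wound/laurdan/flow-style multi-group tables.

suppressPackageStartupMessages(library(stiffquant))

dir.create("results", showWarnings = FALSE)

auc <- utils::read.csv("results/internalization_auc.csv")
by_cond <- split(auc$auc, auc$condition)
tt <- t_test_two_sample(by_cond$stiff, by_cond$soft)
cat(sprintf("stiff vs soft AUC: t = %.3f, df = %.0f, p = %.3g\n",
            tt$statistic, tt$degrees_of_freedom, tt$p_value))

out <- data.frame(test = "t_stiff_vs_soft_auc", statistic = tt$statistic,
                  df = tt$degrees_of_freedom, p_value = tt$p_value)

## Multi-group example: per-frame membrane fold change by timepoint
## (3 groups, one observation per scene), ANOVA + Tukey.
fr <- utils::read.csv("results/internalization_frames.csv")
fr <- fr[fr$condition == "stiff", ]
groups <- split(fr$fold_change, fr$t_min)
names(groups) <- paste0("t", names(groups))
an <- anova_oneway_tukey(groups)
cat(sprintf("fold change across timepoints: F = %.3f, p = %.3g\n",
            an$statistic, an$p_value))
out <- rbind(out, data.frame(test = "anova_fold_by_timepoint",
                             statistic = an$statistic,
                             df = an$degrees_of_freedom[1],
                             p_value = an$p_value))

utils::write.csv(out, "results/statistics.csv", row.names = FALSE)
utils::write.csv(an$tukey, "results/tukey_fold_by_timepoint.csv",
                 row.names = FALSE)
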