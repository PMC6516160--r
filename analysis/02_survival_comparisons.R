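#!/usr/bin/env Rscript

# Stage 2: classical survival comparisons between the sexes.
#
# Kaplan-Meier medians with confidence intervals per sex, the log-rank test,
# and the maximum-lifespan proportion test (the age at which the pooled
# population reaches 90% mortality, then a Fisher exact comparison of the
# proportion of each sex still alive at that age).

library(murihaz)

cohort <- read_cohort("results/cohort.csv")
ss <- survival_summary(cohort)

cat(sprintf("median lifespan F: %.0f d (95%% CI %.0f-%.0f)\n",
            ss$median$F$median_days, ss$median$F$ci_lower_days,
            ss$median$F$ci_upper_days))
cat(sprintf("median lifespan M: %.0f d (95%% CI %.0f-%.0f)\n",
            ss$median$M$median_days, ss$median$M$ci_lower_days,
            ss$median$M$ci_upper_days))
cat(sprintf("log-rank chi2 = %.2f, p = %.3g\n",
            ss$logrank$chi_square, ss$logrank$p))
ml <- ss$max_lifespan
cat(sprintf("90%%-mortality age: %.0f d; alive beyond it: F %.3f, M %.3f; fisher p = %.3f\n",
            ml$threshold_age_days, ml$proportions$F$proportion,
            ml$proportions$M$proportion, ml$fisher_p))

res <- data.frame(
  quantity = c("median_f", "median_m", "logrank_p", "max_lifespan_age",
               "prop_alive_f", "prop_alive_m", "max_lifespan_fisher_p"),
  value = c(ss$median$F$median_days, ss$median$M$median_days, ss$logrank$p,
            ml$threshold_age_days, ml$proportions$F$proportion,
            ml$proportions$M$proportion, ml$fisher_p))
write.csv(res, "results/survival_comparisons.csv", row.names = FALSE)
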