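#!/usr/bin/env Rscript

# Stage 6: age-stratified linear regressions of lifespan on bodyweight.
#
# Applies the study's exclusion rules (censored animals out, post-mortem
# weight records out, orphans out), then fits pooled and per-sex OLS at
# each scheduled measurement age, with standardized coefficients, plus the
# sex x weight and site x weight interaction models at 6 months.

library(murihaz)

cohort <- read_cohort("results/cohort.csv")
weights <- read_weights("results/weights.csv")

joined <- join_weights(cohort, weights)
write_exclusion_report(joined, "results/weight_exclusions.csv")
excl <- attr(joined, "exclusions")
cat("exclusions by rule and sex:\n")
print(excl, row.names = FALSE)

tabs <- weight_regression_tables(joined)
write.csv(tabs$pooled, "results/weightreg_pooled.csv", row.names = FALSE)
write.csv(tabs$by_sex, "results/weightreg_by_sex.csv", row.names = FALSE)

cat("\npooled slopes (days/g):\n")
print(tabs$pooled[, c("age_months", "n", "coefficient", "se", "p",
                      "r_squared", "standardized_coefficient")],
      digits = 3, row.names = FALSE)
cat("\nper-sex slopes (days/g):\n")
print(tabs$by_sex[, c("stratum", "age_months", "n", "coefficient", "se",
                      "p", "standardized_coefficient")],
      digits = 3, row.names = FALSE)

ir_sex <- interaction_regression(joined, 6, "sex")
ir_site <- interaction_regression(joined, 6, "site")
cat(sprintf("\nsex x weight interaction at 6 mo: F = %.2f, p = %.3g\n",
            ir_sex$interaction_f, ir_sex$interaction_p))
cat(sprintf("site x weight interaction at 6 mo: F = %.2f, p = %.3g\n",
            ir_site$interaction_f, ir_site$interaction_p))

# heavy-animal sensitivity: excluding the heaviest animals should not
# change the qualitative pattern
heavy <- heavy_animal_filter(joined, threshold_g = 50)
cat(sprintf("\nheavy-animal filter (>50 g): %d rows removed\n",
            attr(heavy, "n_excluded")))
t6 <- weight_regression(heavy, 6, stratify_by_sex = FALSE)
cat(sprintf("pooled 6-month slope after filter: %+.2f days/g\n",
            t6$coefficient))
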