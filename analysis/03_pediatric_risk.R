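#!/usr/bin/env Rscript
# Risk assessment for the five paediatric HD categories (ages 0, 1, 5, 10,
# 15 at diagnosis), both sexes, with and without correction for
# disease-related mortality (10-year HD survival 94%).

suppressPackageStartupMessages(library(lymphorad))
dir.create("results", showWarnings = FALSE)

background <- make_background_table()
cancer <- make_cancer_rate_tables(background = background)

corr <- summarize_cohort("HD", background, cancer, corrected = TRUE)
uncorr <- summarize_cohort("HD", background, cancer, corrected = FALSE)

out <- rbind(uncorr$results, corr$results)
write.csv(out, "results/pediatric_risk.csv", row.names = FALSE)
avg <- rbind(uncorr$averages, corr$averages)
write.csv(avg, "results/pediatric_risk_averages.csv", row.names = FALSE)

print(corr)
cat("\nWithout the disease correction:\n")
print(uncorr$averages[, c("sex", "reid", "dle_radiation_days")], digits = 3)
cat("\nCorrecting for disease-related mortality lowers both the fraction",
    "of radiation-induced deaths and the radiation-induced loss of life",
    "expectancy in every category; girls carry roughly twice the boys'",
    "radiation risk, driven by breast and the higher female lung ERR.\n")
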