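#!/usr/bin/env Rscript
# Step 1 — weight-of-evidence hazard scores and relative ranking.
#
# Scores the bundled TiO2 evidence table (22 lines of evidence with
# printed index columns) after recovering the unpublished aggregation
# weights by least squares, then scores the synthetic stand-in tables
# for Ag and ZnO and reports the relative hazard ranking.

suppressPackageStartupMessages(library(nanoscreen))
dir.create("results", showWarnings = FALSE)

tabs <- synthetic_comparison_tables()
fit <- fit_aggregation_weights(tabs$TiO2)
cat("Recovered aggregation weights from the TiO2 table:\n")
print(fit)

scores <- lapply(tabs, hazard_score, weights = fit)
for (hs in scores) print(hs)

v <- vapply(scores, `[[`, numeric(1), "V")
ranking <- names(sort(v, decreasing = TRUE))
cat("\nRelative hazard ranking (highest first):",
    paste(ranking, collapse = " > "), "\n")

write.csv(scores$TiO2$breakdown, "results/woe_tio2_breakdown.csv",
          row.names = FALSE)
write.csv(data.frame(nm = names(v), V = as.numeric(v),
                     n_loe = vapply(tabs, nrow, integer(1)),
                     w_pchem = fit$w_pchem, w_tox = fit$w_tox),
          "results/woe_scores.csv", row.names = FALSE)
cat("written: results/woe_tio2_breakdown.csv, results/woe_scores.csv\n")
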