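#!/usr/bin/env Rscript
# Step 5 — comparison of the two frameworks on the synthetic database:
# WoE hazard scores V per nanomaterial versus the learned network's
# normalized hazard scores, with the agreement flag on the relative
# ranking.

suppressPackageStartupMessages(library(nanoscreen))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 2026L)
bundle <- generate_loe_database(cfg)

woe <- vapply(bundle$woe_tables, function(t) hazard_score(t)$V, numeric(1))
fit <- learn_parameters_em(synthetic_ground_truth(), bundle$bn_train)
bn <- vapply(names(bundle$woe_tables), function(nm) {
  as.numeric(normalized_hazard_score(
    infer_posterior(fit, list(nanoparticle = nm), "nm_hazard")))
}, numeric(1))

cmp <- compare_frameworks(woe, bn)
print(cmp)
cat("\nGround-truth expected normalized scores:\n")
print(round(bundle$ground_truth$expected_scores, 3))

out <- cmp$table
out$seed <- cfg$seed
write.csv(out, "results/comparison.csv", row.names = FALSE)
cat("written: results/comparison.csv\n")
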