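#!/usr/bin/env Rscript
# Stage 2 — feature RDMs and their intercorrelations.
#
# Applies the rater exclusion rules, aggregates ratings, assembles the
# feature battery (ratings + annotations + embedding proxy), builds the
# feature RDM battery, and reports rater exclusions, predictor collinearity
# (VIFs), and the tau-a intercorrelation matrix.

suppressPackageStartupMessages(library(actionrsa))
world <- readRDS("results/world_152.rds")

kept <- exclude_raters(world$ratings)
excl <- attr(kept, "exclusions")
cat(sprintf("excluded %d of %d raters:\n", nrow(excl),
            length(unique(world$ratings$rater))))
print(table(excl$reason))

fs <- assemble_features(world, zscore = TRUE)
rdms <- build_feature_rdms(fs)
cat(sprintf("built %d feature RDMs over %d items\n", length(rdms),
            length(world$items)))

inter <- feature_intercorrelations(rdms)
write.csv(round(inter, 4), "results/feature_intercorrelations.csv")
cat("largest off-diagonal |tau_a|:",
    max(abs(inter[upper.tri(inter)])), "\n")

X <- sapply(rdms, function(r) r$values)
vifs <- variance_inflation_factors(X)
write.csv(data.frame(feature = names(vifs), vif = vifs),
          "results/feature_vifs.csv", row.names = FALSE)
cat("mean predictor VIF:", round(mean(vifs), 2), "\n")

for (nm in names(rdms)) {
  write_rdm_csv(rdms[[nm]], file.path("results", paste0("rdm_", nm, ".csv")))
}
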