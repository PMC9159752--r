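#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study.
#
# Builds the two stimulus sets (152 items over 18 activity categories plus
# agent-free controls; 65 items with 3-4 exemplars per category), the rater
# pool with plantable bad raters, and the one-back session design, and writes
# the rating tables, annotations, and design to results/.

suppressPackageStartupMessages(library(actionrsa))
dir.create("results", showWarnings = FALSE)
seed <- 20260924L

world152 <- gen_feature_set(gt_config(n_bad_raters = 1, n_catchfail_raters = 1),
                            seed = seed)
world65 <- gen_feature_set(
  gt_config_65(weights = c(gist = sqrt(0.02), transitivity = sqrt(0.02),
                           sociality = sqrt(0.06), valence = sqrt(0.90))),
  seed = seed + 1)

write.csv(world152$ratings, "results/ratings_152.csv", row.names = FALSE)
write.csv(world152$annotations, "results/annotations_152.csv", row.names = FALSE)
write.csv(world65$ratings, "results/ratings_65.csv", row.names = FALSE)
write.csv(world65$annotations, "results/annotations_65.csv", row.names = FALSE)
saveRDS(world152, "results/world_152.rds")
saveRDS(world65, "results/world_65.rds")

des <- gen_session_design(seed = seed + 2)
write.csv(des, "results/session_design.csv", row.names = FALSE)

cat(sprintf("152-item world: %d items, %d categories, %d rating rows\n",
            length(world152$items), length(unique(world152$categories)),
            nrow(world152$ratings)))
cat(sprintf("65-item world:  %d items\n", length(world65$items)))
cat(sprintf("one-back design: %d trials (%d experimental + %d catch)\n",
            nrow(des), sum(!des$is_catch), sum(des$is_catch)))
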