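#!/usr/bin/env Rscript
# Stage 4 — cross-validated variance partitioning of behavior.
#
# Decomposes the predicted squared tau-a of the simulated behavioral RDMs
# into unique and shared contributions of the visual / action /
# social-affective predictor groups, using split-half cross-validation over
# subjects (100 iterations), with one-tailed sign permutation tests
# (omnibus-corrected) and paired Wilcoxon comparisons between groups.

suppressPackageStartupMessages(library(actionrsa))
world <- readRDS("results/world_65.rds")
subject_rdms <- readRDS("results/behavior_subject_rdms.rds")

pg <- predictor_groups(
  visual = list(euclidean_rdm(world$latents[, "gist", drop = FALSE]),
                euclidean_rdm(world$latents[, "environment", drop = FALSE])),
  action = list(euclidean_rdm(world$latents[, "transitivity", drop = FALSE]),
                euclidean_rdm(world$latents[, "activity", drop = FALSE])),
  social = list(euclidean_rdm(world$latents[, "sociality", drop = FALSE]),
                euclidean_rdm(world$latents[, "arousal", drop = FALSE])))

vp <- crossval_varpart(subject_rdms, pg, "split_subjects", n_iter = 100,
                       seed = 20260941L)
print(vp)
m <- colMeans(vp$components)
cat(sprintf("full model predicted tau_a^2: %.4f\n", m["full"]))
p <- vp$tests$p_corrected
out <- data.frame(component = vp$component_names[1:7],
                  mean = m[1:7], p_omnibus = p,
                  significant = vp$tests$significant)
write.csv(out, "results/behavior_varpart.csv", row.names = FALSE)
print(out, digits = 3)

pu <- c(
  V_vs_A = paired_comparison(vp$components[, "unique_V"], vp$components[, "unique_A"]),
  V_vs_S = paired_comparison(vp$components[, "unique_V"], vp$components[, "unique_S"]),
  A_vs_S = paired_comparison(vp$components[, "unique_A"], vp$components[, "unique_S"]))
cat("paired comparisons of unique components (two-sided Wilcoxon):\n")
print(round(pu, 5))
write.csv(data.frame(contrast = names(pu), p = pu),
          "results/behavior_varpart_contrasts.csv", row.names = FALSE)
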