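#!/usr/bin/env Rscript
# Stage 5: two-stage random-forest classifiers.
#
# For each site and each target (disease state; behavior B1 vs B2/B3 in
# CD; progression in followed CD), the cohort is split 60/40 stratified by
# class, features are the taxa significant in the matching covariate-
# adjusted NB contrast computed on the training split only, a preliminary
# forest (mtry 2, 1001 trees) is filtered at importance z > 2, and the
# refined forest is scored on the held-out subset with a stratified
# bootstrap AUC interval. The generator plants disease-state and
# progression effects but no behavior effect, so the behavior classifier
# is expected to sit near chance here.

library(cdmli)

cohort <- read_cohort("results/cohort")
samples <- cohort$samples

classify <- function(st, target, subset_expr, covars, label_col) {
  idx <- samples$site == st & subset_expr & !is.na(samples[[label_col]])
  meta <- samples[idx, ]
  counts <- cohort$counts[, idx]
  labels <- setNames(meta[[label_col]], meta$sample_id)
  if (length(unique(labels)) < 2 || min(table(labels)) < 5) return(NULL)
  sp <- stratified_split(labels, seed = 50)
  tr <- match(sp$train, meta$sample_id)
  da <- suppressMessages(nb_wald_test(
    prevalence_filter(counts[, tr], 0.25), meta[tr, ], label_col, covars))
  sets <- suppressMessages(significant_sets(da, 0.05))
  feats <- c(sets$enriched, sets$depleted)
  if (length(feats) < 2) {
    message(sprintf("[%s %s] fewer than 2 significant training taxa; skipped",
                    st, target))
    return(NULL)
  }
  x <- abundance_features(counts)[, feats, drop = FALSE]
  rep_ <- train_two_stage_rf(x, labels, sp$train, sp$test, seed = 51)
  message(sprintf("[%s %s] %d input taxa -> %d refined; test AUC %.2f (95%% CI %.2f-%.2f)",
                  st, target, length(feats), length(rep_$refined_features),
                  rep_$auc, rep_$ci$lower, rep_$ci$upper))
  rep_
}

for (st in c("cecum", "sigmoid")) {
  classify(st, "disease state", rep(TRUE, nrow(samples)),
           c("gender", "bmi_cat"), "dx")
  classify(st, "behavior B1 vs B2B3", samples$dx == "CD",
           c("gender", "bmi_cat"), "behavior")
  classify(st, "progression", samples$dx == "CD",
           c("gender", "bmi_cat", "behavior"), "progression")
}
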