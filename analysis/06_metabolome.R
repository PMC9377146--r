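#!/usr/bin/env Rscript
# Stage 6: untargeted metabolomics.
#
# Preprocessing in the fixed order (10% prevalence filter, KNN imputation
# with k = 10, IQR filter, natural-log transform, quantile normalization,
# per-batch location/scale standardization), per-feature linear models for
# CD adjusting for gender and obesity, the cholate:deoxycholate log ratio
# on raw intensities, the bai (bile-acid 7-alpha-dehydroxylation) pathway
# abundance in the predicted metagenome, and microbe-metabolite residual
# Spearman correlations for the CD-associated taxa against the two bile
# acids.

library(cdmli)

cohort <- read_cohort("results/cohort")
samples <- cohort$samples
mtb <- cohort$metabolome
tsv <- function(x, f) write.table(x, file.path("results", f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

proc <- preprocess_metabolome(mtb$intensities, samples$batch)
message(sprintf("processed metabolite table: %d of %d features retained",
                nrow(proc), nrow(mtb$intensities)))

pfm <- per_feature_models(proc, samples, "dx", c("gender", "bmi_cat"))
tsv(pfm, "metabolite_dx.tsv")
message(sprintf("%d features differential for CD at q < 0.05",
                sum(pfm$q < 0.05, na.rm = TRUE)))

blr <- bile_log_ratio(mtb$intensities, cohort$truth$cholate_id,
                      cohort$truth$deoxycholate_id, group = samples$dx)
cd <- samples$dx == "CD"
message(sprintf("cholate:deoxycholate log ratio: CD %.2f vs control %.2f (Wilcoxon p = %.2g)",
                mean(blr$log_ratio[cd], na.rm = TRUE),
                mean(blr$log_ratio[!cd], na.rm = TRUE), blr$test$p_value))
tsv(data.frame(sample_id = names(blr$log_ratio),
               log_ratio = blr$log_ratio, dx = samples$dx), "bile_log_ratio.tsv")

bai <- aggregate_bai(cohort$ko)
bt <- wilcoxon_rank_sum(bai[cd], bai[!cd])
message(sprintf("bai pathway relative abundance: CD %.2g vs control %.2g (Wilcoxon p = %.2g)",
                mean(bai[cd]), mean(bai[!cd]), bt$p_value))

# residual correlations of CD-associated taxa with the two bile acids
da <- read.delim("results/da_dx_cecum.tsv")
sets <- significant_sets(da, 0.05)
taxa <- head(c(sets$enriched, sets$depleted), 12)
bile_feats <- intersect(c(cohort$truth$cholate_id, cohort$truth$deoxycholate_id),
                        rownames(proc))
if (length(taxa) >= 1 && length(bile_feats) == 2) {
  cec <- samples$site == "cecum"
  cors <- microbe_metabolite_correlations(
    cohort$counts[taxa, cec, drop = FALSE], proc[bile_feats, cec],
    samples[cec, ], covariates = c("dx", "gender", "age", "bmi_cat"))
  tsv(cors, "microbe_bile_correlations.tsv")
  message(sprintf("%d significant microbe-bile correlations (q < 0.05) among %d pairs",
                  sum(cors$q < 0.05, na.rm = TRUE), nrow(cors)))
}
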