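#!/usr/bin/env Rscript
# Stage 4: polygenic risk score and its microbiome associations.
#
# GRS = sum of per-SNP log odds ratios times risk-allele dosages over the
# 186-variant panel. CD and control strata are analyzed separately (GRS
# analyses in CD adjust additionally for disease behavior): GRS against
# alpha diversity and the cecal dysbiosis index by sequential ANOVA,
# against composition by PERMANOVA, per taxon by NB Wald tests at the
# relaxed q < 0.1 threshold, and the overlap of GRS-associated taxa with
# the CD-associated sets by Fisher's exact test.

library(cdmli)

cohort <- read_cohort("results/cohort")
samples <- cohort$samples
subjects <- cohort$subjects
grs <- setNames(compute_grs(cohort$dosages, cohort$weights),
                rownames(cohort$dosages))
stopifnot(all.equal(unname(grs[subjects$subject_id]), subjects$grs))

wt <- wilcoxon_rank_sum(grs[subjects$subject_id[subjects$dx == "CD"]],
                        grs[subjects$subject_id[subjects$dx == "nonIBD"]])
message(sprintf("GRS: CD median %.2f vs control %.2f (Wilcoxon p = %.2g)",
                median(grs[subjects$subject_id[subjects$dx == "CD"]]),
                median(grs[subjects$subject_id[subjects$dx == "nonIBD"]]),
                wt$p_value))

# cecal dysbiosis index from the CD contrast of stage 3
dys <- read.delim("results/dysbiosis_cecum.tsv")
da <- read.delim("results/da_dx_cecum.tsv")
cd_sets <- significant_sets(da, 0.05)

for (stratum in c("CD", "nonIBD")) {
  subj <- subjects[subjects$dx == stratum, ]
  covars <- c("gender", "age", "bmi_cat", if (stratum == "CD") "behavior")
  idx <- samples$site == "cecum" & samples$subject_id %in% subj$subject_id
  di <- setNames(dys$index[match(samples$sample_id[idx], dys$sample_id)],
                 samples$subject_id[idx])
  res <- grs_associations(
    grs[subj$subject_id], list(dysbiosis = di), subj, covars,
    d = bray_curtis(cohort$counts[, idx]), samples = samples[idx, ],
    counts = prevalence_filter(cohort$counts[, idx], 0.25),
    cd_sets = cd_sets, q_threshold = 0.1, n_perm = 9999, seed = 4)
  message(sprintf("[%s] GRS vs cecal dysbiosis index: p = %.2g",
                  stratum, res$scalar$dysbiosis$p_value))
  message(sprintf("[%s] GRS vs composition (PERMANOVA): p = %.2g", stratum,
                  res$composition$p_value[res$composition$term == "grs"]))
  n_assoc <- length(res$overlap$grs_sets$enriched) +
    length(res$overlap$grs_sets$depleted)
  message(sprintf("[%s] %d GRS-associated taxa (q < 0.1); overlap with CD sets: enriched p = %.2g, depleted p = %.2g",
                  stratum, n_assoc, res$overlap$enriched$p_value,
                  res$overlap$depleted$p_value))
  write.table(res$taxa, file.path("results",
                                  paste0("grs_taxa_", stratum, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
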