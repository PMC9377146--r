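#!/usr/bin/env Rscript
# Stage 2: diversity and biogeography.
#
# Alpha diversity (Chao1, Shannon) on rarefied counts with sequential
# ANOVA adjusted for gender, age and obesity category; Bray-Curtis
# PERMANOVA of CD status per site; PCoA coordinates for plotting; and the
# paired cecum-sigmoid contrasts (per-subject alpha differences and
# paired Bray-Curtis) that probe the biogeographic disruption in CD.

library(cdmli)

cohort <- read_cohort("results/cohort")
samples <- cohort$samples
dir.create("results", showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path("results", f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

depth <- min(colSums(cohort$counts))
rare <- rarefy_counts(cohort$counts, depth, seed = 1)
message("rarefied to ", depth, " reads/sample")
alpha <- alpha_diversity(rare)
alpha <- cbind(alpha, samples[alpha$sample_id,
                              c("subject_id", "site", "dx", "gender",
                                "age", "bmi_cat")])
tsv(alpha, "alpha_diversity.tsv")

for (st in c("cecum", "sigmoid")) {
  sub <- alpha[alpha$site == st, ]
  for (metric in c("chao1", "shannon")) {
    res <- anova_with_covariates(sub[[metric]], sub, "dx",
                                 c("gender", "age", "bmi_cat"))
    message(sprintf("%s %s, CD vs control (adj. gender/age/obesity): F = %.1f, p = %.2g",
                    st, metric, res$statistic, res$p_value))
  }
}

d <- bray_curtis(cohort$counts)
for (st in c("cecum", "sigmoid")) {
  idx <- samples$site == st
  ds <- as.dist(as.matrix(d)[idx, idx])
  pm <- permanova(ds, samples[idx, ], "dx", c("gender", "age", "bmi_cat"),
                  n_perm = 9999, seed = 2)
  message(sprintf("%s PERMANOVA dx: R2 = %.3f, p = %.2g", st,
                  pm$r2[pm$term == "dx"], pm$p_value[pm$term == "dx"]))
  ord <- pcoa(ds, k = 2)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates,
                       dx = samples$dx[idx][match(rownames(ord$coordinates),
                                                  samples$sample_id[idx])])
  tsv(coords, paste0("pcoa_", st, ".tsv"))
  tsv(pm, paste0("permanova_dx_", st, ".tsv"))
}

# paired biogeography: alpha gradient and intra-subject dissimilarity
chao_by_sample <- setNames(alpha$chao1, alpha$sample_id)
pa <- paired_site_contrast(chao_by_sample, samples[samples$sample_id %in%
                                                   alpha$sample_id, ],
                           group_by = "dx", type = "alpha")
message(sprintf("paired cecum-sigmoid Chao1 difference: CD %.1f vs control %.1f (p = %.2g)",
                mean(pa$contrasts$value[pa$contrasts$group == "CD"]),
                mean(pa$contrasts$value[pa$contrasts$group == "nonIBD"]),
                pa$test$p_value))
pb <- paired_site_contrast(d, samples, group_by = "dx", type = "beta")
message(sprintf("paired Bray-Curtis: CD %.3f vs control %.3f (p = %.2g)",
                mean(pb$contrasts$value[pb$contrasts$group == "CD"]),
                mean(pb$contrasts$value[pb$contrasts$group == "nonIBD"]),
                pb$test$p_value))
tsv(pa$contrasts, "paired_chao1.tsv")
tsv(pb$contrasts, "paired_bray_curtis.tsv")
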