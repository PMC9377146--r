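#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a synthetic mucosal-luminal-interface cohort at the real
# study's arm sizes (88 CD in endoscopic remission, 110 non-IBD screening
# controls; two lavage samples per subject, cecum and sigmoid) with the
# generator defaults: planted CD enrichment/depletion, a weaker
# overlapping obesity effect, GRS-coupled taxa, CD-specific cecum-sigmoid
# divergence, progression-depleted taxa, a 186-SNP risk panel, and an
# LC-MS table with planted cholate (+) / deoxycholate (-) shifts.
# Everything downstream (02-06) reads the files written here.

library(cdmli)

out <- "results/cohort"
cfg <- cohort_config(n_cd = 88, n_control = 110, seed = 20260925 %% 1e6)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

message(sprintf("cohort: %d subjects (%d CD / %d control), %d taxa x %d samples",
                nrow(cohort$subjects), sum(cohort$subjects$dx == "CD"),
                sum(cohort$subjects$dx == "nonIBD"),
                nrow(cohort$counts), ncol(cohort$counts)))
message(sprintf("median GRS: CD %.2f vs control %.2f",
                median(cohort$subjects$grs[cohort$subjects$dx == "CD"]),
                median(cohort$subjects$grs[cohort$subjects$dx == "nonIBD"])))
message(sprintf("metabolite table: %d features, %.1f%% missing",
                nrow(cohort$metabolome$intensities),
                100 * mean(is.na(cohort$metabolome$intensities))))
message("written to ", out)
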