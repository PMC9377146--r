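#' Polygenic genetic risk score
#'
#' `GRS = sum_i beta_i G_i`: per-subject weighted sum of risk-allele
#' dosages, weights being per-SNP log odds ratios. The join on SNP id is
#' order-insensitive. Missing dosages are an error by default; with
#' `missing_policy = "mean"` they are imputed by the SNP's mean dosage
#' across subjects (2 x allele frequency), with a message.
#'
#' @param dosages subjects x SNPs matrix with entries in 0/1/2.
#' @param weights data.frame with `snp_id` and `beta`.
#' @param missing_policy `"error"` (default) or `"mean"`.
#' @return named per-subject numeric vector.
#' @export
compute_grs <- function(dosages, weights, missing_policy = c("error", "mean")) {
  missing_policy <- match.arg(missing_policy)
  if (anyDuplicated(weights$snp_id)) stop("compute_grs: duplicated SNP ids in weights")
  absent <- setdiff(weights$snp_id, colnames(dosages))
  if (length(absent))
    stop("compute_grs: SNPs missing from dosages: ", paste(absent, collapse = ", "))
  G <- dosages[, weights$snp_id, drop = FALSE]
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) stop("compute_grs: dosages must be 0, 1 or 2")
  if (anyNA(G)) {
    if (missing_policy == "error")
      stop("compute_grs: missing dosage entries (set missing_policy = 'mean' to impute)")
    message("compute_grs: mean-imputing ", sum(is.na(G)), " missing dosage entries")
    for (j in which(colSums(is.na(G)) > 0)) {
      G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  drop(G %*% weights$beta)[rownames(dosages)]
}

#' Fisher overlap test of two taxon sets
#'
#' Tests whether two taxon sets (e.g. GRS-associated and CD-associated)
#' overlap more than expected by chance, with the tested-taxon universe
#' (post prevalence filter) as background.
#'
#' @param set_a,set_b character vectors of taxon ids.
#' @param universe all tested taxon ids.
#' @return list with `p_value`, `odds_ratio`, `table`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' GRS-microbiome associations within a disease stratum
#'
#' Runs the genetic-risk association battery on one stratum (CD or
#' control, analyzed separately): continuous GRS tested last in a
#' covariate-adjusted sequential ANOVA against scalar targets (alpha
#' diversity, dysbiosis index), in a covariate-adjusted PERMANOVA against
#' composition, and per taxon via the NB Wald test at a relaxed q
#' threshold (0.1), with Fisher overlap of the GRS-associated taxa against
#' supplied CD-associated sets. For CD strata include `"behavior"` among
#' the covariates.
#'
#' @param grs named per-subject GRS vector (nonzero variance required).
#' @param targets named list of per-subject numeric vectors (e.g. `chao1`,
#'   `shannon`, `dysbiosis`), names aligned with `subjects$subject_id`.
#' @param subjects subject-level covariate data.frame.
#' @param covariates adjustment covariates (e.g. gender, age, bmi_cat,
#'   behavior for CD).
#' @param d optional `dist` over the stratum's samples for the PERMANOVA
#'   stage, with `samples` giving their metadata (needs `subject_id`).
#' @param samples per-sample metadata matching `d`.
#' @param counts optional taxa x samples matrix for the per-taxon stage.
#' @param cd_sets optional `taxon_sets` of the CD contrast for the overlap
#'   stage.
#' @param q_threshold q cutoff for GRS-associated taxa (default 0.1).
#' @param n_perm PERMANOVA permutations.
#' @param seed seed for the PERMANOVA stage.
#' @return list with `scalar` (per-target ANOVA results), `composition`
#'   (PERMANOVA table), `taxa` (`da_result`), `overlap` (Fisher tests
#'   against enriched and depleted CD sets).
#' @export
grs_associations <- function(grs, targets, subjects, covariates = c("gender", "age"),
                             d = NULL, samples = NULL, counts = NULL,
                             cd_sets = NULL, q_threshold = 0.1,
                             n_perm = 999, seed = NULL) {
  if (stats::sd(grs, na.rm = TRUE) == 0)
    stop("grs_associations: GRS has zero variance")
  if (nrow(subjects) < length(covariates) + 2)
    stop("grs_associations: stratum too small for the covariate set")
  subjects$grs <- grs[subjects$subject_id]
  scalar <- lapply(targets, function(y) {
    anova_with_covariates(y[subjects$subject_id], subjects, "grs", covariates)
  })
  composition <- NULL
  if (!is.null(d)) {
    stopifnot(!is.null(samples))
    samples$grs <- grs[samples$subject_id]
    composition <- permanova(d, samples, "grs", covariates,
                             n_perm = n_perm, seed = seed)
  }
  taxa <- NULL
  overlap <- NULL
  if (!is.null(counts)) {
    stopifnot(!is.null(samples))
    samples$grs <- grs[samples$subject_id]
    taxa <- nb_wald_test(counts, samples, "grs", covariates)
    if (!is.null(cd_sets)) {
      grs_sets <- suppressMessages(
        significant_sets(taxa, q_threshold = q_threshold, contrast = "grs"))
      universe <- taxa$taxon_id[taxa$converged]
      overlap <- list(
        enriched = fisher_overlap(grs_sets$enriched, cd_sets$enriched, universe),
        depleted = fisher_overlap(grs_sets$depleted, cd_sets$depleted, universe),
        grs_sets = grs_sets)
    }
  }
  list(scalar = scalar, composition = composition, taxa = taxa,
       overlap = overlap)
}
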