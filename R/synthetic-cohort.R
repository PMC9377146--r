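#' Configuration for a synthetic MLI cohort
#'
#' Builds and validates the parameter set for the synthetic-cohort generator.
#' The generator emulates the structure of a paired cecum/sigmoid
#' mucosal-luminal interface (MLI) study of Crohn's disease (CD) in
#' endoscopic remission versus non-IBD controls: negative-binomial ASV
#' counts with planted CD / obesity / genetic-risk / site / progression
#' effects on log-scale latent abundances, subject-level random effects that
#' control intra-subject cecum-sigmoid similarity, log-normal library sizes,
#' biallelic dosage genotypes with log-odds-ratio weights, and log-normal
#' LC-MS intensities with intensity-dependent missingness plus planted
#' cholate/deoxycholate shifts.
#'
#' Planted effects are expressed as log2 fold changes on latent abundances
#' which are renormalized through a softmax, so realized fold changes on
#' relative abundances are approximate (compositional coupling); downstream
#' tests tolerate this.
#'
#' @param n_cd,n_control arm sizes (subjects). Either may be 0; the total
#'   must be positive.
#' @param n_taxa,n_snps,n_metabolites feature-space sizes. `n_snps`
#'   defaults to 186, the size of the CD risk panel the genetic risk score
#'   is built from.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   per-sample sequencing depth. The default depth scale (5e4) is a desk
#'   scale chosen for testability, not the depth of a real HiSeq run.
#' @param baseline_abundance_log_mean,baseline_abundance_log_sd normal
#'   parameters of per-taxon baseline log abundance.
#' @param dispersion_shape,dispersion_mean per-taxon NB dispersions are drawn
#'   Gamma(shape = `dispersion_shape`, mean = `dispersion_mean`).
#' @param effect_sets named list of data.frames `data.frame(taxon, lfc)`
#'   with components `cd_enriched`, `cd_depleted`, `obesity`, `grs_coupled`,
#'   `site`, `progression`. `NULL` uses [default_effect_sets()].
#' @param site_divergence_sd named vector `c(CD = , nonIBD = )`: SD of
#'   per-subject per-taxon cecum-sigmoid effects; a larger CD value plants
#'   CD-specific biogeographic divergence.
#' @param subject_effect_sd SD of subject-level random effects shared by a
#'   subject's two samples (controls paired similarity).
#' @param grs_effect_slope log2 fold change per GRS unit applied to the
#'   `grs_coupled` taxa.
#' @param grs_case_offset expected upward shift of the CD arm's mean GRS.
#' @param weight_log_or_sd SD of the per-SNP log odds-ratio weights.
#' @param maf_range range of uniform minor-allele frequencies.
#' @param behavior_split probability a CD subject is Montreal B1
#'   (non-stricturing/non-penetrating) rather than B2/B3.
#' @param progression_subset fraction of CD subjects with follow-up
#'   (progression label available).
#' @param progression_fraction fraction of followed CD subjects who progress.
#' @param missingness_intercept,missingness_slope logistic
#'   missing-not-at-random model for LC-MS entries:
#'   P(missing) = plogis(intercept - slope * log intensity).
#' @param bile_shift_log2 planted CD shift (log2 units) applied + to the
#'   cholate-like feature and - to the deoxycholate-like feature.
#' @param metabolite_log_sd residual SD of log intensities.
#' @param n_batches,batch_location_sd,batch_scale_sd LC-MS batch structure:
#'   per-batch additive shift (on log scale) and multiplicative spread of
#'   the residual SD.
#' @param n_background_kos number of non-bai KEGG orthologies in the
#'   predicted-metagenome table.
#' @param seed integer; fixes all randomness end-to-end.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cd = 50, n_control = 50,
                          n_taxa = 120, n_snps = 186, n_metabolites = 300,
                          library_size_log_mean = log(5e4),
                          library_size_log_sd = 0.25,
                          baseline_abundance_log_mean = 0,
                          baseline_abundance_log_sd = 1.5,
                          dispersion_shape = 4, dispersion_mean = 0.3,
                          effect_sets = NULL,
                          site_divergence_sd = c(CD = 0.8, nonIBD = 0.25),
                          subject_effect_sd = 0.4,
                          grs_effect_slope = 1,
                          grs_case_offset = 0.5,
                          weight_log_or_sd = 0.15,
                          maf_range = c(0.05, 0.5),
                          behavior_split = 0.34,
                          progression_subset = 0.8,
                          progression_fraction = 0.44,
                          missingness_intercept = 3,
                          missingness_slope = 0.6,
                          bile_shift_log2 = 1.5,
                          metabolite_log_sd = 0.6,
                          n_batches = 2,
                          batch_location_sd = 0.4,
                          batch_scale_sd = 0.15,
                          n_background_kos = 40,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$effect_sets)) cfg$effect_sets <- default_effect_sets(n_taxa)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default planted effect sets
#'
#' Disjoint taxon blocks sized for testability (the study the generator
#' emulates does not report per-taxon effect magnitudes): 8 CD-enriched and
#' 12 CD-depleted taxa at |log2FC| = 3 (depletion broader than enrichment,
#' as observed in CD cohorts); an obesity effect on an overlapping subset at
#' half magnitude; GRS-coupled taxa as a subset of the CD-enriched block;
#' 6 consistent cecum/sigmoid biogeography taxa; 3 progression-depleted
#' taxa, the first of which plays the role of the dominant
#' Parasutterella-like progression marker.
#'
#' @param n_taxa total number of taxa (must be at least 30).
#' @return named list of `data.frame(taxon, lfc)`.
#' @export
default_effect_sets <- function(n_taxa) {
  stopifnot(n_taxa >= 30)
  list(
    cd_enriched = data.frame(taxon = 1:8, lfc = 3),
    cd_depleted = data.frame(taxon = 9:20, lfc = -3),
    obesity     = data.frame(taxon = c(1:4, 9:14), lfc = c(rep(1.5, 4), rep(-1.5, 6))),
    grs_coupled = data.frame(taxon = 1:6, lfc = 1),
    site        = data.frame(taxon = 21:26, lfc = c(1, 1, 1, -1, -1, -1)),
    progression = data.frame(taxon = 27:29, lfc = c(-2.5, -2, -2))
  )
}

#' Null cohort configuration for calibration studies
#'
#' A configuration with every planted effect set empty and every latent
#' heterogeneity term (subject random effects, site divergence, GRS
#' coupling, metabolite disease shifts) switched off, so that counts are
#' exactly negative binomial given the library size and group labels carry
#' no signal. This is the reference condition for type-I-error calibration
#' of the downstream tests: under it, rejection rates estimate the tests'
#' size rather than their robustness to latent structure.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  empty <- data.frame(taxon = integer(), lfc = numeric())
  defaults <- list(
    effect_sets = list(cd_enriched = empty, cd_depleted = empty,
                       obesity = empty, grs_coupled = empty,
                       site = empty, progression = empty),
    site_divergence_sd = c(CD = 0, nonIBD = 0),
    subject_effect_sd = 0,
    grs_effect_slope = 0,
    grs_case_offset = 0,
    bile_shift_log2 = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

validate_cohort_config <- function(cfg) {
  need_pos <- c("n_taxa", "n_snps", "n_metabolites", "n_batches")
  for (f in need_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("cohort_config: field '", f, "' must be a positive integer")
  }
  for (f in c("n_cd", "n_control")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("cohort_config: field '", f, "' must be a non-negative integer")
  }
  if (cfg$n_cd + cfg$n_control < 1)
    stop("cohort_config: field 'n_cd'/'n_control' must total at least one subject")
  for (f in c("library_size_log_sd", "baseline_abundance_log_sd",
              "dispersion_shape", "dispersion_mean", "subject_effect_sd",
              "metabolite_log_sd")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop("cohort_config: field '", f, "' must be finite and non-negative")
  }
  if (!all(c("CD", "nonIBD") %in% names(cfg$site_divergence_sd)))
    stop("cohort_config: field 'site_divergence_sd' needs named entries CD and nonIBD")
  for (nm in names(cfg$effect_sets)) {
    es <- cfg$effect_sets[[nm]]
    if (!is.data.frame(es) || !all(c("taxon", "lfc") %in% names(es)))
      stop("cohort_config: field 'effect_sets$", nm, "' must have columns taxon, lfc")
    if (nrow(es) && (any(es$taxon < 1) || any(es$taxon > cfg$n_taxa)))
      stop("cohort_config: field 'effect_sets$", nm, "' has taxon indices outside 1..n_taxa")
    if (!all(is.finite(es$lfc)))
      stop("cohort_config: field 'effect_sets$", nm, "' has non-finite fold changes")
  }
  for (f in c("behavior_split", "progression_subset", "progression_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("cohort_config: field '", f, "' must lie in [0, 1]")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("cohort_config: field 'seed' must be a single integer")
  invisible(cfg)
}

set_seed_if <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Simulate subject-level metadata
#'
#' One row per subject: disease status (CD / nonIBD), gender, age, BMI
#' category (`lt25`, `25to30`, `gt30` -- cutoffs 25 and 30 for overweight
#' and obese), Montreal behavior (B1 vs B2B3, CD only) and a progression
#' label for the followed subset of CD subjects. Demographic distributions
#' loosely follow a screening-colonoscopy control arm (older, mostly
#' overweight/obese, majority male) against a younger, leaner CD arm.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return data.frame with one row per subject.
#' @export
simulate_metadata <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set_seed_if(seed)
  n <- config$n_cd + config$n_control
  dx <- rep(c("CD", "nonIBD"), c(config$n_cd, config$n_control))
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    dx = dx,
    stringsAsFactors = FALSE
  )
  p_male <- ifelse(dx == "CD", 0.47, 0.70)
  subjects$gender <- ifelse(stats::runif(n) < p_male, "male", "female")
  age_mu <- ifelse(dx == "CD", 41, 64)
  age_sd <- ifelse(dx == "CD", 12, 10)
  subjects$age <- round(pmin(pmax(stats::rnorm(n, age_mu, age_sd), 18), 90))
  bmi_levels <- c("lt25", "25to30", "gt30")
  p_bmi <- matrix(rep(c(0.35, 0.40, 0.25), each = n), n, 3)
  p_bmi[dx == "CD", ] <- rep(c(0.60, 0.25, 0.15), each = sum(dx == "CD"))
  subjects$bmi_cat <- vapply(seq_len(n), function(i)
    sample(bmi_levels, 1, prob = p_bmi[i, ]), character(1))
  subjects$behavior <- NA_character_
  is_cd <- dx == "CD"
  subjects$behavior[is_cd] <- ifelse(
    stats::runif(sum(is_cd)) < config$behavior_split, "B1", "B2B3")
  subjects$progression <- NA_character_
  followed <- is_cd & stats::runif(n) < config$progression_subset
  subjects$progression[followed] <- ifelse(
    stats::runif(sum(followed)) < config$progression_fraction,
    "progressor", "nonprogressor")
  subjects$grs <- NA_real_
  subjects
}

build_sample_frame <- function(config, subjects, seed = NULL) {
  set_seed_if(seed)
  n <- nrow(subjects)
  samples <- data.frame(
    sample_id = paste0(rep(subjects$subject_id, each = 2), c("_cecum", "_sigmoid")),
    subject_id = rep(subjects$subject_id, each = 2),
    site = rep(c("cecum", "sigmoid"), n),
    stringsAsFactors = FALSE
  )
  samples <- cbind(samples,
                   subjects[rep(seq_len(n), each = 2),
                            setdiff(names(subjects), "subject_id"), drop = FALSE])
  rownames(samples) <- samples$sample_id
  samples$batch <- paste0("batch", sample(rep_len(seq_len(config$n_batches),
                                                  nrow(samples))))
  samples
}

#' Simulate paired cecum/sigmoid ASV count tables
#'
#' Counts for taxon t in sample s are negative binomial with mean
#' `library_size * softmax_t(baseline + planted effects + site effect +
#' subject random effect)` and per-taxon dispersion drawn from a gamma.
#' Planted effects (CD enrichment/depletion, obesity, GRS coupling,
#' biogeography, progression) act on the log-scale latent abundances; CD
#' subjects draw their per-taxon cecum-sigmoid effects with a larger SD
#' than controls, planting CD-specific paired divergence. If `subjects$grs`
#' is all-NA the GRS coupling term is skipped.
#'
#' @param config a [cohort_config()].
#' @param subjects output of [simulate_metadata()] (optionally with a `grs`
#'   column filled in).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `counts` (taxa x samples integer matrix), `samples`
#'   (per-sample metadata incl. subject, site, batch) and `truth`
#'   (ground-truth record: effect sets, baselines, dispersions, per-subject
#'   site deltas).
#' @export
simulate_counts <- function(config, subjects, seed = config$seed) {
  validate_cohort_config(config)
  if (nrow(subjects) == 0) stop("simulate_counts: 'subjects' is empty")
  set_seed_if(seed)
  nt <- config$n_taxa
  taxa <- sprintf("ASV%03d", seq_len(nt))
  samples <- build_sample_frame(config, subjects)
  ns <- nrow(samples)

  baseline <- stats::rnorm(nt, config$baseline_abundance_log_mean,
                           config$baseline_abundance_log_sd)
  dispersions <- stats::rgamma(nt, shape = config$dispersion_shape,
                               rate = config$dispersion_shape / config$dispersion_mean)
  names(baseline) <- names(dispersions) <- taxa

  nsub <- nrow(subjects)
  subj_eff <- matrix(stats::rnorm(nt * nsub, 0, config$subject_effect_sd), nt, nsub)
  site_sd <- config$site_divergence_sd[ifelse(subjects$dx == "CD", "CD", "nonIBD")]
  site_delta <- matrix(stats::rnorm(nt * nsub), nt, nsub) *
    rep(site_sd, each = nt)
  colnames(subj_eff) <- colnames(site_delta) <- subjects$subject_id

  es <- config$effect_sets
  ln2 <- log(2)
  grs <- subjects$grs
  use_grs <- !all(is.na(grs))
  if (use_grs) grs[is.na(grs)] <- 0

  loglam <- matrix(baseline, nt, ns)
  for (j in seq_len(ns)) {
    sub_idx <- match(samples$subject_id[j], subjects$subject_id)
    eff <- numeric(nt)
    if (samples$dx[j] == "CD") {
      eff[es$cd_enriched$taxon] <- eff[es$cd_enriched$taxon] + es$cd_enriched$lfc * ln2
      eff[es$cd_depleted$taxon] <- eff[es$cd_depleted$taxon] + es$cd_depleted$lfc * ln2
      if (!is.na(samples$progression[j]) && samples$progression[j] == "progressor")
        eff[es$progression$taxon] <- eff[es$progression$taxon] + es$progression$lfc * ln2
    }
    bmi_mult <- switch(samples$bmi_cat[j], gt30 = 1, `25to30` = 0.5, 0)
    if (bmi_mult > 0)
      eff[es$obesity$taxon] <- eff[es$obesity$taxon] + bmi_mult * es$obesity$lfc * ln2
    if (use_grs && nrow(es$grs_coupled))
      eff[es$grs_coupled$taxon] <- eff[es$grs_coupled$taxon] +
        config$grs_effect_slope * grs[sub_idx] * es$grs_coupled$lfc * ln2
    site_sign <- if (samples$site[j] == "cecum") 0.5 else -0.5
    eff[es$site$taxon] <- eff[es$site$taxon] +
      es$site$lfc * ln2 * (if (samples$site[j] == "cecum") 1 else 0)
    loglam[, j] <- loglam[, j] + eff + subj_eff[, sub_idx] +
      site_sign * site_delta[, sub_idx]
  }

  lib <- stats::rlnorm(ns, config$library_size_log_mean, config$library_size_log_sd)
  counts <- matrix(0L, nt, ns, dimnames = list(taxa, samples$sample_id))
  for (j in seq_len(ns)) {
    p <- exp(loglam[, j] - max(loglam[, j]))
    p <- p / sum(p)
    mu <- lib[j] * p
    counts[, j] <- stats::rnbinom(nt, mu = mu, size = 1 / pmax(dispersions, 1e-8))
  }

  truth <- list(
    effect_sets = es,
    taxa = taxa,
    baseline = baseline,
    dispersions = dispersions,
    library_sizes = stats::setNames(lib, samples$sample_id),
    site_divergence_sd = config$site_divergence_sd,
    grs_effect_slope = config$grs_effect_slope,
    cd_enriched = taxa[es$cd_enriched$taxon],
    cd_depleted = taxa[es$cd_depleted$taxon],
    grs_coupled = taxa[es$grs_coupled$taxon],
    progression_depleted = taxa[es$progression$taxon]
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate biallelic genotypes and SNP weights
#'
#' Dosages are drawn binomial(2, maf) per SNP; weights are per-SNP log odds
#' ratios drawn from a centered normal. CD subjects' risk-allele
#' probabilities are tilted along the weight vector so the expected CD
#' minus control GRS difference equals `grs_case_offset`.
#'
#' @param config a [cohort_config()].
#' @param subjects subject metadata.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `dosages` (subjects x SNPs matrix of 0/1/2) and
#'   `weights` (data.frame snp_id, beta, maf).
#' @export
simulate_genotypes <- function(config, subjects, seed = config$seed) {
  validate_cohort_config(config)
  stopifnot(config$n_snps >= 1)
  set_seed_if(seed)
  m <- config$n_snps
  snp_id <- sprintf("rs%05d", seq_len(m))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  beta <- stats::rnorm(m, 0, config$weight_log_or_sd)
  # tilt chosen so E[GRS | CD] - E[GRS | control] = grs_case_offset:
  # d E[sum beta G] / d c = sum 2 maf (1 - maf) beta^2 at c = 0
  denom <- sum(2 * maf * (1 - maf) * beta^2)
  tilt <- if (denom > 0) config$grs_case_offset / denom else 0
  n <- nrow(subjects)
  dosages <- matrix(0L, n, m, dimnames = list(subjects$subject_id, snp_id))
  for (i in seq_len(n)) {
    p <- if (subjects$dx[i] == "CD")
      stats::plogis(stats::qlogis(maf) + tilt * beta) else maf
    dosages[i, ] <- stats::rbinom(m, 2, p)
  }
  list(dosages = dosages,
       weights = data.frame(snp_id = snp_id, beta = beta, maf = maf,
                            stringsAsFactors = FALSE))
}

#' Simulate an untargeted LC-MS metabolite table
#'
#' Log-normal intensities per feature and sample. The first two features
#' act as cholate and deoxycholate and receive opposite planted CD shifts
#' of `bile_shift_log2` log2 units (+ cholate, - deoxycholate). Each batch
#' receives an additive log-scale location shift and a multiplicative
#' residual-scale factor. Entries are then set missing with probability
#' `plogis(missingness_intercept - missingness_slope * log intensity)`, so
#' missingness is intensity-dependent (missing-not-at-random, standard
#' LC-MS behavior).
#'
#' @param config a [cohort_config()].
#' @param samples per-sample metadata (needs `sample_id`, `dx`, `batch`);
#'   the frame produced by [simulate_counts()] or [simulate_cohort()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `intensities` (features x samples, NA = missing),
#'   `features` (feature_id, mz, rt, mode), `complete` (pre-missingness
#'   matrix) and `truth` (`cholate_id`, `deoxycholate_id`, planted shift).
#' @export
simulate_metabolome <- function(config, samples, seed = config$seed) {
  validate_cohort_config(config)
  stopifnot(config$n_metabolites >= 2)
  if (is.null(samples$batch))
    stop("simulate_metabolome: 'samples' needs a batch column")
  set_seed_if(seed)
  nf <- config$n_metabolites
  ns <- nrow(samples)
  feature_id <- sprintf("M%04d", seq_len(nf))
  cholate_id <- feature_id[1]
  deoxycholate_id <- feature_id[2]
  mu_f <- stats::rnorm(nf, 10, 1.5)
  batches <- sort(unique(samples$batch))
  b_loc <- stats::setNames(stats::rnorm(length(batches), 0, config$batch_location_sd),
                           batches)
  b_scale <- stats::setNames(exp(stats::rnorm(length(batches), 0, config$batch_scale_sd)),
                             batches)
  ln2 <- log(2)
  shift <- numeric(nf)
  shift[1] <- config$bile_shift_log2 * ln2
  shift[2] <- -config$bile_shift_log2 * ln2
  is_cd <- as.numeric(samples$dx == "CD")
  logx <- matrix(mu_f, nf, ns) +
    outer(shift, is_cd) +
    matrix(rep(b_loc[samples$batch], each = nf), nf, ns) +
    matrix(stats::rnorm(nf * ns, 0, config$metabolite_log_sd), nf, ns) *
      rep(b_scale[samples$batch], each = nf)
  x <- exp(logx)
  dimnames(x) <- list(feature_id, samples$sample_id)
  p_miss <- stats::plogis(config$missingness_intercept -
                          config$missingness_slope * logx)
  miss <- matrix(stats::runif(nf * ns), nf, ns) < p_miss
  xm <- x
  xm[miss] <- NA_real_
  features <- data.frame(
    feature_id = feature_id,
    mz = stats::runif(nf, 50, 1200),
    rt = stats::runif(nf, 0.5, 13),
    mode = sample(c("pos", "neg"), nf, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(intensities = xm, complete = x, features = features,
       truth = list(cholate_id = cholate_id,
                    deoxycholate_id = deoxycholate_id,
                    bile_shift_log2 = config$bile_shift_log2))
}

#' Simulate a predicted-metagenome KEGG-orthology table
#'
#' Plays the role of a metagenome-prediction step: KO relative abundance is
#' the taxon relative-abundance matrix multiplied by a taxon-to-KO incidence
#' (copy-number) matrix, renormalized per sample. The six bile-acid
#' 7-alpha-dehydroxylation orthologies (baiB K15868, baiA K15869, baiCD
#' K15870, baiF K15871, baiE K15872, baiN K07007) are carried by a subset of
#' the CD-depleted taxa, so the planted CD depletion propagates to the bai
#' pathway.
#'
#' @param config a [cohort_config()].
#' @param counts taxa x samples count matrix.
#' @param truth ground-truth record from [simulate_counts()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param normalize renormalize KO abundances per sample (default TRUE).
#' @return list with `ko` (KO x samples relative abundances), `incidence`
#'   (taxa x KO copy numbers) and `bai_carriers` (taxon ids).
#' @export
simulate_ko_table <- function(config, counts, truth, seed = NULL,
                              normalize = TRUE) {
  if (!identical(rownames(counts), truth$taxa))
    stop("simulate_ko_table: taxon sets of 'counts' and 'truth' differ")
  set_seed_if(seed)
  bai <- bai_ko_ids()
  n_bg <- config$n_background_kos
  kos <- c(bai, sprintf("K%05d", 90000 + seq_len(n_bg)))
  nt <- nrow(counts)
  incidence <- matrix(0, nt, length(kos), dimnames = list(rownames(counts), kos))
  carriers <- truth$cd_depleted[seq_len(min(4, length(truth$cd_depleted)))]
  incidence[carriers, bai] <- 1
  for (k in seq_along(kos)[-seq_along(bai)]) {
    carrier_taxa <- sample(rownames(counts), min(10, nt))
    incidence[carrier_taxa, k] <- 1
  }
  relab <- sweep(counts, 2, colSums(counts), "/")
  ko <- t(incidence) %*% relab
  if (normalize) {
    tot <- colSums(ko)
    tot[tot == 0] <- 1
    ko <- sweep(ko, 2, tot, "/")
  }
  list(ko = ko, incidence = incidence, bai_carriers = carriers)
}

#' The six bai-operon KEGG orthology ids
#' @return character vector of KO ids.
#' @export
bai_ko_ids <- function() {
  c(baiB = "K15868", baiA = "K15869", baiCD = "K15870",
    baiF = "K15871", baiE = "K15872", baiN = "K07007")
}

#' Simulate a complete synthetic cohort
#'
#' Runs the generator stages in order under a single seed: metadata,
#' genotypes (GRS attached to subjects before counts so GRS-coupled taxon
#' effects can be planted), paired counts, metabolome, KO table.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects`, `samples`, `counts`, `truth`, `dosages`,
#'   `weights`, `metabolome`, `ko`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(as.integer(config$seed))
  subjects <- simulate_metadata(config, seed = NULL)
  geno <- simulate_genotypes(config, subjects, seed = NULL)
  subjects$grs <- compute_grs(geno$dosages, geno$weights)[subjects$subject_id]
  cnt <- simulate_counts(config, subjects, seed = NULL)
  mtb <- simulate_metabolome(config, cnt$samples, seed = NULL)
  ko <- simulate_ko_table(config, cnt$counts, cnt$truth, seed = NULL)
  truth <- cnt$truth
  truth$cholate_id <- mtb$truth$cholate_id
  truth$deoxycholate_id <- mtb$truth$deoxycholate_id
  truth$bile_shift_log2 <- mtb$truth$bile_shift_log2
  truth$bai_carriers <- ko$bai_carriers
  list(subjects = subjects, samples = cnt$samples, counts = cnt$counts,
       truth = truth, dosages = geno$dosages, weights = geno$weights,
       metabolome = mtb, ko = ko, config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Serializes counts (TSV, taxa rows x sample columns), sample metadata,
#' dosages, weights, metabolite intensities with feature annotations, the
#' KO table and a JSON ground-truth sidecar into a directory.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, col.names = NA)
  w(cohort$counts, "counts.tsv")
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  w(cohort$dosages, "dosages.tsv")
  utils::write.table(cohort$weights, file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mtb <- cbind(cohort$metabolome$features,
               as.data.frame(cohort$metabolome$intensities))
  utils::write.table(mtb, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  w(cohort$ko$ko, "ko.tsv")
  truth <- cohort$truth
  truth$effect_sets <- lapply(truth$effect_sets, as.list)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return list with `counts`, `samples`, `subjects`, `dosages`, `weights`,
#'   `metabolome` (`intensities`, `features`), `ko`, `truth`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, rn = TRUE) {
    x <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                           row.names = if (rn) 1 else NULL,
                           stringsAsFactors = FALSE)
    x
  }
  counts <- as.matrix(rd("counts.tsv"))
  samples <- rd("samples.tsv", rn = FALSE)
  rownames(samples) <- samples$sample_id
  subjects <- rd("subjects.tsv", rn = FALSE)
  mtb_raw <- rd("metabolites.tsv", rn = FALSE)
  ann_cols <- c("feature_id", "mz", "rt", "mode")
  intensities <- as.matrix(mtb_raw[, setdiff(names(mtb_raw), ann_cols)])
  rownames(intensities) <- mtb_raw$feature_id
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  truth$effect_sets <- lapply(truth$effect_sets, as.data.frame)
  list(counts = counts, samples = samples, subjects = subjects,
       dosages = as.matrix(rd("dosages.tsv")),
       weights = rd("weights.tsv", rn = FALSE),
       metabolome = list(intensities = intensities,
                         features = mtb_raw[, ann_cols]),
       ko = as.matrix(rd("ko.tsv")),
       truth = truth)
}
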