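#' Pipeline run configuration
#'
#' Collects thresholds, seeds and sizes for an end-to-end run on a
#' synthetic cohort. Defaults mirror the analysis conventions of the
#' workflow: DA q threshold 0.05 (0.1 for GRS), prevalence filters 0.25
#' (ASVs) / 0.10 (metabolite features), abundance floor 1e-5, importance
#' cut 2. `n_perm` defaults to a test-scale 999; "paper mode" analyses use
#' 1e5 permutations via the `n_perm` field.
#'
#' @param cohort a [cohort_config()].
#' @param out_dir output directory.
#' @param n_perm PERMANOVA permutations.
#' @param q_threshold,grs_q_threshold DA significance cutoffs.
#' @param abund_threshold mean normalized relative-abundance floor.
#' @param prevalence,metabolite_prevalence prevalence filters.
#' @param importance_cut RF importance z cut.
#' @param n_boot bootstrap resamples for AUC CIs.
#' @param rarefaction_depth alpha-diversity rarefaction depth (NULL = the
#'   minimum sample total).
#' @param seed master seed (defaults to the cohort seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = tempfile("mli_run_"),
                       n_perm = 999, q_threshold = 0.05,
                       grs_q_threshold = 0.1, abund_threshold = 1e-5,
                       prevalence = 0.25, metabolite_prevalence = 0.10,
                       importance_cut = 2, n_boot = 500,
                       rarefaction_depth = NULL, seed = cohort$seed) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the end-to-end MLI analysis on a synthetic cohort
#'
#' Executes, in order: cohort simulation; alpha diversity on rarefied
#' counts with covariate-adjusted ANOVA; Bray-Curtis PERMANOVA and paired
#' cecum-sigmoid biogeography contrasts; per-site differential abundance,
#' significant sets and dysbiosis indices; GRS associations per disease
#' stratum; the two-stage random-forest disease classifier per site; the
#' metabolome stage (preprocessing, per-feature models, bile log ratio,
#' bai-pathway aggregation). Writes per-stage TSVs plus a machine-readable
#' `summary.json` into `out_dir` and logs each stage's dimensions. Stage
#' failures abort with the stage named; previously written outputs are
#' retained.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the summary list, invisibly; written to
#'   `file.path(config$out_dir, "summary.json")`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(seed = config$seed)
  tsv <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  say("simulated cohort: ", nrow(cohort$subjects), " subjects, ",
      nrow(cohort$counts), " taxa x ", ncol(cohort$counts), " samples")
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  samples <- cohort$samples
  set.seed(as.integer(config$seed) + 1L)

  ## -- diversity ---------------------------------------------------------
  depth <- config$rarefaction_depth
  if (is.null(depth)) depth <- min(colSums(cohort$counts))
  rare <- stage("rarefy", suppressMessages(
    rarefy_counts(cohort$counts, depth, seed = NULL)))
  alpha <- stage("alpha_diversity", alpha_diversity(rare))
  alpha <- cbind(alpha, samples[match(alpha$sample_id, samples$sample_id),
                                c("subject_id", "site", "dx", "gender", "age",
                                  "bmi_cat")])
  tsv(alpha, "alpha_diversity.tsv")
  alpha_tests <- lapply(c(chao1 = "chao1", shannon = "shannon"), function(metric)
    lapply(c(cecum = "cecum", sigmoid = "sigmoid"), function(st) {
      sub <- alpha[alpha$site == st, ]
      anova_with_covariates(sub[[metric]], sub, "dx",
                            c("gender", "age", "bmi_cat"))
    }))
  summary$alpha_dx_p <- lapply(alpha_tests, lapply, `[[`, "p_value")

  d_all <- stage("bray_curtis", bray_curtis(cohort$counts))
  perma <- lapply(c(cecum = "cecum", sigmoid = "sigmoid"), function(st) {
    idx <- samples$site == st
    ds <- stats::as.dist(as.matrix(d_all)[idx, idx])
    permanova(ds, samples[idx, ], "dx", c("gender", "age", "bmi_cat"),
              n_perm = config$n_perm, seed = NULL)
  })
  summary$permanova_dx_p <- lapply(perma, function(tb)
    tb$p_value[tb$term == "dx"])
  say("PERMANOVA (", config$n_perm, " perms): cecum p = ",
      summary$permanova_dx_p$cecum)

  paired <- stage("biogeography",
                  paired_site_contrast(d_all, samples, group_by = "dx",
                                       type = "beta"))
  tsv(paired$contrasts, "paired_bray_curtis.tsv")
  summary$paired_bray_curtis_p <- paired$test$p_value

  ## -- differential abundance + dysbiosis --------------------------------
  da_by_site <- list()
  dysbiosis <- list()
  for (st in c("cecum", "sigmoid")) {
    idx <- samples$site == st
    cts <- stage("prevalence_filter",
                 prevalence_filter(cohort$counts[, idx], config$prevalence))
    da <- stage("nb_wald_test",
                nb_wald_test(cts, samples[idx, ], "dx",
                             c("gender", "bmi_cat")))
    sets <- suppressMessages(significant_sets(
      da, config$q_threshold, config$abund_threshold,
      contrast = paste0("dx_", st)))
    dys <- if (length(sets$enriched) || length(sets$depleted))
      dysbiosis_index(cohort$counts[, idx], sets) else NULL
    da_by_site[[st]] <- list(da = da, sets = sets, dysbiosis = dys)
    tsv(da, paste0("da_dx_", st, ".tsv"))
    if (!is.null(dys)) {
      dys_df <- data.frame(sample_id = names(dys$index), index = dys$index,
                           dx = samples$dx[idx][match(names(dys$index),
                                                      samples$sample_id[idx])])
      tsv(dys_df, paste0("dysbiosis_", st, ".tsv"))
      sp <- split(dys_df$index, dys_df$dx)
      dysbiosis[[st]] <- list(
        n_enriched = length(sets$enriched),
        n_depleted = length(sets$depleted),
        cd_vs_control_p = wilcoxon_rank_sum(sp$CD, sp$nonIBD)$p_value)
    }
  }
  summary$dysbiosis <- dysbiosis
  say("DA: ", dysbiosis$cecum$n_enriched, " enriched / ",
      dysbiosis$cecum$n_depleted, " depleted taxa in cecum")

  ## -- GRS ---------------------------------------------------------------
  grs <- stats::setNames(cohort$subjects$grs, cohort$subjects$subject_id)
  summary$grs_cd_vs_control_p <-
    wilcoxon_rank_sum(grs[cohort$subjects$dx == "CD"],
                      grs[cohort$subjects$dx == "nonIBD"])$p_value
  grs_stage <- list()
  for (stratum in c("CD", "nonIBD")) {
    subj <- cohort$subjects[cohort$subjects$dx == stratum, ]
    covars <- if (stratum == "CD") c("gender", "age", "bmi_cat", "behavior")
      else c("gender", "age", "bmi_cat")
    if (nrow(subj) < length(covars) + 2) {
      say("GRS stratum ", stratum, " too small; skipped")
      next
    }
    idx <- samples$site == "cecum" & samples$subject_id %in% subj$subject_id
    dys <- da_by_site$cecum$dysbiosis
    targets <- list()
    if (!is.null(dys)) {
      di <- dys$index[samples$sample_id[idx]]
      names(di) <- samples$subject_id[idx]
      targets$dysbiosis <- di
    }
    res <- stage(paste0("grs_", stratum), grs_associations(
      grs[subj$subject_id], targets, subj, covars,
      counts = prevalence_filter(cohort$counts[, idx], config$prevalence),
      samples = samples[idx, ], cd_sets = da_by_site$cecum$sets,
      q_threshold = config$grs_q_threshold, n_perm = config$n_perm))
    grs_stage[[stratum]] <- list(
      dysbiosis_p = if (length(res$scalar)) res$scalar$dysbiosis$p_value else NA,
      overlap_enriched_p = if (!is.null(res$overlap)) res$overlap$enriched$p_value else NA)
  }
  summary$grs <- grs_stage

  ## -- classifier --------------------------------------------------------
  clf <- list()
  for (st in c("cecum", "sigmoid")) {
    idx <- samples$site == st
    sets <- da_by_site[[st]]$sets
    feats <- c(sets$enriched, sets$depleted)
    if (length(feats) < 2) next
    x <- abundance_features(cohort$counts[, idx])[, feats, drop = FALSE]
    labels <- stats::setNames(samples$dx[idx], samples$sample_id[idx])
    split <- stratified_split(labels, seed = NULL)
    rep <- stage(paste0("classifier_", st), train_two_stage_rf(
      x, labels, split$train, split$test,
      importance_cut = config$importance_cut, n_boot = config$n_boot))
    clf[[st]] <- list(auc = rep$auc, ci_lower = rep$ci$lower,
                      ci_upper = rep$ci$upper,
                      n_features = length(rep$refined_features))
    say("classifier (", st, "): test AUC = ", round(rep$auc, 3))
  }
  summary$classifier_dx <- clf

  ## -- metabolome --------------------------------------------------------
  mtb <- cohort$metabolome
  proc <- stage("metabolome_preprocess", suppressMessages(
    preprocess_metabolome(mtb$intensities, samples$batch,
                          config$metabolite_prevalence)))
  pfm <- stage("per_feature_models",
               per_feature_models(proc, samples, "dx",
                                  c("gender", "bmi_cat")))
  tsv(pfm, "metabolite_dx.tsv")
  summary$metabolome_n_significant <- sum(pfm$q < 0.05, na.rm = TRUE)
  blr <- stage("bile_log_ratio", bile_log_ratio(
    mtb$intensities, mtb$truth$cholate_id, mtb$truth$deoxycholate_id,
    group = samples$dx))
  summary$bile_log_ratio_p <- blr$test$p_value
  bai <- stage("aggregate_bai", aggregate_bai(cohort$ko$ko))
  sp <- split(bai, samples$dx)
  summary$bai_cd_vs_control_p <- wilcoxon_rank_sum(sp$CD, sp$nonIBD)$p_value
  summary$bai_mean_cd <- mean(sp$CD)
  summary$bai_mean_control <- mean(sp$nonIBD)
  say("bile log-ratio CD vs control p = ", summary$bile_log_ratio_p)

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
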