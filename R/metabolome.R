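#' Metabolite-feature prevalence filter
#'
#' Retains spectral features observed (non-missing) in strictly more than
#' `min_prevalence` of samples.
#'
#' @param m features x samples intensity matrix (NA = missing).
#' @param min_prevalence proportion in (0, 1); strict inequality.
#' @return filtered matrix.
#' @export
feature_prevalence_filter <- function(m, min_prevalence = 0.10) {
  if (min_prevalence <= 0 || min_prevalence >= 1)
    stop("feature_prevalence_filter: min_prevalence must be in (0, 1)")
  prev <- rowMeans(!is.na(m))
  keep <- prev > min_prevalence
  if (!any(keep)) stop("feature_prevalence_filter: all features removed")
  m[keep, , drop = FALSE]
}

#' KNN imputation over features
#'
#' A missing value of feature f in sample s is the unweighted mean, at
#' sample s, of the k features nearest to f -- Euclidean distance over the
#' samples where both features are observed, rescaled to the full sample
#' count so distances with different overlap are comparable. Candidate
#' neighbors must themselves be observed at s; if fewer than k qualify the
#' available ones are used, and if none qualify the feature's observed
#' mean is substituted (with a message). The feature-space neighborhood is
#' the standard choice for LC-MS missingness, where co-eluting /
#' biochemically related features are the best predictors.
#'
#' @param m features x samples intensity matrix with NAs.
#' @param k number of neighbor features (default 10).
#' @return completed matrix.
#' @export
knn_impute <- function(m, k = 10) {
  if (any(rowSums(!is.na(m)) == 0))
    stop("knn_impute: feature(s) entirely missing")
  if (!anyNA(m)) return(m)
  nf <- nrow(m)
  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0
  # pairwise Euclidean over shared observed samples, scaled to full length
  sq <- m0^2
  cross <- tcrossprod(m0)
  a2 <- sq %*% t(obs)          # sum over shared of x_f^2
  b2 <- obs %*% t(sq)          # sum over shared of x_g^2
  shared <- tcrossprod(obs * 1)
  d2 <- (a2 + b2 - 2 * cross) / pmax(shared, 1) * ncol(m)
  d2[shared == 0] <- Inf
  diag(d2) <- Inf
  out <- m
  feat_mean <- rowMeans(m, na.rm = TRUE)
  n_fallback <- 0L
  for (f in which(rowSums(!obs) > 0)) {
    ord <- order(d2[f, ])
    for (s in which(!obs[f, ])) {
      candidates <- ord[obs[ord, s] & is.finite(d2[f, ord])]
      if (!length(candidates)) {
        out[f, s] <- feat_mean[f]
        n_fallback <- n_fallback + 1L
      } else {
        out[f, s] <- mean(m[candidates[seq_len(min(k, length(candidates)))], s])
      }
    }
  }
  if (n_fallback > 0)
    message("knn_impute: ", n_fallback,
            " entr(ies) fell back to the feature mean (no eligible neighbor)")
  out
}

#' Interquartile-range feature filter
#'
#' Ranks features by IQR across samples and drops the lowest-IQR tail.
#' Default rule: keep all features when there are 250 or fewer, else drop
#' the bottom 10%; fully configurable via `keep_fraction`.
#'
#' @param m complete features x samples matrix.
#' @param keep_fraction fraction of features retained (NULL = default
#'   rule).
#' @return filtered matrix.
#' @export
iqr_filter <- function(m, keep_fraction = NULL) {
  if (anyNA(m)) stop("iqr_filter: missing values present; impute first")
  if (is.null(keep_fraction)) keep_fraction <- if (nrow(m) > 250) 0.9 else 1
  if (keep_fraction >= 1) return(m)
  iqr <- apply(m, 1, stats::IQR)
  n_keep <- max(1, ceiling(keep_fraction * nrow(m)))
  keep <- order(iqr, decreasing = TRUE)[seq_len(n_keep)]
  m[sort(keep), , drop = FALSE]
}

#' Log transform and quantile normalization
#'
#' Natural-log transform followed by per-sample quantile normalization to
#' the mean quantile profile; tied values receive the average of their
#' tied quantiles. Idempotent up to the log step: normalizing an
#' already-normalized matrix (with `log = FALSE`) leaves it unchanged.
#'
#' @param m strictly positive features x samples matrix.
#' @param log apply the natural-log transform first (default TRUE).
#' @return normalized matrix (log scale).
#' @export
log_quantile_normalize <- function(m, log = TRUE) {
  if (log) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("log_quantile_normalize: nonpositive entry at feature ",
           rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]])
    m <- base::log(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average-of-tied-quantiles: interpolate the sorted reference at midranks
    stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Per-batch location/scale standardization
#'
#' For each feature and batch, centers the batch at the feature's grand
#' mean and rescales the batch standard deviation to the pooled
#' within-batch value. A documented simple stand-in for empirical-Bayes
#' batch correction.
#'
#' @param m features x samples matrix (log scale).
#' @param batch per-sample batch labels; every batch needs >= 2 samples.
#' @return corrected matrix.
#' @export
batch_standardize <- function(m, batch) {
  batch <- as.character(batch)
  if (length(batch) != ncol(m))
    stop("batch_standardize: batch labels do not match samples")
  if (any(table(batch) < 2)) stop("batch_standardize: single-sample batch")
  if (length(unique(batch)) == 1) return(m)
  out <- m
  for (f in seq_len(nrow(m))) {
    x <- m[f, ]
    grand <- mean(x)
    mb <- tapply(x, batch, mean)[batch]
    sb <- tapply(x, batch, stats::sd)
    nb <- table(batch)
    pooled <- sqrt(sum((nb - 1) * sb^2) / sum(nb - 1))
    sbx <- sb[batch]
    scale <- ifelse(sbx > 0, pooled / sbx, 1)
    out[f, ] <- (x - mb) * scale + grand
  }
  out
}

#' Preprocess an LC-MS metabolite table
#'
#' Fixed processing order: prevalence filter, KNN imputation, IQR filter,
#' natural-log transform, quantile normalization, per-batch
#' standardization.
#'
#' @param m features x samples raw intensity matrix with NAs.
#' @param batch per-sample batch labels (NULL skips batch correction).
#' @param min_prevalence,k,keep_fraction stage parameters.
#' @return processed (log-scale) matrix.
#' @export
preprocess_metabolome <- function(m, batch = NULL, min_prevalence = 0.10,
                                  k = 10, keep_fraction = NULL) {
  m <- feature_prevalence_filter(m, min_prevalence)
  m <- knn_impute(m, k)
  m <- iqr_filter(m, keep_fraction)
  m <- log_quantile_normalize(m)
  if (!is.null(batch)) m <- batch_standardize(m, batch)
  m
}

#' Per-feature covariate linear models
#'
#' Least-squares fit of each feature on the covariates plus the term of
#' interest (entered last, single contrast), t-test on the term, BH
#' q-values over features. Fits are vectorized through a single QR
#' decomposition of the shared design.
#'
#' @param m processed features x samples matrix.
#' @param data per-sample covariate data.frame.
#' @param term term of interest.
#' @param covariates adjustment covariates (e.g. gender, bmi_cat).
#' @return data.frame: `feature_id`, `estimate`, `se`, `t`, `p`, `q`.
#' @export
per_feature_models <- function(m, data, term, covariates = character()) {
  if (!term %in% names(data)) stop("per_feature_models: term '", term, "' not in data")
  design <- build_design(data, c(covariates, term))
  X <- stats::model.matrix(~ ., design)
  check_full_rank(X)
  term_cols <- which(attr(X, "assign") == length(c(covariates, term)))
  if (length(term_cols) != 1)
    stop("per_feature_models: term must encode to a single contrast column")
  n <- nrow(X); p <- ncol(X)
  qr_ <- qr(X)
  coefs <- qr.coef(qr_, t(m))
  res <- t(m) - X %*% coefs
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtxinv_jj <- chol2inv(qr.R(qr_))[term_cols, term_cols]
  est <- coefs[term_cols, ]
  se <- sqrt(sigma2 * xtxinv_jj)
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  data.frame(feature_id = rownames(m), estimate = est, se = se, t = tstat,
             p = pval, q = bh_adjust(pval),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cholate:deoxycholate log ratio
#'
#' Per-sample natural-log ratio of the cholate-like feature to the
#' deoxycholate-like feature on the raw (pre-log-transform) intensity
#' scale, with a CD-vs-control Wilcoxon rank-sum comparison when a
#' grouping is supplied.
#'
#' @param m features x samples intensity matrix (raw scale by default;
#'   pass a processed matrix and `already_log = TRUE` to use processed
#'   values).
#' @param cholate_id,deoxycholate_id feature ids.
#' @param group optional per-sample two-level grouping (e.g. dx); the test
#'   compares the second level against the first.
#' @param already_log intensities are already on the log scale.
#' @param alternative passed to the Wilcoxon test.
#' @return list with `log_ratio` (named per-sample vector) and `test`.
#' @export
bile_log_ratio <- function(m, cholate_id, deoxycholate_id, group = NULL,
                           already_log = FALSE, alternative = "two.sided") {
  for (id in c(cholate_id, deoxycholate_id)) {
    if (!id %in% rownames(m)) stop("bile_log_ratio: feature '", id, "' not present")
  }
  lr <- if (already_log) m[cholate_id, ] - m[deoxycholate_id, ] else
    log(m[cholate_id, ] / m[deoxycholate_id, ])
  test <- NULL
  if (!is.null(group)) {
    g <- factor(group)
    stopifnot(nlevels(g) == 2)
    test <- wilcoxon_rank_sum(lr[g == levels(g)[2]], lr[g == levels(g)[1]],
                              alternative = alternative)
    test$groups <- rev(levels(g))
  }
  list(log_ratio = lr, test = test)
}

#' Aggregate the bile-acid 7-alpha-dehydroxylation (bai) pathway
#'
#' Per-sample sum of the six bai-operon KEGG orthologies (baiB K15868,
#' baiA K15869, baiCD K15870, baiF K15871, baiE K15872, baiN K07007) in a
#' KO relative-abundance table. Absent KOs contribute 0 (with a message);
#' if none of the six is present it is an error.
#'
#' @param ko KO x samples relative-abundance matrix.
#' @return named per-sample pathway relative abundance.
#' @export
aggregate_bai <- function(ko) {
  bai <- bai_ko_ids()
  present <- intersect(bai, rownames(ko))
  if (!length(present)) stop("aggregate_bai: none of the six bai KOs present")
  if (length(present) < length(bai))
    message("aggregate_bai: missing KO(s) contribute 0: ",
            paste(setdiff(bai, present), collapse = ", "))
  colSums(ko[present, , drop = FALSE])
}

#' Microbe-metabolite residual Spearman correlations
#'
#' Microbe residuals are deviance residuals from per-taxon NB fits on the
#' design; metabolite residuals are least-squares residuals from the same
#' design. All taxon-metabolite pairs are then correlated with
#' [residual_spearman()] on an intercept-only design (the adjustment
#' already happened in the residualization), and BH q-values are computed
#' over the pair grid. Degenerate pairs (constant residuals) are flagged
#' and excluded from q computation.
#'
#' @param counts taxa x samples matrix restricted to the taxa of interest.
#' @param m processed metabolite matrix restricted to the features of
#'   interest.
#' @param data per-sample covariates shared by both tables (rows =
#'   intersection of sample sets, matched by column names).
#' @param covariates adjustment covariates (e.g. dx, gender, age,
#'   bmi_cat).
#' @param sf size factors for the NB stage (default recomputed).
#' @return data.frame: `taxon_id`, `feature_id`, `rho`, `p`, `q`,
#'   `degenerate`.
#' @export
microbe_metabolite_correlations <- function(counts, m, data,
                                            covariates = c("dx", "gender", "age", "bmi_cat"),
                                            sf = NULL) {
  shared <- intersect(colnames(counts), colnames(m))
  if (!length(shared)) stop("microbe_metabolite_correlations: no shared samples")
  counts <- counts[, shared, drop = FALSE]
  m <- m[, shared, drop = FALSE]
  data <- data[match(shared, data$sample_id), , drop = FALSE]
  if (length(covariates)) {
    design <- build_design(data, covariates)
    X <- stats::model.matrix(~ ., design)
    check_full_rank(X)
  } else {
    X <- matrix(1, length(shared), 1)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  offset <- log(sf)
  taxon_res <- matrix(NA_real_, nrow(counts), length(shared),
                      dimnames = list(rownames(counts), shared))
  for (i in seq_len(nrow(counts))) {
    taxon_res[i, ] <- tryCatch({
      alpha <- genewise_dispersion(counts[i, ], X, offset)
      fit <- fit_nb_glm(counts[i, ], X, offset, alpha)
      fam <- MASS::negative.binomial(theta = 1 / alpha)
      y <- counts[i, ]; mu <- fit$fitted.values
      sign(y - mu) * sqrt(pmax(fam$dev.resids(y, mu, rep(1, length(y))), 0))
    }, error = function(e) rep(NA_real_, length(shared)))
  }
  mtb_res <- t(m) - X %*% qr.coef(qr(X), t(m))
  grid <- expand.grid(taxon_id = rownames(counts), feature_id = rownames(m),
                      stringsAsFactors = FALSE)
  df <- length(shared) - 2 - (ncol(X) - 1)
  res <- mapply(function(tx, ft) {
    rx <- taxon_res[tx, ]; ry <- mtb_res[, ft]
    if (anyNA(rx) || stats::sd(rx) == 0 || stats::sd(ry) == 0)
      return(c(NA_real_, NA_real_, 1))
    rho <- stats::cor(rank(rx), rank(ry))
    # t approximation with partial-correlation df (see residual_spearman)
    p <- if (abs(rho) >= 1) 0 else
      2 * stats::pt(-abs(rho * sqrt(df / (1 - rho^2))), df)
    c(rho, p, 0)
  }, grid$taxon_id, grid$feature_id)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$degenerate <- res[3, ] == 1
  grid$q <- NA_real_
  grid$q[!grid$degenerate] <- bh_adjust(grid$p[!grid$degenerate])
  grid
}
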