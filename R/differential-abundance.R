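#' Prevalence filter
#'
#' Retains taxa with a nonzero count in at least `min_prevalence` of
#' samples. The boundary is inclusive: taxa present in exactly the
#' threshold fraction are kept, only those present in *less* than it are
#' removed.
#'
#' @param counts taxa x samples matrix.
#' @param min_prevalence proportion in (0, 1].
#' @return filtered matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.25) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("prevalence_filter: min_prevalence must be in (0, 1]")
  prev <- rowMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("prevalence_filter: all taxa removed")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' `sf_j = median over reference taxa of count_ij / geometric mean_i`,
#' where the reference set is the taxa with nonzero counts in every sample;
#' factors are rescaled so their geometric mean is 1. If no taxon is
#' all-positive, geometric means are taken over positive entries only
#' (logged notice).
#'
#' @param counts taxa x samples matrix.
#' @return named positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (any(all_pos)) {
    ref <- counts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    ratios <- sweep(ref, 1, geo, "/")
  } else {
    message("size_factors: no all-positive taxon; using positive-entries-only geometric means")
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ratios <- sweep(counts, 1, geo, "/")
    ratios[counts == 0] <- NA
  }
  sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood in the dispersion, means fixed.
nb_cr_profile <- function(log_alpha, y, mu, X) {
  alpha <- exp(log_alpha)
  w <- mu / (1 + alpha * mu)
  ld <- determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  nb_loglik(y, mu, alpha) - 0.5 * as.numeric(ld)
}

fit_nb_glm <- function(y, X, offset, alpha, start = NULL) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                         start = start))
  fit
}

genewise_dispersion <- function(y, X, offset, max_alpha = 50) {
  pfit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                          offset = offset))
  mu <- pmax(pfit$fitted.values, 1e-8)
  opt <- stats::optimize(nb_cr_profile, c(log(1e-8), log(max_alpha)),
                         y = y, mu = mu, X = X, maximum = TRUE)
  alpha <- exp(opt$maximum)
  # one refit of the means at the estimated dispersion, then re-optimize
  fit <- fit_nb_glm(y, X, offset, alpha, start = pfit$coefficients)
  mu <- pmax(fit$fitted.values, 1e-8)
  opt <- stats::optimize(nb_cr_profile, c(log(1e-8), log(max_alpha)),
                         y = y, mu = mu, X = X, maximum = TRUE)
  exp(opt$maximum)
}

#' Per-taxon NB dispersions with trend shrinkage
#'
#' Gene-wise dispersions are Cox-Reid adjusted profile maximum-likelihood
#' estimates given fitted means under the design. A parametric trend
#' `alpha(mu) = a0 / mu + a1` is fitted across taxa (least squares on
#' mean normalized counts, one robustness pass dropping gross outliers,
#' coefficients floored at 0), and the final dispersion is a weighted
#' geometric combination of the gene-wise estimate and the trend value:
#' `exp((1 - w) log alpha_gene + w log alpha_trend)` with `w =
#' shrink_weight`. Floored at 1e-8. Taxa whose gene-wise fit fails fall
#' back to the trend value and are flagged.
#'
#' @param counts taxa x samples matrix.
#' @param data per-sample covariate data.frame.
#' @param term,covariates model terms (term of interest last).
#' @param sf size factors (default [size_factors()]).
#' @param shrink_weight weight on the trend in (0, 1); default 0.5.
#' @return data.frame: `taxon_id`, `genewise`, `trend`, `dispersion`,
#'   `fallback`.
#' @export
fit_dispersions <- function(counts, data, term, covariates = character(),
                            sf = NULL, shrink_weight = 0.5) {
  design <- build_design(data, c(covariates, term))
  X <- stats::model.matrix(~ ., design)
  if (nrow(X) <= ncol(X))
    stop("fit_dispersions: need more samples than design columns")
  check_full_rank(X)
  if (is.null(sf)) sf <- size_factors(counts)
  offset <- log(sf)
  nt <- nrow(counts)
  genewise <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    genewise[i] <- tryCatch(genewise_dispersion(counts[i, ], X, offset),
                            error = function(e) NA_real_)
  }
  mu_bar <- rowMeans(sweep(counts, 2, sf, "/"))
  trend <- fit_dispersion_trend(genewise, mu_bar)
  fallback <- !is.finite(genewise)
  gw <- ifelse(fallback, trend, pmax(genewise, 1e-8))
  final <- pmax(exp((1 - shrink_weight) * log(gw) +
                    shrink_weight * log(pmax(trend, 1e-8))), 1e-8)
  data.frame(taxon_id = rownames(counts), genewise = genewise, trend = trend,
             dispersion = final, fallback = fallback,
             row.names = NULL, stringsAsFactors = FALSE)
}

fit_dispersion_trend <- function(alpha, mu_bar) {
  ok <- is.finite(alpha) & alpha > 1e-7 & mu_bar > 0
  if (sum(ok) < 3) {
    a0 <- 0
    a1 <- stats::median(alpha[is.finite(alpha)], na.rm = TRUE)
    if (!is.finite(a1)) a1 <- 0.1
  } else {
    fit_once <- function(idx) {
      cf <- stats::coef(stats::lm(alpha[idx] ~ I(1 / mu_bar[idx])))
      c(a1 = max(cf[1], 1e-8), a0 = max(cf[2], 0))
    }
    cf <- fit_once(ok)
    pred <- cf["a0"] / mu_bar + cf["a1"]
    ratio <- alpha / pred
    ok2 <- ok & is.finite(ratio) & ratio > 1e-4 & ratio < 15
    if (sum(ok2) >= 3) cf <- fit_once(ok2)
    a0 <- cf[["a0"]]; a1 <- cf[["a1"]]
  }
  pmax(a0 / pmax(mu_bar, 1e-8) + a1, 1e-8)
}

#' Negative-binomial Wald differential-abundance test
#'
#' Per-taxon NB log-linear regression with a log size-factor offset;
#' covariates enter first and the term of interest last (its coefficient
#' must be a single contrast). The Wald statistic is coefficient / SE with
#' the SE from the expected information at the final (shrunk) dispersion;
#' two-sided normal p-values are converted to q-values by
#' [storey_qvalues()] over the converged taxa. `log2_fold_change` is the
#' coefficient divided by ln 2; `mean_norm_rel_abund` is the mean over
#' samples of the size-factor-normalized relative abundance.
#'
#' @param counts taxa x samples matrix (prevalence-filtered).
#' @param data per-sample covariate data.frame.
#' @param term term of interest; must encode to exactly one column.
#' @param covariates adjustment covariates.
#' @param sf size factors (default [size_factors()]).
#' @param dispersions per-taxon dispersions (default [fit_dispersions()]).
#' @param shrink_weight passed to [fit_dispersions()] when they are fitted
#'   here.
#' @return data.frame of class `da_result`: `taxon_id`, `log2_fold_change`,
#'   `se`, `stat`, `p`, `q`, `mean_norm_rel_abund`, `dispersion`,
#'   `converged`.
#' @export
nb_wald_test <- function(counts, data, term, covariates = character(),
                         sf = NULL, dispersions = NULL, shrink_weight = 0.5) {
  design <- build_design(data, c(covariates, term))
  tv <- design[[term]]
  if (length(unique(tv[!is.na(tv)])) < 2)
    stop("nb_wald_test: term '", term, "' is constant")
  X <- stats::model.matrix(~ ., design)
  check_full_rank(X)
  term_cols <- which(attr(X, "assign") == length(c(covariates, term)))
  if (length(term_cols) != 1)
    stop("nb_wald_test: term '", term,
         "' must encode to a single contrast column (got ",
         length(term_cols), ")")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- fit_dispersions(counts, data, term, covariates, sf,
                                   shrink_weight)$dispersion
  } else if (is.data.frame(dispersions)) {
    dispersions <- dispersions$dispersion
  }
  offset <- log(sf)
  nt <- nrow(counts)
  est <- se <- rep(NA_real_, nt)
  converged <- logical(nt)
  for (i in seq_len(nt)) {
    res <- tryCatch({
      fit <- fit_nb_glm(counts[i, ], X, offset, dispersions[i])
      if (!fit$converged) stop("no convergence")
      w <- fit$weights
      info <- crossprod(X * sqrt(w))
      vc <- chol2inv(chol(info))
      list(b = fit$coefficients[term_cols], s = sqrt(vc[term_cols, term_cols]))
    }, error = function(e) NULL)
    if (!is.null(res) && is.finite(res$b) && is.finite(res$s) && res$s > 0) {
      est[i] <- res$b
      se[i] <- res$s
      converged[i] <- TRUE
    }
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, nt)
  q[converged] <- suppressMessages(storey_qvalues(p[converged]))
  normc <- sweep(counts, 2, sf, "/")
  relab <- sweep(normc, 2, colSums(normc), "/")
  out <- data.frame(taxon_id = rownames(counts),
                    log2_fold_change = est / log(2),
                    se = se / log(2), stat = z, p = p, q = q,
                    mean_norm_rel_abund = rowMeans(relab),
                    dispersion = dispersions, converged = converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("da_result", class(out))
  out
}

#' Significant enriched/depleted taxon sets
#'
#' Enriched taxa have `q < q_threshold`, positive log2 fold change and mean
#' normalized relative abundance above `abund_threshold`; depleted likewise
#' with negative fold change. The abundance filter is applied after q
#' computation.
#'
#' @param da a `da_result` from [nb_wald_test()].
#' @param q_threshold q cutoff (0.05 by default; 0.1 for GRS analyses).
#' @param abund_threshold mean normalized relative-abundance floor.
#' @param contrast label carried in the result.
#' @return list of class `taxon_sets`: `enriched`, `depleted`, `contrast`,
#'   thresholds.
#' @export
significant_sets <- function(da, q_threshold = 0.05, abund_threshold = 1e-5,
                             contrast = "dx") {
  if (q_threshold <= 0 || q_threshold >= 1 || abund_threshold <= 0 ||
      abund_threshold >= 1)
    stop("significant_sets: thresholds must lie in (0, 1)")
  ok <- !is.na(da$q) & da$q < q_threshold &
    da$mean_norm_rel_abund > abund_threshold
  sets <- list(enriched = da$taxon_id[ok & da$log2_fold_change > 0],
               depleted = da$taxon_id[ok & da$log2_fold_change < 0],
               contrast = contrast, q_threshold = q_threshold,
               abund_threshold = abund_threshold)
  if (!length(sets$enriched) && !length(sets$depleted))
    message("significant_sets: both sets empty for contrast '", contrast, "'")
  class(sets) <- "taxon_sets"
  sets
}

#' CD dysbiosis index
#'
#' Per-sample natural-log ratio of the summed relative abundances of the
#' enriched taxa over the depleted taxa, with a pseudocount on both sums so
#' the index stays finite when one set is absent from a sample:
#' `ln((sum enriched + pc) / (sum depleted + pc))`.
#'
#' @param counts taxa x samples count matrix (converted to relative
#'   abundances per sample) or an already-relative matrix with
#'   `relative = TRUE`.
#' @param sets a `taxon_sets` (or list with `enriched`, `depleted`).
#' @param pseudocount positive guard (default 1e-6).
#' @param relative set TRUE if `counts` already holds relative abundances.
#' @return list of class `dysbiosis_result`: `index` (named per-sample
#'   vector), `sets`, `pseudocount`.
#' @export
dysbiosis_index <- function(counts, sets, pseudocount = 1e-6,
                            relative = FALSE) {
  if (pseudocount <= 0) stop("dysbiosis_index: pseudocount must be > 0")
  if (!length(sets$enriched) && !length(sets$depleted))
    stop("dysbiosis_index: both taxon sets are empty")
  relab <- if (relative) counts else sweep(counts, 2, colSums(counts), "/")
  enr <- intersect(sets$enriched, rownames(relab))
  dep <- intersect(sets$depleted, rownames(relab))
  s_enr <- if (length(enr)) colSums(relab[enr, , drop = FALSE]) else
    stats::setNames(numeric(ncol(relab)), colnames(relab))
  s_dep <- if (length(dep)) colSums(relab[dep, , drop = FALSE]) else
    stats::setNames(numeric(ncol(relab)), colnames(relab))
  idx <- log((s_enr + pseudocount) / (s_dep + pseudocount))
  structure(list(index = idx, sets = sets, pseudocount = pseudocount),
            class = "dysbiosis_result")
}
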