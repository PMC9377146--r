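#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples with total below `depth` are dropped and reported via the
#' `dropped` attribute (mirroring depth-based exclusion of shallow
#' samples). Deterministic per seed.
#'
#' @param counts taxa x samples integer matrix.
#' @param depth target depth (>= 1).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return rarefied matrix with attribute `dropped` (character vector of
#'   excluded sample ids).
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (depth < 1) stop("rarefy_counts: depth must be >= 1")
  set_seed_if(seed)
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("rarefy_counts: depth drops all samples")
  dropped <- colnames(counts)[!keep]
  if (length(dropped))
    message("rarefy_counts: dropped ", length(dropped),
            " sample(s) below depth: ", paste(dropped, collapse = ", "))
  out <- counts[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    tot <- totals[keep][j]
    if (tot == depth) next
    # draw `depth` distinct read indices from 1..tot and map to taxa
    draws <- sample.int(tot, depth)
    cum <- cumsum(out[, j])
    taxon <- findInterval(draws - 1L, cum) + 1L
    out[, j] <- tabulate(taxon, nbins = nrow(out))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where F1 and F2 are the singleton
#' and doubleton counts. Always at least the observed richness.
#'
#' @param x vector of non-negative integer counts.
#' @return richness estimate (scalar).
#' @export
chao1 <- function(x) {
  if (any(x < 0)) stop("chao1: negative counts")
  if (sum(x) == 0) {
    warning("chao1: all-zero count vector")
    return(0)
  }
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' `-sum p_i ln p_i` over nonzero proportions, in nats.
#'
#' @param x vector of non-negative counts with positive total.
#' @return entropy in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("shannon: negative counts")
  if (sum(x) == 0) stop("shannon: zero-sum count vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param counts taxa x samples matrix.
#' @return data.frame with `sample_id`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  data.frame(sample_id = colnames(counts),
             chao1 = apply(counts, 2, chao1),
             shannon = apply(counts, 2, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x_i + sum y_i)` on the
#' supplied (raw-count) table; computed with `vegan::vegdist`.
#'
#' @param counts taxa x samples matrix; every sample needs a positive total.
#' @return `dist` object over samples.
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2) stop("bray_curtis: need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("bray_curtis: zero-total sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  vegan::vegdist(t(counts), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical scaling of a dissimilarity matrix (Gower double centering of
#' -d^2/2 and eigendecomposition); coordinates are eigenvectors scaled by
#' the square root of their (positive) eigenvalues. Negative eigenvalues
#' are reported, not corrected. If fewer than `k` positive eigenvalues
#' exist the ordination is truncated with a warning.
#'
#' @param d `dist` object or symmetric matrix.
#' @param k number of axes (default 2).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `variance_explained` (fractions of the positive-eigenvalue
#'   total).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n - 1) stop("pcoa: k must be at most n - 1")
  # cmdscale warns when semi-metric dissimilarities yield negative
  # eigenvalues; those are reported, not corrected, so the warning is noise
  cs <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cs$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos) {
    warning("pcoa: only ", n_pos, " positive eigenvalues; truncating to k = ", n_pos)
    k <- n_pos
  }
  coords <- cs$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       variance_explained = pmax(eig, 0)[seq_len(k)] / sum(pmax(eig, 0)))
}

#' Covariate-adjusted PERMANOVA
#'
#' Sequential partitioning of the distance matrix by term order (covariates
#' first, the term of interest last) with free row permutation, via
#' `vegan::adonis2` with `by = "terms"`. The permutation p-value is
#' `(1 + #permuted F >= observed) / (1 + n_perm)`.
#'
#' @param d `dist` object over samples.
#' @param data data.frame of per-sample covariates, rows aligned with `d`.
#' @param term term of interest (tested last).
#' @param covariates adjustment covariates, entered first.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame with one row per term: `term`, `df`, `pseudo_f`,
#'   `r2`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, data, term, covariates = character(),
                      n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("permanova: n_perm must be >= 99")
  vars <- c(covariates, term)
  design <- build_design(data, vars)
  for (v in vars) {
    if (length(unique(design[[v]])) < 2)
      stop("permanova: term '", v, "' is constant across samples")
  }
  if (anyNA(design)) stop("permanova: metadata incomplete for samples in d")
  set_seed_if(seed)
  fml <- stats::as.formula(paste("d ~", paste(vars, collapse = " + ")))
  fit <- vegan::adonis2(fml, data = design, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df, pseudo_f = fit$F,
                    r2 = fit$R2, p_value = fit$`Pr(>F)`, n_perm = n_perm,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[out$term != "Total", , drop = FALSE]
}

#' Paired cecum-sigmoid contrasts
#'
#' For each subject with exactly one sample per site, computes either the
#' per-subject alpha-diversity difference (cecum minus sigmoid) or the
#' Bray-Curtis dissimilarity between the subject's paired samples, then
#' compares subject groups with a Wilcoxon rank-sum test (2 groups) or
#' Kruskal-Wallis plus Dunn (3+ groups). Subjects missing a site are
#' excluded with a message.
#'
#' @param x for `type = "alpha"`, a named numeric vector of per-sample
#'   alpha diversity; for `type = "beta"`, a `dist` or matrix of
#'   Bray-Curtis dissimilarities over samples.
#' @param samples per-sample metadata with `sample_id`, `subject_id`,
#'   `site`.
#' @param group_by subject-level grouping column in `samples` (e.g. `dx`
#'   or `bmi_cat`); NULL skips the group test.
#' @param type `"alpha"` or `"beta"`.
#' @param alternative passed to the Wilcoxon test (two-group case).
#' @return list with `contrasts` (subject_id, value, group) and `test`.
#' @export
paired_site_contrast <- function(x, samples, group_by = "dx",
                                 type = c("alpha", "beta"),
                                 alternative = "two.sided") {
  type <- match.arg(type)
  tab <- table(samples$subject_id, samples$site)
  complete <- rownames(tab)[tab[, "cecum"] == 1 & tab[, "sigmoid"] == 1]
  excluded <- setdiff(unique(samples$subject_id), complete)
  if (length(excluded))
    message("paired_site_contrast: excluded ", length(excluded),
            " subject(s) missing a site")
  if (type == "beta") x <- as.matrix(x)
  vals <- vapply(complete, function(s) {
    rows <- samples[samples$subject_id == s, ]
    cec <- rows$sample_id[rows$site == "cecum"]
    sig <- rows$sample_id[rows$site == "sigmoid"]
    if (type == "alpha") unname(x[cec] - x[sig]) else unname(x[cec, sig])
  }, numeric(1))
  grp <- if (is.null(group_by)) rep(NA_character_, length(complete)) else
    samples[[group_by]][match(complete, samples$subject_id)]
  contrasts <- data.frame(subject_id = complete, value = vals, group = grp,
                          row.names = NULL, stringsAsFactors = FALSE)
  test <- NULL
  if (!is.null(group_by)) {
    g <- factor(contrasts$group)
    if (nlevels(g) == 2) {
      sp <- split(contrasts$value, g)
      test <- wilcoxon_rank_sum(sp[[1]], sp[[2]], alternative = alternative)
      test$groups <- levels(g)
    } else if (nlevels(g) >= 3) {
      test <- kruskal_dunn(contrasts$value, g)
    }
  }
  list(contrasts = contrasts, test = test)
}
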