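#' Stratified train/test split
#'
#' Splits sample ids into train and test subsets preserving class
#' proportions within rounding; disjoint, exhaustive and deterministic per
#' seed.
#'
#' @param labels named vector (or plain vector) of class labels.
#' @param train_fraction fraction assigned to training (default 0.6).
#' @param seed integer seed.
#' @return list with `train` and `test` index vectors (names if `labels`
#'   is named, indices otherwise).
#' @export
stratified_split <- function(labels, train_fraction = 0.6, seed = NULL) {
  lab <- factor(labels)
  if (nlevels(lab) < 2) stop("stratified_split: need at least 2 classes")
  if (any(table(lab) < 2)) stop("stratified_split: every class needs >= 2 members")
  set_seed_if(seed)
  ids <- if (!is.null(names(labels))) names(labels) else seq_along(labels)
  train <- unlist(lapply(levels(lab), function(l) {
    members <- ids[lab == l]
    n_tr <- round(train_fraction * length(members))
    n_tr <- min(max(n_tr, 1), length(members) - 1)
    sample(members, n_tr)
  }), use.names = FALSE)
  list(train = train, test = setdiff(ids, train))
}

#' Log-transformed normalized relative-abundance features
#'
#' Classifier feature representation: counts normalized by size factor,
#' renormalized to relative abundances per sample, then log10 with a
#' pseudocount. Returns a samples x taxa matrix.
#'
#' @param counts taxa x samples matrix.
#' @param sf size factors (default [size_factors()]).
#' @param pseudocount added before the log (default 1e-6).
#' @return samples x taxa numeric matrix.
#' @export
abundance_features <- function(counts, sf = NULL, pseudocount = 1e-6) {
  if (is.null(sf)) sf <- size_factors(counts)
  normc <- sweep(counts, 2, sf, "/")
  relab <- sweep(normc, 2, colSums(normc), "/")
  t(log10(relab + pseudocount))
}

#' Two-stage random-forest classifier
#'
#' Stage 1 fits a random forest (`mtry = 2`, 1001 trees) on all input
#' features -- the caller restricts these to taxa significant in the
#' relevant covariate-adjusted differential-abundance contrast -- and
#' computes permutation importance scaled by its standard error
#' (mean-decrease-accuracy z-score). Stage 2 refits on the features with
#' importance above `importance_cut` (default 2). If no feature exceeds
#' the cut, the refined stage reuses all preliminary features with a
#' warning. Test-set class-probability scores (fraction of trees voting
#' positive), Mann-Whitney AUC and a stratified percentile-bootstrap CI
#' are reported.
#'
#' @param features samples x features matrix (e.g. [abundance_features()]).
#' @param labels named per-sample class labels (2 classes); the second
#'   factor level is scored as positive.
#' @param train_ids,test_ids sample ids from [stratified_split()].
#' @param mtry,n_trees forest parameters (defaults 2 and 1001).
#' @param importance_cut importance z-score threshold (default 2).
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param seed integer seed.
#' @return list of class `classifier_report`: `preliminary_features`,
#'   `refined_features`, `importance`, `auc`, `ci`, `test_scores`,
#'   `positive_class`, `oob_error`.
#' @export
train_two_stage_rf <- function(features, labels, train_ids, test_ids,
                               mtry = 2, n_trees = 1001, importance_cut = 2,
                               n_boot = 2000, seed = NULL) {
  set_seed_if(seed)
  lab <- factor(labels)
  positive <- levels(lab)[2]
  x_tr <- features[train_ids, , drop = FALSE]
  y_tr <- lab[match(train_ids, names(labels))]
  rf1 <- randomForest::randomForest(
    x = x_tr, y = y_tr, mtry = min(mtry, ncol(x_tr)), ntree = n_trees,
    importance = TRUE)
  imp <- randomForest::importance(rf1, type = 1, scale = TRUE)[, 1]
  refined <- names(imp)[imp > importance_cut]
  if (!length(refined)) {
    warning("train_two_stage_rf: no feature exceeds the importance cut; ",
            "refined stage uses all preliminary features")
    refined <- colnames(x_tr)
  }
  rf2 <- randomForest::randomForest(
    x = x_tr[, refined, drop = FALSE], y = y_tr,
    mtry = min(mtry, length(refined)), ntree = n_trees)
  x_te <- features[test_ids, refined, drop = FALSE]
  y_te <- lab[match(test_ids, names(labels))]
  scores <- stats::predict(rf2, x_te, type = "prob")[, positive]
  auc <- roc_auc(scores, y_te == positive)
  ci <- bootstrap_auc_ci(scores, y_te == positive, n_boot = n_boot)
  structure(list(preliminary_features = colnames(x_tr),
                 refined_features = refined,
                 importance = sort(imp, decreasing = TRUE),
                 auc = auc, ci = ci,
                 test_scores = stats::setNames(scores, test_ids),
                 test_labels = stats::setNames(y_te == positive, test_ids),
                 positive_class = positive,
                 oob_error = rf1$err.rate[n_trees, "OOB"]),
            class = "classifier_report")
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted half.
#'
#' @param scores numeric scores.
#' @param labels logical (or two-level) labels; TRUE / second level =
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(if (is.logical(labels)) labels else
    factor(labels) == levels(factor(labels))[2])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified percentile-bootstrap AUC confidence interval
#'
#' Resamples positives and negatives separately (so no resample is
#' degenerate), recomputes the AUC and takes percentile bounds.
#' Deterministic per seed.
#'
#' @param scores numeric test-set scores.
#' @param labels logical labels (TRUE = positive), both classes with >= 2
#'   members.
#' @param n_boot number of resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = NULL) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("bootstrap_auc_ci: both classes need >= 2 members")
  if (n_boot < 2) warning("bootstrap_auc_ci: n_boot < 2 gives a degenerate interval")
  set_seed_if(seed)
  s_pos <- scores[labels]; s_neg <- scores[!labels]
  aucs <- vapply(seq_len(n_boot), function(b) {
    bp <- sample(s_pos, length(s_pos), replace = TRUE)
    bn <- sample(s_neg, length(s_neg), replace = TRUE)
    roc_auc(c(bp, bn), c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
  }, numeric(1))
  qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 6)
  list(lower = qs[1], upper = qs[2], level = level, n_boot = n_boot)
}
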