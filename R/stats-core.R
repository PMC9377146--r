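#' Build a reference-coded design data frame
#'
#' Encodes cohort covariates with fixed, documented reference levels so
#' coefficients are comparable across runs: disease `nonIBD`, gender
#' `female`, BMI category `lt25`, behavior `B1`. Continuous columns (age,
#' GRS) pass through unchanged.
#'
#' @param metadata data.frame of per-sample or per-subject covariates.
#' @param columns columns to keep, in model order.
#' @return data.frame with releveled factors.
#' @export
build_design <- function(metadata, columns) {
  missing_cols <- setdiff(columns, names(metadata))
  if (length(missing_cols))
    stop("build_design: missing columns: ", paste(missing_cols, collapse = ", "))
  refs <- c(dx = "nonIBD", gender = "female", bmi_cat = "lt25",
            behavior = "B1", site = "cecum", progression = "nonprogressor")
  out <- metadata[, columns, drop = FALSE]
  for (cl in columns) {
    if (is.character(out[[cl]]) || is.factor(out[[cl]])) {
      f <- factor(out[[cl]])
      if (cl %in% names(refs) && refs[[cl]] %in% levels(f))
        f <- stats::relevel(f, refs[[cl]])
      out[[cl]] <- f
    }
  }
  out
}

check_full_rank <- function(mm) {
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Covariate-adjusted sequential ANOVA
#'
#' Sequential (Type-I) F-test with covariates entered first and the term of
#' interest last, the convention of `aov`-style adjusted analyses: the term
#' is tested on variance unexplained by the covariates. The order is part
#' of the contract.
#'
#' @param response numeric vector.
#' @param data data.frame holding `term` and `covariates`.
#' @param term name of the term of interest (tested last).
#' @param covariates character vector of adjustment covariates (may be
#'   empty).
#' @return list with `statistic` (F), `p_value`, `df`, `term`.
#' @export
anova_with_covariates <- function(response, data, term, covariates = character()) {
  if (!term %in% names(data))
    stop("anova_with_covariates: term '", term, "' not in data")
  design <- build_design(data, c(covariates, term))
  if (nrow(design) != length(response))
    stop("anova_with_covariates: response length does not match data")
  mm <- stats::model.matrix(~ ., design)
  if (nrow(mm) <= ncol(mm))
    stop("anova_with_covariates: more design columns than observations")
  check_full_rank(mm)
  if (stats::var(response) == 0)
    return(list(statistic = 0, p_value = 1, df = c(NA, NA), term = term))
  fit <- stats::aov(response ~ ., data = design)
  tab <- summary(fit)[[1]]
  rows <- trimws(rownames(tab))
  i <- match(term, rows)
  if (is.na(i)) stop("anova_with_covariates: term row not found")
  list(statistic = unname(tab[i, "F value"]),
       p_value = unname(tab[i, "Pr(>F)"]),
       df = c(tab[i, "Df"], tab[nrow(tab), "Df"]),
       term = term)
}

#' Tukey honest significant differences
#'
#' Studentized-range pairwise comparisons with family-wise adjusted
#' p-values, via `TukeyHSD` on a one-way fit.
#'
#' @param response numeric vector.
#' @param group factor or character vector of group labels.
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(response, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("tukey_hsd: need at least 2 groups")
  if (any(table(group) < 2)) stop("tukey_hsd: every group needs >= 2 observations")
  fit <- stats::aov(response ~ group)
  tab <- stats::TukeyHSD(fit)$group
  data.frame(comparison = rownames(tab), diff = tab[, "diff"],
             lwr = tab[, "lwr"], upr = tab[, "upr"], p_adj = tab[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties, else the normal approximation with midranks and tie
#' correction.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (W), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = !exact)
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       exact = exact)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Kruskal-Wallis H with tie correction, followed by Dunn pairwise z tests
#' on midranks, Benjamini-Hochberg adjusted.
#'
#' @param response numeric vector.
#' @param group group labels.
#' @return list with `kruskal` (statistic, p_value, df) and `dunn`
#'   (data.frame: comparison, z, p, p_adj).
#' @export
kruskal_dunn <- function(response, group) {
  group <- factor(group)
  if (length(unique(response)) == 1) {
    # all observations tied: no evidence against the null by construction
    pairs <- utils::combn(levels(group), 2)
    dunn_df <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
                          z = 0, p = 1, p_adj = 1,
                          row.names = NULL, stringsAsFactors = FALSE)
    return(list(kruskal = list(statistic = 0, p_value = 1,
                               df = nlevels(group) - 1),
                dunn = dunn_df))
  }
  kw <- stats::kruskal.test(response, group)
  n <- length(response)
  r <- rank(response)
  tie_tab <- table(response)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_corr
  lev <- levels(group)
  mean_r <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  pairs <- utils::combn(lev, 2)
  dunn <- apply(pairs, 2, function(pr) {
    z <- (mean_r[pr[1]] - mean_r[pr[2]]) /
      sqrt(sigma2 * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    c(z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  })
  dunn_df <- data.frame(
    comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
    z = dunn["z", ], p = dunn["p", ],
    p_adj = bh_adjust(dunn["p", ]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      df = unname(kw$parameter)),
       dunn = dunn_df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 as `#\{p > lambda\} / (n (1 - lambda))`, smoothed by taking the
#' median over the upper half of the grid (a simple stable rule), capped to
#' (0, 1]. q-values are pi0 times the BH step-up values. With fewer than 50
#' p-values pi0 estimation is unstable, so the function falls back to BH
#' (pi0 = 1) with a message.
#'
#' @param p vector of p-values.
#' @return q-values, same length and order as `p`, with the pi0 estimate
#'   attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("storey_qvalues: p-values outside [0, 1]")
  ok <- !is.na(p)
  n <- sum(ok)
  if (n < 50) {
    message("storey_qvalues: fewer than 50 p-values; falling back to BH (pi0 = 1)")
    return(bh_adjust(p))
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1))
  pi0 <- stats::median(pi0_l[lambda >= 0.5])
  pi0 <- min(max(pi0, 1e-8), 1)
  structure(pmin(pi0 * bh_adjust(p), 1), pi0 = pi0)
}

#' Spearman correlation of model residuals
#'
#' Regresses `x` and `y` each on the design by least squares and returns
#' the Spearman correlation of the two residual vectors. The p-value uses
#' the t approximation with the partial-correlation degrees of freedom
#' `n - 2 - k`, where k is the number of non-intercept design columns:
#' residualizing both variables on a shared estimated design consumes df,
#' and ignoring that makes the naive Spearman test anticonservative. With
#' an intercept-only design this reduces to the ordinary asymptotic
#' Spearman test. Constant residuals are flagged rather than propagated
#' as NaN.
#'
#' @param x,y numeric vectors, same length.
#' @param design data.frame of covariates (NULL or zero columns =
#'   intercept only).
#' @return list with `rho`, `p_value`, `degenerate`.
#' @export
residual_spearman <- function(x, y, design = NULL) {
  if (length(x) != length(y)) stop("residual_spearman: lengths differ")
  mm <- if (is.null(design) || ncol(as.data.frame(design)) == 0)
    matrix(1, length(x), 1)
  else stats::model.matrix(~ ., build_design(as.data.frame(design),
                                             names(as.data.frame(design))))
  check_full_rank(mm)
  rx <- stats::lm.fit(mm, x)$residuals
  ry <- stats::lm.fit(mm, y)$residuals
  tol <- 1e-10 * max(1, stats::sd(x), stats::sd(y))
  if (stats::sd(rx) < tol || stats::sd(ry) < tol)
    return(list(rho = NA_real_, p_value = NA_real_, degenerate = TRUE))
  rho <- stats::cor(rank(rx), rank(ry))
  df <- length(x) - 2 - (ncol(mm) - 1)
  if (df < 1) stop("residual_spearman: not enough observations for the design")
  p <- if (abs(rho) >= 1) 0 else
    2 * stats::pt(-abs(rho * sqrt(df / (1 - rho^2))), df)
  list(rho = rho, p_value = p, degenerate = FALSE)
}
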