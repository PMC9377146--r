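test_that("feature prevalence filter is strict at the boundary", {
  m <- matrix(NA_real_, 3, 10, dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  m[1, 1] <- 5          # 10% exactly: removed (strict >)
  m[2, 1:2] <- 5        # 20%: kept
  m[3, ] <- 1           # all samples: kept
  f <- feature_prevalence_filter(m, 0.10)
  expect_setequal(rownames(f), c("f2", "f3"))
  expect_identical(feature_prevalence_filter(m, 0.05), m)
  expect_error(feature_prevalence_filter(m[1:2, , drop = FALSE], 0.5),
               "all features removed")
})

test_that("KNN imputation follows the neighbor-mean rule", {
  # three features; f2 and f3 are identical to f1 on observed samples, so
  # they are its nearest neighbors; imputed value is their mean at s1
  m <- rbind(f1 = c(NA, 1, 2, 3, 4),
             f2 = c(4, 1, 2, 3, 4),
             f3 = c(6, 1, 2, 3, 4),
             f4 = c(100, 50, 60, 80, 90))
  colnames(m) <- paste0("s", 1:5)
  out <- knn_impute(m, k = 2)
  expect_equal(out["f1", "s1"], 5)           # mean(4, 6)
  expect_equal(out[-1, ], m[-1, ])           # observed entries untouched

  full <- matrix(rnorm(20), 4, 5)
  expect_identical(knn_impute(full, 3), full)
  m_bad <- m; m_bad[1, ] <- NA
  expect_error(knn_impute(m_bad), "entirely missing")
})

test_that("KNN imputation beats feature-mean imputation under MAR", {
  set.seed(201)
  wins <- 0
  for (r in 1:20) {
    # correlated features: latent sample factor + noise
    ns <- 30; nf <- 40
    latent <- rnorm(ns)
    m <- outer(rnorm(nf, 10, 1), rep(1, ns)) +
      outer(runif(nf, 0.5, 2), latent) + matrix(rnorm(nf * ns, 0, 0.3), nf, ns)
    mask <- matrix(runif(nf * ns) < 0.1, nf, ns)
    mask[rowSums(!mask) == 0, 1] <- FALSE
    mm <- m; mm[mask] <- NA
    imp <- knn_impute(mm, k = 5)
    rmse_knn <- sqrt(mean((imp[mask] - m[mask])^2))
    fm <- rowMeans(mm, na.rm = TRUE)
    rmse_mean <- sqrt(mean((outer(fm, rep(1, ns))[mask] - m[mask])^2))
    wins <- wins + (rmse_knn < rmse_mean)
  }
  expect_gte(wins, 17)
})

test_that("IQR filter drops the flattest features per the configured rule", {
  m <- rbind(flat = rep(5, 10), mid = rep(c(4, 6), 5), wide = c(1:9 * 3, 50))
  colnames(m) <- paste0("s", 1:10)
  f <- iqr_filter(m, keep_fraction = 2 / 3)
  expect_setequal(rownames(f), c("mid", "wide"))
  expect_identical(iqr_filter(m, keep_fraction = 1), m)
  # default rule keeps everything at <= 250 features
  expect_identical(iqr_filter(m), m)
  big <- matrix(rnorm(300 * 4), 300, 4)
  expect_equal(nrow(iqr_filter(big)), 270)
  expect_error(iqr_filter(cbind(c(NA, 1))), "impute first")
})

test_that("quantile normalization maps samples to the mean sorted profile", {
  m <- cbind(s1 = exp(c(1, 2, 3)), s2 = exp(c(4, 5, 6)))
  rownames(m) <- paste0("f", 1:3)
  out <- log_quantile_normalize(m)
  expect_equal(unname(out[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(2.5, 3.5, 4.5))

  same <- cbind(s1 = exp(c(3, 1, 2)), s2 = exp(c(3, 1, 2)))
  expect_equal(log_quantile_normalize(same), log(same))

  set.seed(211)
  r <- matrix(exp(rnorm(60)), 12, 5)
  dimnames(r) <- list(paste0("f", 1:12), paste0("s", 1:5))
  nr <- log_quantile_normalize(r)
  sorted <- apply(nr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
  # idempotent once on the log scale
  expect_equal(log_quantile_normalize(nr, log = FALSE), nr, tolerance = 1e-9)
  bad <- r; bad[2, 3] <- -1
  expect_error(log_quantile_normalize(bad), "f2.*s3")
})

test_that("batch standardization removes a planted location shift", {
  set.seed(221)
  nf <- 60; ns <- 40
  batch <- rep(c("b1", "b2"), each = ns / 2)
  m <- matrix(rnorm(nf * ns, 8), nf, ns,
              dimnames = list(paste0("f", 1:nf), paste0("s", 1:ns)))
  m[, batch == "b2"] <- m[, batch == "b2"] + 2
  out <- batch_standardize(m, batch)
  p_batch <- apply(out, 1, function(x)
    anova(lm(x ~ factor(batch)))$`Pr(>F)`[1])
  expect_gte(mean(p_batch > 0.05), 0.95)
  # one batch only: unchanged
  expect_identical(batch_standardize(m, rep("b1", ns)), m)
  # commutes with feature reordering
  i <- sample(nf)
  expect_equal(batch_standardize(m[i, ], batch), out[i, ])
  expect_error(batch_standardize(m, c("b1", rep("b2", ns - 1))),
               "single-sample")
})

test_that("the preprocessing chain runs in the documented order", {
  cfg <- small_config(seed = 231)
  ch <- simulate_cohort(cfg)
  proc <- suppressMessages(preprocess_metabolome(
    ch$metabolome$intensities, ch$samples$batch))
  expect_false(anyNA(proc))
  expect_lte(nrow(proc), nrow(ch$metabolome$intensities))
  sorted <- apply(proc, 2, sort)
  # batch standardization perturbs the exact quantile tie, but profiles stay close
  expect_lt(max(abs(sorted - rowMeans(sorted))), 1.0)
})

test_that("per-feature linear models match lm and stay calibrated", {
  set.seed(241)
  ns <- 40
  data <- data.frame(dx = rep(c("nonIBD", "CD"), each = ns / 2),
                     gender = sample(c("male", "female"), ns, TRUE))
  m <- matrix(rnorm(30 * ns), 30, ns,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:ns)))
  m[1, data$dx == "CD"] <- m[1, data$dx == "CD"] + 3
  res <- per_feature_models(m, data, "dx", "gender")
  data_ref <- data.frame(dx = relevel(factor(data$dx), "nonIBD"),
                         gender = relevel(factor(data$gender), "female"))
  f5 <- summary(lm(m[5, ] ~ gender + dx, data_ref))
  expect_equal(res$estimate[5], f5$coefficients["dxCD", "Estimate"],
               tolerance = 1e-10)
  expect_equal(res$p[5], f5$coefficients["dxCD", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_lt(res$q[1], 0.05)
  expect_error(per_feature_models(m, data, "absent"), "absent")
})

test_that("the bile log ratio is the guarded quotient with a Wilcoxon test", {
  m <- rbind(chol = c(100, 10, 7), deoxy = c(10, 10, 7))
  colnames(m) <- paste0("s", 1:3)
  res <- bile_log_ratio(m, "chol", "deoxy")
  expect_equal(unname(res$log_ratio), c(log(10), 0, 0))
  swapped <- bile_log_ratio(m, "deoxy", "chol")
  expect_equal(res$log_ratio, -swapped$log_ratio)
  expect_error(bile_log_ratio(m, "chol", "nope"), "nope")

  set.seed(251)
  m2 <- rbind(chol = exp(rnorm(40, c(rep(2, 20), rep(0, 20)))),
              deoxy = exp(rnorm(40, c(rep(-2, 20), rep(0, 20)))))
  colnames(m2) <- paste0("s", 1:40)
  grp <- rep(c("CD", "nonIBD"), each = 20)
  res2 <- bile_log_ratio(m2, "chol", "deoxy", group = grp)
  expect_lt(res2$test$p_value, 1e-4)
})

test_that("bai aggregation sums exactly the six orthologies", {
  kos <- c(bai_ko_ids(), "K00001")
  ko <- matrix(1e-4, length(kos), 3, dimnames = list(kos, paste0("s", 1:3)))
  expect_equal(unname(aggregate_bai(ko)), rep(6e-4, 3))
  expect_equal(aggregate_bai(ko[sample(nrow(ko)), ]), aggregate_bai(ko))
  partial <- ko[c("K15868", "K00001"), , drop = FALSE]
  expect_message(res <- aggregate_bai(partial), "contribute 0")
  expect_equal(unname(res), rep(1e-4, 3))
  expect_error(aggregate_bai(ko["K00001", , drop = FALSE]), "none of the six")
})

test_that("microbe-metabolite residual correlations find a monotone link", {
  set.seed(261)
  ns <- 30
  counts <- matrix(rnbinom(3 * ns, mu = 50, size = 5), 3, ns,
                   dimnames = list(paste0("t", 1:3), paste0("s", 1:ns)))
  m <- matrix(rnorm(2 * ns, 10), 2, ns,
              dimnames = list(c("f1", "f2"), paste0("s", 1:ns)))
  m[1, ] <- log1p(counts[1, ]) + rnorm(ns, 0, 1e-6)  # monotone in t1
  data <- data.frame(sample_id = paste0("s", 1:ns))
  res <- microbe_metabolite_correlations(counts, m, data,
                                         covariates = character(),
                                         sf = setNames(rep(1, ns), colnames(counts)))
  r11 <- res[res$taxon_id == "t1" & res$feature_id == "f1", ]
  expect_gt(r11$rho, 0.99)
  expect_equal(min(res$q, na.rm = TRUE), r11$q)
  expect_error(microbe_metabolite_correlations(
    counts, m[, 0, drop = FALSE], data), "no shared samples")
})
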