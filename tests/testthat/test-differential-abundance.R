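test_that("prevalence filter keeps the boundary and errors when empty", {
  set.seed(101)
  counts <- matrix(0L, 3, 100, dimnames = list(paste0("t", 1:3), NULL))
  counts[1, 1:24] <- 5L   # 24% prevalence: removed
  counts[2, 1:25] <- 5L   # exactly 25%: kept
  counts[3, ] <- 2L
  f <- prevalence_filter(counts, 0.25)
  expect_setequal(rownames(f), c("t2", "t3"))
  expect_identical(prevalence_filter(counts, 1e-9), counts)
  expect_error(prevalence_filter(counts[1:2, , drop = FALSE], 0.5),
               "all taxa removed")
  expect_error(prevalence_filter(counts, 0), "in \\(0, 1\\]")
})

test_that("size factors follow the median-of-ratios closed form", {
  a <- c(10, 20, 40, 8)
  counts <- cbind(s1 = a, s2 = 2 * a)
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(s1 = a, s2 = a, s3 = a)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # multiplying one sample by c multiplies only its factor by c (up to the
  # geometric-mean rescaling common to all)
  counts3 <- cbind(s1 = a, s2 = a + 3, s3 = a * 5)
  sf3 <- size_factors(counts3)
  counts3b <- counts3; counts3b[, 2] <- counts3[, 2] * 4
  sf3b <- size_factors(counts3b)
  expect_equal(unname(sf3b[2] / sf3[2] / (sf3b[1] / sf3[1])), 4,
               tolerance = 1e-12)

  # adding a taxon with identical counts across samples changes nothing
  # when the per-sample ratio medians are unaffected (pure depth scaling:
  # every existing taxon already contributes the sample's common ratio)
  scaled <- cbind(s1 = a, s2 = 2L * a, s3 = 4L * a)
  scaled4 <- rbind(scaled, constant = c(20, 20, 20))
  expect_equal(size_factors(scaled4), size_factors(scaled))

  # no all-positive taxon: positive-entry fallback with a notice
  sparse <- cbind(s1 = c(5L, 0L), s2 = c(0L, 8L))
  expect_message(sf_sp <- size_factors(sparse), "positive-entries-only")
  expect_true(all(is.finite(sf_sp) & sf_sp > 0))
})

test_that("dispersion fitting recovers the Poisson limit and a planted value", {
  set.seed(111)
  n <- 60
  data <- data.frame(g = factor(rep(c("a", "b"), each = n / 2)))
  # Poisson data: fitted dispersions collapse toward zero
  pois <- matrix(rpois(40 * n, lambda = 50), 40, n)
  rownames(pois) <- paste0("t", 1:40)
  colnames(pois) <- paste0("s", 1:n)
  dp <- fit_dispersions(pois, data, "g", sf = setNames(rep(1, n), colnames(pois)))
  expect_lt(median(dp$dispersion), 0.05)

  # NB with alpha = 0.5: recovered within the stated band at n = 100
  n2 <- 100
  data2 <- data.frame(g = factor(rep(c("a", "b"), each = n2 / 2)))
  nb <- matrix(rnbinom(40 * n2, mu = 80, size = 2), 40, n2)
  rownames(nb) <- paste0("t", 1:40)
  colnames(nb) <- paste0("s", 1:n2)
  dn <- fit_dispersions(nb, data2, "g", sf = setNames(rep(1, n2), colnames(nb)))
  expect_gt(median(dn$dispersion), 0.35)
  expect_lt(median(dn$dispersion), 0.65)

  # full shrinkage puts every taxon on the trend curve
  d1 <- fit_dispersions(nb, data2, "g", sf = setNames(rep(1, n2), colnames(nb)),
                        shrink_weight = 1)
  expect_equal(d1$dispersion, pmax(d1$trend, 1e-8), tolerance = 1e-9)
})

test_that("NB Wald coefficients match a brute-force likelihood oracle", {
  set.seed(121)
  n <- 12
  data <- data.frame(g = factor(rep(c("a", "b"), each = 6)))
  X <- model.matrix(~ g, data)
  sf <- exp(rnorm(n, 0, 0.1)); sf <- sf / exp(mean(log(sf)))
  names(sf) <- paste0("s", 1:n)
  alpha <- 0.3
  counts <- t(sapply(1:6, function(i) {
    beta <- c(log(50), rnorm(1, 0, 1))
    rnbinom(n, mu = sf * exp(drop(X %*% beta)), size = 1 / alpha)
  }))
  dimnames(counts) <- list(paste0("t", 1:6), names(sf))
  da <- nb_wald_test(counts, data, "g", sf = sf,
                     dispersions = rep(alpha, 6))
  for (i in 1:6) {
    opt <- optim(c(log(mean(counts[i, ])), 0), function(b)
      -oracle_nb_loglik(b, counts[i, ], X, log(sf), alpha),
      method = "BFGS", control = list(reltol = 1e-14))
    expect_equal(da$log2_fold_change[i] * log(2), opt$par[2], tolerance = 1e-4)
  }
  expect_true(all(da$p >= 0 & da$p <= 1))
  expect_error(nb_wald_test(counts, data.frame(g = rep("a", n)), "g"),
               "constant")
})

test_that("significance filters honor the q, sign and abundance rules", {
  da <- data.frame(
    taxon_id = paste0("t", 1:5),
    log2_fold_change = c(2, -2, 1.5, -1, 3),
    q = c(0.04, 0.04, 0.08, 0.2, 0.01),
    mean_norm_rel_abund = c(1e-6, 1e-3, 1e-3, 1e-3, 1e-3))
  s05 <- significant_sets(da, 0.05)
  expect_equal(s05$enriched, "t5")      # t1 fails the abundance floor
  expect_equal(s05$depleted, "t2")
  s10 <- significant_sets(da, 0.1)
  expect_true("t3" %in% s10$enriched)   # q = 0.08 enters at the GRS threshold
  da$q <- 1
  expect_message(s_empty <- significant_sets(da), "empty")
  expect_length(s_empty$enriched, 0)
  expect_error(significant_sets(da, q_threshold = 0), "thresholds")
})

test_that("the dysbiosis index is the guarded log ratio of set sums", {
  relab <- matrix(c(0.2, 0.1, 0.7,
                    0.15, 0.15, 0.7), 3, 2,
                  dimnames = list(c("e1", "d1", "x"), c("s1", "s2")))
  sets <- list(enriched = "e1", depleted = "d1")
  idx <- dysbiosis_index(relab, sets, pseudocount = 1e-12, relative = TRUE)
  expect_equal(unname(idx$index["s1"]), log(2), tolerance = 1e-9)
  expect_equal(unname(idx$index["s2"]), 0, tolerance = 1e-9)

  # swapping the sets flips the sign exactly when the pseudocount is shared
  swapped <- dysbiosis_index(relab, list(enriched = "d1", depleted = "e1"),
                             pseudocount = 1e-12, relative = TRUE)
  expect_equal(unname(idx$index), -unname(swapped$index), tolerance = 1e-9)

  # a zero depleted sum stays finite through the pseudocount
  relab0 <- matrix(c(0.5, 0, 0.5), 3, 1,
                   dimnames = list(c("e1", "d1", "x"), "s1"))
  idx0 <- dysbiosis_index(relab0, sets, pseudocount = 1e-6, relative = TRUE)
  expect_true(is.finite(idx0$index))
  expect_error(dysbiosis_index(relab, list(enriched = character(),
                                           depleted = character())),
               "empty")
  expect_error(dysbiosis_index(relab, sets, pseudocount = 0), "pseudocount")
})

test_that("planted CD effects are recovered end to end at small n", {
  cfg <- small_config(n_cd = 20, n_control = 20, seed = 131)
  ch <- simulate_cohort(cfg)
  cec <- ch$samples$site == "cecum"
  da <- nb_wald_test(prevalence_filter(ch$counts[, cec], 0.25),
                     ch$samples[cec, ], "dx", c("gender", "bmi_cat"))
  sets <- significant_sets(da)
  expect_gte(length(intersect(sets$enriched, ch$truth$cd_enriched)), 6)
  expect_gte(length(intersect(sets$depleted, ch$truth$cd_depleted)), 9)
  dys <- dysbiosis_index(ch$counts[, cec], sets)
  sp <- split(dys$index, ch$samples$dx[cec])
  expect_lt(wilcoxon_rank_sum(sp$CD, sp$nonIBD)$p_value, 0.01)
})
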