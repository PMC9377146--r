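test_that("cohort_config validates its fields and names the offender", {
  expect_error(cohort_config(n_taxa = 0), "n_taxa")
  expect_error(cohort_config(n_cd = -1), "n_cd")
  expect_error(cohort_config(n_cd = 0, n_control = 0), "n_cd")
  expect_error(cohort_config(behavior_split = 1.2), "behavior_split")
  expect_error(
    cohort_config(effect_sets = utils::modifyList(
      default_effect_sets(40),
      list(cd_enriched = data.frame(taxon = 999, lfc = 2))), n_taxa = 40),
    "cd_enriched")
})

test_that("metadata respects arm sizes, labels and the behavior split", {
  cfg <- small_config(n_cd = 0, n_control = 10)
  sub <- simulate_metadata(cfg)
  expect_equal(nrow(sub), 10)
  expect_true(all(sub$dx == "nonIBD"))
  expect_true(all(is.na(sub$behavior)))
  expect_true(all(is.na(sub$progression)))

  cfg2 <- small_config(n_cd = 100, n_control = 0, behavior_split = 0.5, seed = 3)
  sub2 <- simulate_metadata(cfg2)
  n_b1 <- sum(sub2$behavior == "B1")
  bounds <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_gte(n_b1, bounds[1])
  expect_lte(n_b1, bounds[2])
  expect_true(all(sub2$bmi_cat %in% c("lt25", "25to30", "gt30")))
})

test_that("the whole cohort is deterministic given the seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$metabolome$intensities, b$metabolome$intensities)
  expect_identical(a$subjects, b$subjects)
})

test_that("counts are non-negative integers with softmax-composition structure", {
  cfg <- small_config(seed = 5)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$counts >= 0))
  expect_true(all(ch$counts == round(ch$counts)))
  relab <- sweep(ch$counts, 2, colSums(ch$counts), "/")
  expect_equal(unname(colSums(relab)), rep(1, ncol(relab)))
  expect_equal(ncol(ch$counts), 2 * nrow(ch$subjects))
  expect_setequal(unique(ch$samples$site), c("cecum", "sigmoid"))
})

test_that("a single taxon receives the whole library (softmax degenerates)", {
  cfg <- null_cohort_config(n_cd = 2, n_control = 2, n_taxa = 1,
                            library_size_log_sd = 0, dispersion_shape = 100,
                            dispersion_mean = 1e-4, seed = 2)
  sub <- simulate_metadata(cfg)
  cnt <- simulate_counts(cfg, sub)
  lib <- exp(cfg$library_size_log_mean)
  # counts are Poisson-like around the library size with vanishing dispersion
  expect_true(all(abs(colSums(cnt$counts) - lib) < 5 * sqrt(lib)))
})

test_that("a strongly CD-enriched taxon is enriched in every replicate", {
  es <- default_effect_sets(40)
  for (r in 1:5) {
    cfg <- small_config(seed = 100 + r, effect_sets = es)
    sub <- simulate_metadata(cfg, seed = NULL)
    cnt <- simulate_counts(cfg, sub, seed = NULL)
    relab <- sweep(cnt$counts, 2, colSums(cnt$counts), "/")
    cd <- cnt$samples$dx == "CD"
    for (tx in cnt$truth$cd_enriched[1:3]) {
      expect_gt(mean(relab[tx, cd]), mean(relab[tx, !cd]))
    }
  }
})

test_that("genotypes honor allele frequencies, panel size and the GRS offset", {
  cfg <- small_config(maf_range = c(0, 0), seed = 4)
  g0 <- simulate_genotypes(cfg, simulate_metadata(cfg))
  expect_true(all(g0$dosages == 0))

  cfg_default <- cohort_config(seed = 6)
  expect_equal(nrow(simulate_genotypes(
    cfg_default, simulate_metadata(cfg_default))$weights), 186)

  cfg_null <- small_config(n_cd = 150, n_control = 150, grs_case_offset = 0,
                           n_snps = 100, seed = 8)
  sub <- simulate_metadata(cfg_null, seed = NULL)
  geno <- simulate_genotypes(cfg_null, sub, seed = NULL)
  grs <- compute_grs(geno$dosages, geno$weights)
  diff <- mean(grs[sub$dx == "CD"]) - mean(grs[sub$dx == "nonIBD"])
  se <- sqrt(var(grs[sub$dx == "CD"]) / 150 + var(grs[sub$dx == "nonIBD"]) / 150)
  expect_lt(abs(diff), 4 * se)
})

test_that("metabolome missingness targets low intensities and shifts are planted", {
  cfg <- small_config(missingness_slope = 5, missingness_intercept = 40, seed = 9)
  ch <- simulate_cohort(cfg)
  m <- ch$metabolome
  miss <- is.na(m$intensities)
  expect_true(any(miss) && !all(miss))
  expect_lt(mean(log(m$complete[miss])), mean(log(m$complete[!miss])))

  # planted difference in the mean log ratio ~ 2 * shift * ln 2
  for (shift in c(0, 2)) {
    cfg2 <- small_config(n_cd = 150, n_control = 150, bile_shift_log2 = shift,
                         missingness_intercept = -20, seed = 20 + shift)
    sub <- simulate_metadata(cfg2, seed = NULL)
    samples <- data.frame(sample_id = sub$subject_id, dx = sub$dx,
                          batch = "batch1")
    mt <- simulate_metabolome(cfg2, samples, seed = NULL)
    lr <- log(mt$intensities[mt$truth$cholate_id, ] /
              mt$intensities[mt$truth$deoxycholate_id, ])
    d <- mean(lr[sub$dx == "CD"]) - mean(lr[sub$dx == "nonIBD"])
    expect_lt(abs(d - 2 * shift * log(2)), 0.25)
  }
})

test_that("KO table is the incidence-weighted taxon composition", {
  cfg <- small_config(seed = 12)
  ch <- simulate_cohort(cfg)
  ko_raw <- simulate_ko_table(cfg, ch$counts, ch$truth, seed = 99,
                              normalize = FALSE)
  relab <- sweep(ch$counts, 2, colSums(ch$counts), "/")
  expect_equal(ko_raw$ko, t(ko_raw$incidence) %*% relab)
  # a KO with no carrier is zero everywhere
  inc0 <- ko_raw$incidence
  no_carrier <- which(colSums(inc0) == 0)
  if (length(no_carrier))
    expect_true(all(ko_raw$ko[no_carrier, ] == 0))
  expect_true(all(ko_raw$bai_carriers %in% ch$truth$cd_depleted))
  expect_error(simulate_ko_table(cfg, ch$counts[-1, ], ch$truth), "taxon sets")
})

test_that("planted depletion of bai carriers lowers the pathway in CD", {
  wins <- 0
  for (r in 1:10) {
    cfg <- small_config(seed = 300 + r)
    ch <- simulate_cohort(cfg)
    bai <- aggregate_bai(ch$ko$ko)
    cd <- ch$samples$dx == "CD"
    wins <- wins + (mean(bai[cd]) < mean(bai[!cd]))
  }
  expect_gte(wins, 9)
})

test_that("write_cohort produces the full plain-text layout", {
  dir <- tempfile("cohort_")
  ch <- simulate_cohort(small_config(n_cd = 4, n_control = 4, seed = 13))
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "counts.tsv", "samples.tsv", "subjects.tsv", "dosages.tsv",
    "weights.tsv", "metabolites.tsv", "ko.tsv", "ground_truth.json")))))
  cnt <- as.matrix(read.delim(file.path(dir, "counts.tsv"), row.names = 1))
  expect_equal(unname(cnt), unname(ch$counts))
})
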