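test_that("invalid configurations are rejected", {
  expect_error(gen_config(n_participants = 0), class = "ckm_invalid_config")
  expect_error(gen_config(n_features = 0), class = "ckm_invalid_config")
  expect_error(gen_config(K_true = 5, alpha_gen = rep(0.3, 3)),
               class = "ckm_invalid_config")
  expect_error(gen_config(n_variants = 10, maf_range = c(0, 0.5)),
               class = "ckm_invalid_config")
  expect_error(gen_config(n_variants = 10, maf_range = c(0.1, 0.6)),
               class = "ckm_invalid_config")
  expect_error(gen_config(n_variants = 10,
                          platform_fractions = c(0.5, 0.5, 0.5)),
               class = "ckm_invalid_config")
  expect_error(
    generate_genotypes(gen_config(n_variants = 0)),
    class = "ckm_invalid_config")
})

test_that("same seed reproduces the cohort bit-for-bit", {
  cfg <- gen_config(n_participants = 150, n_features = 6, K_true = 3,
                    n_variants = 20, missing_rates = 0.2, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$binned$levels, b$binned$levels)
  expect_identical(a$truth$theta, b$truth$theta)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(generate_genotypes(cfg)$dosage, a$geno$dosage)
})

test_that("null disease weights give baseline prevalence", {
  specs <- list(disease_spec("dz", 0, rep(0, 3)))
  cfg <- gen_config(n_participants = 10000, n_features = 4, K_true = 3,
                    disease_specs = specs, seed = 21)
  coh <- generate_cohort(cfg)
  # logistic(0) = 0.5; binomial 99.9% band at n = 10,000 is about +-0.016
  expect_lt(abs(mean(coh$pheno$dz) - 0.5), 0.02)
})

test_that("K_true = 1 forces degenerate loadings", {
  cfg <- gen_config(n_participants = 50, n_features = 4, K_true = 1,
                    alpha_gen = 0.3, seed = 2)
  coh <- generate_cohort(cfg)
  expect_equal(unname(coh$truth$theta[, 1]), rep(1, 50))
})

test_that("per-feature missingness hits its configured rate", {
  # emulates a biomarker observed for about a third of participants
  cfg <- gen_config(n_participants = 5000, n_features = 3, K_true = 2,
                    missing_rates = c(0.655, 0, 0), seed = 13)
  coh <- generate_cohort(cfg)
  obs_frac <- mean(!is.na(coh$binned$levels[, 1]))
  expect_lt(abs(obs_frac - 0.345), 0.02)
  expect_true(all(!is.na(coh$binned$levels[, 2:3])))
  # missing entries appear exactly where the recorded mask is true
  expect_equal(is.na(coh$binned$levels), coh$truth$missing_mask,
               ignore_attr = TRUE)
})

test_that("single-topic level frequencies converge to the true phi row", {
  cfg <- gen_config(n_participants = 20000, n_features = 6, K_true = 1,
                    alpha_gen = 1, seed = 31)
  coh <- generate_cohort(cfg)
  for (f in 1:6) {
    emp <- tabulate(coh$binned$levels[, f] + 1L, nbins = 5) / 20000
    tv <- 0.5 * sum(abs(emp - coh$truth$phi_levels[[f]][1, ]))
    expect_lt(tv, 0.02)
  }
})

test_that("generated levels are always in range and match the mixture", {
  cfg <- gen_config(n_participants = 300, n_features = 5, K_true = 3,
                    seed = 5)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$binned$levels >= 0 & coh$binned$levels <= 4,
                  na.rm = TRUE))
  expect_true(all(abs(rowSums(coh$truth$theta) - 1) < 1e-9))
  expect_true(all(abs(rowSums(coh$truth$phi) - 1) < 1e-9))
})

test_that("dosages have the expected mean at a fixed allele frequency", {
  cfg <- gen_config(n_participants = 10000, n_features = 2, K_true = 2,
                    n_variants = 1, ld_block_size = 1,
                    maf_range = c(0.5, 0.5), seed = 41)
  g <- generate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(abs(mean(g$dosage) - 1), 0.05)
})

test_that("blocks of size 1 give independent variants", {
  cfg <- gen_config(n_participants = 2000, n_features = 2, K_true = 2,
                    n_variants = 30, ld_block_size = 1,
                    maf_range = c(0.2, 0.4), seed = 43)
  g <- generate_genotypes(cfg)
  # force all variants onto one chromosome position-wise comparison is
  # irrelevant here; just test pairwise correlations against the
  # permutation null: E[r^2] under independence is ~ 1/(n-1)
  r2 <- cor(g$dosage)^2
  obs <- mean(r2[upper.tri(r2)])
  set.seed(1)
  null_r2 <- replicate(200, {
    i <- sample(30, 2)
    cor(g$dosage[, i[1]], sample(g$dosage[, i[2]]))^2
  })
  expect_lt(obs, mean(null_r2) + 3 * sd(null_r2))
})

test_that("within-block LD is strong, between-block absent", {
  cfg <- gen_config(n_participants = 2000, n_features = 2, K_true = 2,
                    n_variants = 20, ld_block_size = 10, ld_rho = 0.9,
                    seed = 47)
  g <- generate_genotypes(cfg)
  within <- cor(g$dosage[, 1:10])^2
  between <- cor(g$dosage[, 1:10], g$dosage[, 11:20])^2
  expect_gt(mean(within[upper.tri(within)]), 0.3)
  expect_lt(mean(between), 0.01)
})

test_that("platform split follows the configured fractions", {
  cfg <- gen_config(n_participants = 10000, n_features = 2, K_true = 2,
                    n_variants = 5, platform_fractions = c(0.12, 0.45, 0.43),
                    seed = 53)
  g <- generate_genotypes(cfg)
  counts <- tabulate(g$platform, nbins = 3)
  expected <- c(1200, 4500, 4300)
  # 99% binomial bounds
  for (i in 1:3) {
    p <- expected[i] / 10000
    half <- 2.58 * sqrt(10000 * p * (1 - p))
    expect_lt(abs(counts[i] - expected[i]), half + 1)
  }
})

test_that("genetic tilt raises loadings monotonically in dosage", {
  ge <- data.frame(variant = 1, topic = 1, gamma = 0.5)
  cfg <- gen_config(n_participants = 6000, n_features = 2, K_true = 3,
                    n_variants = 1, ld_block_size = 1,
                    maf_range = c(0.3, 0.3), genetic_effects = ge, seed = 61)
  coh <- generate_cohort(cfg)
  g <- coh$geno$dosage[, 1]
  means <- tapply(coh$truth$theta[, 1], g, mean)
  expect_true(all(diff(means) > 0))
})
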