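test_that("per-variant OLS matches lm() exactly, monomorphics excluded", {
  set.seed(1)
  n <- 300
  g <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.1),
             mono = rep(1L, n))
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 0.2 * g[, 1] + 0.1 * covs$age + rnorm(n)
  res <- gwas_platform(y, g, covs)
  for (v in c("a", "b")) {
    fit <- summary(lm(y ~ g[, v] + age + sex, data = covs))$coefficients
    i <- which(res$variant == v)
    expect_equal(res$beta[i], fit[2, 1], tolerance = 1e-10)
    expect_equal(res$se[i], fit[2, 2], tolerance = 1e-10)
    expect_equal(res$p[i], fit[2, 4], tolerance = 1e-10)
  }
  expect_true(is.na(res$beta[res$variant == "mono"]))
})

test_that("inverse-variance meta-analysis matches the closed form", {
  m <- meta_fixed(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(m$beta, 0.3, tolerance = 1e-12)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # single platform: identity
  m1 <- meta_fixed(0.25, 0.07)
  expect_equal(m1$beta, 0.25)
  expect_equal(m1$se, 0.07)
  # invariant to platform order
  ma <- meta_fixed(c(0.1, 0.3, -0.2), c(0.05, 0.2, 0.11))
  mb <- meta_fixed(c(-0.2, 0.1, 0.3), c(0.11, 0.05, 0.2))
  expect_equal(ma$beta, mb$beta, tolerance = 1e-12)
  expect_equal(ma$se, mb$se, tolerance = 1e-12)
  # an infinitely uncertain platform contributes nothing
  m2 <- meta_fixed(c(0.2, 5), c(0.1, Inf))
  expect_equal(m2$beta, 0.2, tolerance = 1e-9)
  expect_equal(m2$se, 0.1, tolerance = 1e-9)
  # all-undefined record stays undefined
  m3 <- meta_fixed(c(NA, NA), c(NA, NA))
  expect_true(is.na(m3$beta))
})

test_that("meta-analysis matches a stacked weighted-least-squares oracle", {
  set.seed(2)
  n <- 900
  platform <- rep(1:3, each = 300)
  g <- rbinom(n, 2, 0.4)
  y <- 0.15 * g + rnorm(n)
  per <- lapply(1:3, function(pl) {
    idx <- platform == pl
    gwas_platform(y[idx], cbind(v = g[idx]))
  })
  meta <- meta_fixed(vapply(per, function(x) x$beta, numeric(1)),
                     vapply(per, function(x) x$se, numeric(1)))
  # oracle: OLS on stacked data with platform-specific intercepts
  oracle <- summary(lm(y ~ g + factor(platform)))$coefficients["g", ]
  expect_equal(meta$beta, unname(oracle[1]), tolerance = 0.02)
})

test_that("genomic inflation is 1 at the null median and monotone", {
  expect_equal(lambda_gc(rep(0.5, 200)), 1, tolerance = 1e-6)
  set.seed(3)
  p <- runif(5000)
  expect_gt(lambda_gc(pmin(p / 2, 1)), lambda_gc(p))
  expect_warning(lambda_gc(runif(50)), "fewer than 100")
})

test_that("run_gwas splits platforms and meta-analyzes with lambda", {
  ge <- data.frame(variant = 3, topic = 1, gamma = 0.4)
  cfg <- gen_config(n_participants = 3000, n_features = 4, K_true = 3,
                    n_variants = 120, ld_block_size = 1,
                    genetic_effects = ge, seed = 7)
  coh <- generate_cohort(cfg)
  y <- rank_transform(coh$truth$theta[, 1], "rint")
  gw <- run_gwas(y, coh$geno, coh$pheno[, c("age", "sex")])
  expect_s3_class(gw, "ckm_gwas")
  expect_equal(nrow(gw), 120)
  expect_true(gw$significant[3])
  expect_true(all(c("beta_p1", "se_p3", "beta", "se", "p") %in% names(gw)))
  expect_gt(attr(gw, "lambda"), 0.8)
  expect_lt(attr(gw, "lambda"), 1.3)
  g <- glance(gw)
  expect_equal(g$n_variants, 120)
})

test_that("clumping keeps one lead per LD block and per chromosome", {
  # construct a deterministic gwas table + genotypes: a perfect-LD pair on
  # one chromosome and an independent significant variant on another
  set.seed(8)
  g1 <- rbinom(500, 2, 0.3)
  g3 <- rbinom(500, 2, 0.3)
  dosage <- cbind(v1 = g1, v2 = g1, v3 = g3)
  tab <- tibble::tibble(
    id = c("v1", "v2", "v3"), chr = c(1L, 1L, 2L),
    pos = c(1000L, 2000L, 1000L), ea = "A", nea = "G",
    maf = 0.3, block = c(1L, 1L, 2L),
    beta = c(0.5, 0.4, 0.3), se = 0.01,
    p = c(1e-20, 1e-15, 1e-12), significant = TRUE)
  class(tab) <- c("ckm_gwas", class(tab))
  attr(tab, "sig_threshold") <- 1e-8
  out <- clump_leads(tab, dosage)
  expect_equal(out$lead, c(TRUE, FALSE, TRUE))
  # determinism
  expect_identical(out$lead, clump_leads(tab, dosage)$lead)
  # nothing significant -> no leads
  tab2 <- tab
  tab2$significant <- FALSE
  expect_equal(sum(clump_leads(tab2, dosage)$lead), 0)
})

test_that("a single-lead PRS is the standardized dosage", {
  set.seed(9)
  dosage <- cbind(rsX = rbinom(400, 2, 0.4))
  prs <- structure(list(weights = tibble::tibble(variant = "rsX", weight = 1),
                        subtype = "s"), class = "ckm_prs")
  sc <- score_prs(prs, dosage)
  expect_equal(sc, as.vector(scale(dosage[, 1])), tolerance = 1e-12)
  # absent variants are dropped with a warning
  prs2 <- structure(list(weights = tibble::tibble(variant = c("rsX", "rsZ"),
                                                  weight = c(1, 2)),
                         subtype = "s"), class = "ckm_prs")
  expect_warning(sc2 <- score_prs(prs2, dosage), "absent")
  expect_equal(sc2, sc)
})

test_that("PRS validation finds a planted signal and not a permuted one", {
  set.seed(10)
  n <- 4000
  g <- rbinom(n, 2, 0.3)
  risk <- plogis(-2 + 0.5 * g)
  dz <- rbinom(n, 1, risk)
  sc <- as.vector(scale(g))
  v <- validate_prs(sc, data.frame(dz = dz))
  expect_lt(v$p, 0.01)
  expect_equal(v$direction, 1)
  vperm <- validate_prs(sc, data.frame(dz = sample(dz)))
  expect_gt(vperm$p, 1e-4)
  # linear-probability option agrees in direction
  vlin <- validate_prs(sc, data.frame(dz = dz), family = "linear")
  expect_equal(vlin$direction, 1)
})

test_that("indicator GWAS covers every feature-level pair", {
  cfg <- gen_config(n_participants = 500, n_features = 3, K_true = 2,
                    seed = 11)
  coh <- generate_cohort(cfg)
  set.seed(11)
  g <- rbinom(500, 2, 0.3)
  sl <- single_level_gwas(coh$binned, g)
  expect_equal(nrow(sl), 3 * 5)
  observed <- !is.na(sl$p)
  expect_gt(sum(observed), 10)
  expect_true(all(is.finite(sl$p[observed])))
})
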