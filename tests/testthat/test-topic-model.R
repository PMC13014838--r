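test_that("tokenization emits one token per observed entry", {
  lev <- matrix(0L, 3, 20)
  lev[1, 1:6] <- NA_integer_  # participant 1: 14 of 20 observed
  b <- toy_binned(lev, n_levels = rep(5L, 20))
  tok <- tokenize(b)
  expect_equal(sum(tok$doc == 0L), 14)
  expect_equal(length(tok$doc), 14 + 20 + 20)

  full <- toy_binned(matrix(1L, 7, 4), n_levels = rep(5L, 4))
  expect_equal(length(tokenize(full)$doc), 7 * 4)
})

test_that("all-missing features are absent from the vocabulary", {
  lev <- cbind(a = c(0L, 1L), b = c(NA_integer_, NA_integer_))
  b <- toy_binned(lev, n_levels = c(5L, 5L))
  tok <- tokenize(b)
  expect_false("b" %in% tok$vocab$feature)
})

test_that("zero-token participants are retained with a warning count", {
  lev <- rbind(c(0L, 1L), c(NA_integer_, NA_integer_))
  colnames(lev) <- c("a", "b")
  b <- toy_binned(lev, n_levels = c(5L, 5L))
  expect_warning(tok <- tokenize(b), "zero observed")
  expect_equal(tok$n_empty, 1L)
  expect_equal(tok$n_docs, 2L)
  # prior-only posterior: uniform loading
  fit <- suppressWarnings(
    fit_chain(b, K = 3, n_burn = 5, n_samples = 2, thin = 1, seed = 1))
  expect_equal(unname(fit$theta[[1]][2, ]), rep(1 / 3, 3))
})

test_that("a sweep conserves counts and matches a full recount", {
  set.seed(4)
  lev <- matrix(sample(0:4, 40 * 6, replace = TRUE), 40, 6)
  b <- toy_binned(lev, n_levels = rep(5L, 6))
  tok <- tokenize(b)
  V <- nrow(tok$vocab)
  z0 <- sample(0:2, length(tok$doc), replace = TRUE)
  out <- cpp_gibbs_sweep(tok$doc, tok$word, z0, tok$n_docs, V, 3L, 0.5, 0.1)
  # recount from scratch
  ndk <- matrix(0L, tok$n_docs, 3)
  nkv <- matrix(0L, 3, V)
  for (i in seq_along(tok$doc)) {
    k <- out$z[i] + 1L
    ndk[tok$doc[i] + 1L, k] <- ndk[tok$doc[i] + 1L, k] + 1L
    nkv[k, tok$word[i] + 1L] <- nkv[k, tok$word[i] + 1L] + 1L
  }
  expect_identical(out$n_dk, ndk)
  expect_identical(out$n_kv, nkv)
  expect_equal(out$n_k, rowSums(nkv), ignore_attr = TRUE)
  expect_equal(sum(out$n_dk), length(tok$doc))
})

test_that("K = 1 is degenerate: assignments never move", {
  lev <- matrix(sample(0:4, 30, replace = TRUE), 10, 3)
  b <- toy_binned(lev, n_levels = rep(5L, 3))
  tok <- tokenize(b)
  z0 <- rep(0L, length(tok$doc))
  out <- cpp_gibbs_sweep(tok$doc, tok$word, z0, tok$n_docs,
                         nrow(tok$vocab), 1L, 1, 0.1)
  expect_identical(out$z, z0)
})

test_that("single-token two-topic chain visits both states equally", {
  # one participant, one token, K = 2, symmetric hyperparameters: the
  # two-state chain's stationary law is (1/2, 1/2) by exact enumeration
  b <- toy_binned(matrix(0L, 1, 1), n_levels = 5L)
  tok <- tokenize(b)
  set.seed(11)
  hits <- 0L
  z <- 0L
  for (s in 1:4000) {
    out <- cpp_gibbs_sweep(tok$doc, tok$word, z, 1L, 1L, 2L, 0.5, 0.1)
    z <- out$z
    hits <- hits + (z == 1L)
  }
  expect_lt(abs(hits / 4000 - 0.5), 0.03)
})

test_that("fixed seeds reproduce a chain exactly", {
  set.seed(3)
  lev <- matrix(sample(0:4, 50 * 5, replace = TRUE), 50, 5)
  b <- toy_binned(lev, n_levels = rep(5L, 5))
  f1 <- fit_chain(b, K = 3, n_burn = 20, n_samples = 5, thin = 2, seed = 77)
  f2 <- fit_chain(b, K = 3, n_burn = 20, n_samples = 5, thin = 2, seed = 77)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("posterior sample rows are normalized", {
  set.seed(5)
  lev <- matrix(sample(0:4, 60 * 4, replace = TRUE), 60, 4)
  b <- toy_binned(lev, n_levels = rep(5L, 4))
  f <- fit_chain(b, K = 4, n_burn = 10, n_samples = 3, thin = 1, seed = 2)
  for (s in 1:3) {
    expect_true(all(abs(rowSums(f$phi[[s]]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(f$theta[[s]]) - 1) < 1e-9))
  }
})

test_that("collapsed log-likelihood is invariant under topic relabeling", {
  set.seed(6)
  lev <- matrix(sample(0:4, 40 * 4, replace = TRUE), 40, 4)
  b <- toy_binned(lev, n_levels = rep(5L, 4))
  tok <- tokenize(b)
  z <- sample(0:2, length(tok$doc), replace = TRUE)
  V <- nrow(tok$vocab)
  ll <- cpp_collapsed_loglik(tok$doc, tok$word, z, tok$n_docs, V, 3L, 0.3, 0.1)
  relab <- c(2L, 0L, 1L)[z + 1L]
  ll2 <- cpp_collapsed_loglik(tok$doc, tok$word, relab, tok$n_docs, V, 3L,
                              0.3, 0.1)
  expect_equal(ll, ll2, tolerance = 1e-12)
})

test_that("two sharp topics are recovered from synthetic data", {
  cfg <- gen_config(n_participants = 1000, n_features = 10, K_true = 2,
                    topic_sharpness = 0.1, alpha_gen = c(0.4, 0.4), seed = 14)
  coh <- generate_cohort(cfg)
  fit <- fit_chain(coh$binned, K = 2, n_burn = 200, n_samples = 40, thin = 2,
                   seed = 14)
  pm <- phi_mean(fit)
  truth <- coh$truth$phi[, colnames(pm)]
  m <- match_topics(truth, pm)
  tvs <- vapply(1:2, function(k)
    0.5 * sum(abs(truth[k, ] - pm[m$perm[k], ])), numeric(1))
  expect_lt(mean(tvs), 0.05)
})

test_that("recovery degrades gracefully under heavy missingness", {
  cfg <- gen_config(n_participants = 1500, n_features = 10, K_true = 2,
                    topic_sharpness = 0.1, alpha_gen = c(0.4, 0.4),
                    missing_rates = rep(c(0.6, 0), each = 5), seed = 15)
  coh <- generate_cohort(cfg)
  fit <- fit_chain(coh$binned, K = 2, n_burn = 200, n_samples = 40, thin = 2,
                   seed = 15)
  pm <- phi_mean(fit)
  # under uneven missingness the estimable token distribution weights each
  # feature by its observation rate; weight the truth identically
  truth <- coh$truth$phi[, colnames(pm)]
  feat <- sub(":[0-9]+$", "", colnames(pm))
  obs_rate <- colMeans(!is.na(coh$binned$levels))
  wts <- obs_rate[feat] / sum(obs_rate[feat] / 5)  # 5 levels per feature
  truth_obs <- sweep(truth, 2, wts * 10, `*`)       # rescale from 1/F weights
  truth_obs <- truth_obs / rowSums(truth_obs)
  m <- match_topics(truth_obs, pm)
  tvs <- vapply(1:2, function(k)
    0.5 * sum(abs(truth_obs[k, ] - pm[m$perm[k], ])), numeric(1))
  expect_lt(mean(tvs), 0.15)
})

test_that("held-out scores are log-probabilities and K = 1 matches the
           smoothed unigram oracle", {
  set.seed(16)
  lev <- matrix(sample(0:4, 200 * 6, replace = TRUE), 200, 6)
  b <- toy_binned(lev, n_levels = rep(5L, 6))
  colnames(lev) <- sprintf("f%02d", 1:6)
  b_tr <- new_binned_cohort(lev[1:100, ], ids = sprintf("A%03d", 1:100),
                            sex = rep("f", 100), n_levels = rep(5L, 6))
  b_va <- new_binned_cohort(lev[101:200, ], ids = sprintf("B%03d", 1:100),
                            sex = rep("f", 100), n_levels = rep(5L, 6))
  hs <- heldout_score(b_tr, b_va, K = 1, n_burn = 5, n_samples = 2, thin = 1)
  expect_lt(hs$score, 0)
  # oracle: for K = 1 phi is deterministic from training counts
  tok_tr <- tokenize(b_tr)
  V <- nrow(tok_tr$vocab)
  counts <- tabulate(tok_tr$word + 1L, nbins = V)
  phi1 <- (counts + 0.1) / (sum(counts) + V * 0.1)
  # held-back = odd-indexed tokens of each validation participant
  tok_va <- tokenize(b_va)
  key_tr <- paste0(tok_tr$vocab$feature, ":", tok_tr$vocab$level)
  key_va <- paste0(tok_va$vocab$feature, ":", tok_va$vocab$level)
  w <- match(key_va, key_tr)[tok_va$word + 1L]
  idx <- sequence(rle(tok_va$doc)$lengths) - 1L
  oracle <- mean(log(phi1[w[idx %% 2L == 1L]]))
  expect_equal(hs$score, oracle, tolerance = 1e-12)
})

test_that("K selection returns singleton grids, is deterministic, and
           rejects empty grids", {
  cfg <- gen_config(n_participants = 300, n_features = 8, K_true = 3,
                    seed = 18)
  coh <- generate_cohort(cfg)
  s1 <- select_K(coh$binned, K_grid = 4, split_seed = 5,
                 n_burn = 20, n_samples = 5, thin = 1)
  expect_equal(s1$K, 4L)
  s2 <- select_K(coh$binned, K_grid = c(2, 3), split_seed = 5,
                 n_burn = 20, n_samples = 5, thin = 1)
  s3 <- select_K(coh$binned, K_grid = c(2, 3), split_seed = 5,
                 n_burn = 20, n_samples = 5, thin = 1)
  expect_identical(s2$curve, s3$curve)
  expect_error(select_K(coh$binned, integer(0)),
               class = "ckm_invalid_config")
})

test_that("entropy diagnostic: identities and degenerate cases", {
  # uniform loadings have entropy ln K exactly
  th <- matrix(1 / 4, 10, 4)
  H <- -rowSums(th * log(th))
  expect_equal(unname(H), rep(log(4), 10))

  phi <- random_phi(2, 5)
  set.seed(19)
  ths <- lapply(1:6, function(s) {
    m <- matrix(rgamma(20 * 2, 1), 20, 2)
    m / rowSums(m)
  })
  ch <- fake_chain(rep(list(phi), 6), ths)
  # identical chains: between-chain variance is 0, statistic ~ sqrt((S-1)/S)
  d <- entropy_diagnostic(list(ch, ch, ch))
  expect_true(all(abs(d$rhat - sqrt(5 / 6)) < 1e-12))
  expect_true(d$pass)
  expect_error(entropy_diagnostic(list(ch)), class = "ckm_diagnostic_error")
})

test_that("independently seeded chains on the same data pass the diagnostic", {
  cfg <- gen_config(n_participants = 400, n_features = 10, K_true = 3,
                    seed = 23)
  coh <- generate_cohort(cfg)
  chains <- fit_chains(coh$binned, K = 3, n_chains = 3, base_seed = 23,
                       n_burn = 150, n_samples = 30, thin = 2)
  d <- entropy_diagnostic(chains)
  expect_true(d$pass)
})
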