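test_that("matching an ensemble to itself is the identity at zero cost", {
  set.seed(1)
  phi <- random_phi(4, 10)
  m <- match_topics(phi, phi)
  expect_equal(m$perm, 1:4)
  expect_equal(m$cost, 0, tolerance = 1e-12)
})

test_that("a cyclic relabeling is inverted exactly", {
  set.seed(2)
  phi <- random_phi(5, 12)
  shift <- c(3, 4, 5, 1, 2)
  m <- match_topics(phi, phi[shift, ])
  # perm[a] indexes the row of the shifted matrix holding reference topic a
  expect_equal(m$perm, order(shift))
  expect_equal(m$cost, 0, tolerance = 1e-12)
})

test_that("assignment equals the brute-force optimum for K <= 6", {
  set.seed(3)
  for (K in c(3, 4, 6)) {
    for (rep in 1:5) {
      phi <- random_phi(K, 15)
      noise <- matrix(rgamma(K * 15, 20), K, 15)
      other <- phi[sample(K), ] * noise
      other <- other / rowSums(other)
      colnames(other) <- colnames(phi)
      m <- match_topics(phi, other)
      sr <- sqrt(phi); so <- sqrt(other)
      cost <- 1 - tcrossprod(sr, so)
      bf <- brute_force_match(cost)
      expect_equal(m$cost, bf$cost, tolerance = 1e-12)
    }
  }
})

test_that("mismatched shapes raise an alignment error", {
  expect_error(match_topics(random_phi(3, 5), random_phi(4, 5)),
               class = "ckm_alignment_error")
  chains_bad <- list(fake_chain(list(random_phi(2, 5)),
                                list(matrix(0.5, 3, 2))),
                     fake_chain(list(random_phi(3, 5)),
                                list(matrix(1 / 3, 3, 3))))
  expect_error(align_ensemble(chains_bad), class = "ckm_alignment_error")
  expect_error(align_ensemble(chains_bad[1]), class = "ckm_alignment_error")
})

test_that("pooling identical chains reproduces the single-chain mean and
           valid credible intervals", {
  set.seed(4)
  phis <- lapply(1:5, function(s) random_phi(3, 8))
  ths <- lapply(1:5, function(s) {
    m <- matrix(rgamma(12, 1), 4, 3)
    m / rowSums(m)
  })
  ch <- fake_chain(phis, ths)
  ens <- align_ensemble(list(ch, ch))
  single <- phi_mean(ch)
  expect_equal(unname(pooled_phi(ens)), unname(single), tolerance = 1e-12)
  expect_true(all(ens$pooled$lower <= ens$pooled$mean + 1e-12))
  expect_true(all(ens$pooled$upper >= ens$pooled$mean - 1e-12))
})

test_that("alignment relabels but never alters sample content", {
  cfg <- gen_config(n_participants = 300, n_features = 8, K_true = 3,
                    seed = 6)
  coh <- generate_cohort(cfg)
  chains <- fit_chains(coh$binned, K = 3, n_chains = 3, base_seed = 31,
                       n_burn = 80, n_samples = 10, thin = 1)
  ens <- align_ensemble(chains)
  for (c in 1:3) {
    for (s in 1:10) {
      orig <- chains[[c]]$phi[[s]]
      alig <- ens$chains[[c]]$phi[[s]]
      # same multiset of phi rows
      expect_equal(orig[order(orig[, 1]), ], alig[order(alig[, 1]), ],
                   ignore_attr = TRUE)
    }
  }
  # total matched cost never exceeds the identity labeling's cost
  for (c in 2:3) {
    ref <- phi_mean(chains[[1]])
    oth <- phi_mean(chains[[c]])
    id_cost <- sum(1 - rowSums(sqrt(ref) * sqrt(oth)))
    expect_lte(ens$costs[c], id_cost + 1e-12)
  }
})

test_that("perfectly replicated topics get silhouette 1", {
  set.seed(7)
  phi <- random_phi(3, 10)
  ch <- fake_chain(list(phi), list(matrix(1 / 3, 2, 3)))
  ens <- silhouette_filter(align_ensemble(list(ch, ch, ch)))
  expect_equal(ens$silhouette$silhouette, rep(1, 3), tolerance = 1e-9)
  expect_equal(ens$robust_topics, 1:3)
})

test_that("a chain-specific noise topic is excluded, replicated ones kept", {
  set.seed(8)
  K <- 4; V <- 20
  base <- random_phi(K, V)
  chains <- lapply(1:4, function(c) {
    phi <- base
    # topic 4 is freshly random in every chain: non-identifiable
    phi[4, ] <- {
      x <- rgamma(V, 0.1); x / sum(x)
    }
    # small replicate noise on the others
    phi[1:3, ] <- phi[1:3, ] + matrix(runif(3 * V, 0, 1e-3), 3, V)
    phi[1:3, ] <- phi[1:3, ] / rowSums(phi[1:3, ])
    colnames(phi) <- colnames(base)
    fake_chain(list(phi), list(matrix(1 / K, 2, K)))
  })
  ens <- silhouette_filter(align_ensemble(chains), threshold = 0.1)
  sil <- ens$silhouette$silhouette
  expect_lt(sil[4], 0.1)
  expect_true(all(sil[1:3] > 0.5))
  expect_equal(ens$robust_topics, 1:3)

  # a vacuous threshold retains everything
  ens_all <- silhouette_filter(align_ensemble(chains), threshold = -1)
  expect_equal(ens_all$robust_topics, 1:4)
})

test_that("K = 1 silhouette is undefined but retained with a warning", {
  phi <- random_phi(1, 6)
  ch <- fake_chain(list(phi), list(matrix(1, 3, 1)))
  ens <- align_ensemble(list(ch, ch))
  expect_warning(ens <- silhouette_filter(ens), "K = 1")
  expect_equal(ens$robust_topics, 1L)
})

test_that("credible intervals cover the truth at near-nominal rate", {
  cfg <- gen_config(n_participants = 800, n_features = 10, K_true = 3,
                    topic_sharpness = 0.2, seed = 9)
  coh <- generate_cohort(cfg)
  chains <- fit_chains(coh$binned, K = 3, n_chains = 3, base_seed = 9,
                       n_burn = 250, n_samples = 50, thin = 2)
  ens <- align_ensemble(chains)
  pm <- pooled_phi(ens)
  truth <- coh$truth$phi[, colnames(pm)]
  perm <- match_topics(truth, pm)$perm
  pooled <- ens$pooled
  hit <- 0; tot <- 0
  for (k in 1:3) {
    rows <- pooled[pooled$topic == perm[k], ]
    tr <- truth[k, match(rows$entry, colnames(truth))]
    hit <- hit + sum(rows$lower - 1e-9 <= tr & tr <= rows$upper + 1e-9)
    tot <- tot + length(tr)
  }
  expect_gte(hit / tot, 0.90)
})
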