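# Shared fixture builders: everything is generated in code at test time.

# tiny deterministic binned cohort with an explicit level matrix
toy_binned <- function(levels, n_levels = NULL, sex = NULL) {
  if (is.null(colnames(levels))) {
    colnames(levels) <- sprintf("f%02d", seq_len(ncol(levels)))
  }
  new_binned_cohort(
    levels,
    ids = sprintf("P%03d", seq_len(nrow(levels))),
    sex = sex %||% rep("female", nrow(levels)),
    n_levels = n_levels %||% rep(max(levels, na.rm = TRUE) + 1L, ncol(levels))
  )
}

# fabricate a ckm_chain from explicit phi/theta sample lists (for alignment
# and diagnostic tests that need controlled posteriors)
fake_chain <- function(phi_samples, theta_samples, K = nrow(phi_samples[[1]])) {
  vnames <- colnames(phi_samples[[1]])
  if (is.null(vnames)) {
    vnames <- paste0("f01:", seq_len(ncol(phi_samples[[1]])) - 1L)
    phi_samples <- lapply(phi_samples, function(p) {
      colnames(p) <- vnames
      p
    })
  }
  vocab <- tibble::tibble(
    token = seq_along(vnames) - 1L,
    feature = sub(":[0-9]+$", "", vnames),
    level = as.integer(sub("^.*:", "", vnames)))
  structure(list(phi = phi_samples, theta = theta_samples,
                 loglik = numeric(0), vocab = vocab,
                 ids = sprintf("P%03d", seq_len(nrow(theta_samples[[1]]))),
                 K = K, alpha = 1 / K, beta_h = 0.1,
                 n_burn = 0, n_samples = length(phi_samples), thin = 1,
                 seed = 0L),
            class = "ckm_chain")
}

# random sharp topic matrix (rows on the simplex)
random_phi <- function(K, V, sharp = 0.1) {
  m <- matrix(rgamma(K * V, shape = sharp), K, V)
  m <- m / rowSums(m)
  colnames(m) <- paste0("f01:", seq_len(V) - 1L)
  m
}

# brute-force minimum-cost assignment over all K! permutations
brute_force_match <- function(cost) {
  K <- nrow(cost)
  perms <- gtools_permutations(K)
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(K), p)]))
  list(perm = perms[which.min(costs), ], cost = min(costs))
}

# all permutations of 1..n (small n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1))
  }))
}
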