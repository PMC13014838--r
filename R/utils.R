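# Internal numerical helpers.

# Dirichlet draws via normalized gamma variates. `alpha` is either a vector
# (shared across rows) or an n x K matrix of per-row concentrations.
rdirichlet_mat <- function(n, alpha) {
  if (is.matrix(alpha)) {
    k <- ncol(alpha)
    g <- matrix(rgamma(n * k, shape = alpha), nrow = n, ncol = k)
  } else {
    k <- length(alpha)
    g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  }
  # guard: all-zero rows can occur for tiny concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k
  g / rowSums(g)
}

# Sample one categorical index per row of a probability matrix.
sample_rows <- function(prob) {
  cum <- prob %*% upper.tri(diag(ncol(prob)), diag = TRUE)
  u <- runif(nrow(prob)) * cum[, ncol(prob)]
  as.integer(rowSums(u > cum)) + 1L
}

# Total-variation distance between two probability vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Squared Hellinger distance between probability vectors, bounded in [0, 1].
hellinger2 <- function(p, q) {
  1 - sum(sqrt(pmax(p, 0) * pmax(q, 0)))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "ckm_invalid_config")
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name), class = "ckm_invalid_config")
  }
  x
}
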