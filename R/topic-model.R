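#' Tokenize a binned cohort
#'
#' Encodes each observed (participant, feature, level) entry as one token
#' over the (feature, level) vocabulary. Missing features contribute no
#' token at all, which is exactly how the model conditions on observed data
#' during posterior inference: no imputation happens anywhere.
#'
#' @param binned A [binned_cohort].
#' @return A list of class `ckm_tokens`: `doc` (0-based participant index
#'   per token), `word` (0-based vocabulary index per token), `vocab`
#'   (tibble: `token`, `feature`, `level`), `n_docs`, `ids`, and
#'   `n_empty` (participants with zero observed features, retained).
#' @export
tokenize <- function(binned) {
  stopifnot(inherits(binned, "binned_cohort"))
  long <- as_tibble(binned)
  key <- paste0(long$feature, ":", long$level)
  # vocabulary in stable (feature, level) order, observed entries only
  vocab_keys <- unlist(lapply(seq_along(binned$features), function(f) {
    paste0(binned$features[f], ":", 0:(binned$n_levels[f] - 1L))
  }))
  vocab_keys <- vocab_keys[vocab_keys %in% key]
  word <- match(key, vocab_keys) - 1L
  doc <- match(long$id, binned$ids) - 1L
  ord <- order(doc, word)
  n_tok <- tabulate(doc + 1L, nbins = length(binned$ids))
  n_empty <- sum(n_tok == 0L)
  if (n_empty > 0) {
    warn(sprintf("%d participant(s) with zero observed features retained",
                 n_empty))
  }
  vocab <- tibble::tibble(
    token = seq_along(vocab_keys) - 1L,
    feature = sub(":[0-9]+$", "", vocab_keys),
    level = as.integer(sub("^.*:", "", vocab_keys))
  )
  structure(list(doc = doc[ord], word = word[ord], vocab = vocab,
                 n_docs = length(binned$ids), ids = binned$ids,
                 n_empty = n_empty),
            class = "ckm_tokens")
}

#' Fit one Markov chain of the collapsed Gibbs sampler
#'
#' Runs the collapsed Gibbs sampler for the multinomial mixed-membership
#' model: token-topic assignments are resampled from
#' `P(z = k | rest) \propto (n_dk + alpha) (n_kv + beta_h) / (n_k + V beta_h)`
#' with the current token excluded from all counts. After `n_burn` sweeps,
#' every `thin`-th sweep is retained as a posterior sample with
#' `phi_kv = (n_kv + beta_h) / (n_k + V beta_h)` and
#' `theta_dk = (n_dk + alpha) / (n_d + K alpha)`. Participants with no
#' observed features get the prior-only loading `1/K`.
#'
#' @param binned A [binned_cohort] (or a [tokenize()] result).
#' @param K Number of topics.
#' @param alpha Symmetric Dirichlet hyperparameter over topics
#'   (default `1/K`).
#' @param beta_h Symmetric Dirichlet hyperparameter over the vocabulary.
#' @param n_burn,n_samples,thin MCMC schedule: burn-in sweeps, retained
#'   samples, sweeps between retained samples.
#' @param seed Integer seed; fixed seed reproduces the chain exactly.
#' @return An object of class `ckm_chain`: `phi` and `theta` sample lists
#'   (conditional posterior means given the sweep's assignments, the
#'   Rao-Blackwellized point estimates), `phi_draw` (exact posterior draws
#'   `phi | z ~ Dirichlet(n_kv + beta_h)`, used for credible intervals),
#'   `loglik` (collapsed log-likelihood per sweep), `vocab`, `ids`, and the
#'   fit parameters.
#' @export
fit_chain <- function(binned, K, alpha = 1 / K, beta_h = 0.1,
                      n_burn = 500, n_samples = 100, thin = 5,
                      seed = 1L) {
  K <- assert_count(K, "K")
  if (n_burn < 0 || n_samples < 1 || thin < 1) {
    abort("MCMC lengths must be positive", class = "ckm_invalid_config")
  }
  tok <- if (inherits(binned, "ckm_tokens")) binned else tokenize(binned)
  V <- nrow(tok$vocab)
  set.seed(seed)
  fit <- cpp_gibbs_fit(tok$doc, tok$word, tok$n_docs, V, K,
                       alpha, beta_h, as.integer(n_burn),
                       as.integer(n_samples), as.integer(thin))
  vnames <- paste0(tok$vocab$feature, ":", tok$vocab$level)
  for (s in seq_along(fit$phi)) {
    dimnames(fit$phi[[s]]) <- list(paste0("topic", seq_len(K)), vnames)
    dimnames(fit$phi_draw[[s]]) <- dimnames(fit$phi[[s]])
    dimnames(fit$theta[[s]]) <- list(tok$ids, paste0("topic", seq_len(K)))
  }
  structure(list(phi = fit$phi, theta = fit$theta,
                 phi_draw = fit$phi_draw, loglik = fit$loglik,
                 vocab = tok$vocab, ids = tok$ids,
                 K = K, alpha = alpha, beta_h = beta_h,
                 n_burn = n_burn, n_samples = n_samples, thin = thin,
                 seed = seed),
            class = "ckm_chain")
}

#' Fit several independent chains
#'
#' @inheritParams fit_chain
#' @param n_chains Number of independent chains; chain `c` uses seed
#'   `base_seed + c - 1`.
#' @param base_seed Base seed.
#' @return A list of [fit_chain()] results.
#' @export
fit_chains <- function(binned, K, n_chains = 8, base_seed = 1L, ...) {
  tok <- if (inherits(binned, "ckm_tokens")) binned else tokenize(binned)
  lapply(seq_len(n_chains), function(ch) {
    fit_chain(tok, K, seed = base_seed + ch - 1L, ...)
  })
}

#' Posterior-mean participant loadings of a chain
#'
#' @param chain A `ckm_chain`.
#' @return n x K matrix of posterior-mean loadings (the 0--100% profile
#'   scores, on the 0--1 scale).
#' @export
theta_mean <- function(chain) {
  stopifnot(inherits(chain, "ckm_chain"))
  Reduce(`+`, chain$theta) / length(chain$theta)
}

#' Posterior-mean topic-level distributions of a chain
#' @param chain A `ckm_chain`.
#' @return K x V matrix.
#' @export
phi_mean <- function(chain) {
  stopifnot(inherits(chain, "ckm_chain"))
  Reduce(`+`, chain$phi) / length(chain$phi)
}

# deterministic document-completion theta: EM fixed point with phi frozen
fold_in_theta <- function(doc, word, n_docs, phi, alpha, n_iter = 50) {
  K <- nrow(phi)
  theta <- matrix(1 / K, n_docs, K)
  nd <- tabulate(doc + 1L, nbins = n_docs)
  phiw <- t(phi)[word + 1L, , drop = FALSE]  # tokens x K
  for (it in seq_len(n_iter)) {
    r <- theta[doc + 1L, , drop = FALSE] * phiw
    r <- r / pmax(rowSums(r), .Machine$double.xmin)
    acc <- rowsum(r, group = doc, reorder = TRUE)
    theta_new <- matrix(alpha, n_docs, K)
    theta_new[sort(unique(doc)) + 1L, ] <-
      theta_new[sort(unique(doc)) + 1L, ] + acc
    theta <- theta_new / (nd + K * alpha)
    theta[nd == 0L, ] <- 1 / K
  }
  theta
}

#' Held-out predictive score by document completion
#'
#' Fits the model on the training participants, then for each validation
#' participant folds in the even-indexed half of their tokens to estimate a
#' loading vector (EM fixed point with the training `phi` frozen) and
#' evaluates the mean per-token predictive log-likelihood
#' `log sum_k theta_k phi_kv` on the held-back odd-indexed half.
#' Validation participants with fewer than 2 tokens are excluded and
#' counted.
#'
#' @param binned_train,binned_valid Disjoint [binned_cohort]s.
#' @param K Number of topics.
#' @param ... Passed to [fit_chain()].
#' @param seed Seed for the training chain.
#' @return List: `score` (mean per-token predictive log-likelihood, always
#'   <= 0), `n_scored` tokens, `n_excluded` participants, `K`.
#' @export
heldout_score <- function(binned_train, binned_valid, K, ..., seed = 1L) {
  fit <- fit_chain(binned_train, K, seed = seed, ...)
  phi <- phi_mean(fit)
  tokv <- tokenize(binned_valid)
  # map validation tokens onto the training vocabulary; unseen entries drop
  key_v <- paste0(tokv$vocab$feature, ":", tokv$vocab$level)
  map <- match(key_v, colnames(phi)) - 1L
  word <- map[tokv$word + 1L]
  keep <- !is.na(word)
  doc <- tokv$doc[keep]
  word <- word[keep]
  # within-participant token index for the even/odd split
  ord <- order(doc)
  doc <- doc[ord]; word <- word[ord]
  idx <- sequence(rle(doc)$lengths) - 1L
  nd <- tabulate(doc + 1L, nbins = tokv$n_docs)
  eligible <- nd >= 2L
  n_excluded <- sum(!eligible)
  use <- eligible[doc + 1L]
  doc <- doc[use]; word <- word[use]; idx <- idx[use]
  fold <- idx %% 2L == 0L  # even-indexed tokens estimate theta
  theta <- fold_in_theta(doc[fold], word[fold], tokv$n_docs, phi,
                         alpha = fit$alpha)
  heldback <- !fold
  pt <- rowSums(theta[doc[heldback] + 1L, , drop = FALSE] *
                  t(phi)[word[heldback] + 1L, , drop = FALSE])
  list(score = mean(log(pmax(pt, .Machine$double.xmin))),
       n_scored = sum(heldback), n_excluded = n_excluded, K = K)
}

#' Select the number of topics by a training-validation split
#'
#' Splits participants at ratio `train_frac` into training and validation
#' sets, computes the [heldout_score()] for every K on the grid, and
#' returns the K with the best generalization performance (ties broken
#' toward smaller K). The 1:2 train:validation split is the default.
#'
#' @param binned A [binned_cohort].
#' @param K_grid Integer vector of candidate K.
#' @param split_seed Seed controlling the split and the per-K fits.
#' @param train_frac Fraction of participants used for training
#'   (default 1/3, a 1:2 train:validation ratio).
#' @param ... Passed to [heldout_score()] / [fit_chain()].
#' @return List of class `ckm_selection`: `K` (selected), `curve` (tibble
#'   `K`, `score`), `train_frac`, `split_seed`.
#' @export
select_K <- function(binned, K_grid, split_seed = 1L, train_frac = 1 / 3,
                     ...) {
  if (length(K_grid) == 0) {
    abort("K_grid is empty", class = "ckm_invalid_config")
  }
  n <- length(binned$ids)
  set.seed(split_seed)
  tr <- sample.int(n, size = round(train_frac * n))
  b_train <- subset_binned(binned, tr)
  b_valid <- subset_binned(binned, setdiff(seq_len(n), tr))
  scores <- vapply(K_grid, function(K) {
    heldout_score(b_train, b_valid, K, seed = split_seed + K, ...)$score
  }, numeric(1))
  curve <- tibble::tibble(K = as.integer(K_grid), score = scores)
  best <- curve$K[order(-curve$score, curve$K)][1]
  structure(list(K = best, curve = curve, train_frac = train_frac,
                 split_seed = split_seed),
            class = "ckm_selection")
}

#' Convergence diagnostic on loading entropy across chains
#'
#' Computes, per participant and posterior sample, the entropy of the
#' loading vector `H = -sum_k theta_k log theta_k`, then compares within-
#' and between-chain variance of H with a potential-scale-reduction (R-hat)
#' statistic per participant. The ensemble passes when R-hat < `limit` for
#' at least `pass_frac` of participants.
#'
#' @param chains List of >= 2 `ckm_chain` fits on the same participants.
#' @param limit R-hat pass threshold (default 1.1).
#' @param pass_frac Required fraction of participants below `limit`.
#' @return A list of class `ckm_diagnostic`: `rhat` (per participant),
#'   `pass` (logical), `frac_ok`, `limit`.
#' @export
entropy_diagnostic <- function(chains, limit = 1.1, pass_frac = 0.99) {
  if (!is.list(chains) || length(chains) < 2) {
    abort("entropy diagnostic needs at least 2 chains",
          class = "ckm_diagnostic_error")
  }
  ent <- function(theta) -rowSums(theta * log(pmax(theta, .Machine$double.xmin)))
  # participants x samples matrix per chain
  H <- lapply(chains, function(ch) vapply(ch$theta, ent,
                                          numeric(nrow(ch$theta[[1]]))))
  S <- ncol(H[[1]])
  M <- length(H)
  means <- vapply(H, rowMeans, numeric(nrow(H[[1]])))          # n x M
  vars <- vapply(H, function(h) apply(h, 1, var), numeric(nrow(H[[1]])))
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)                             # B / S
  rhat <- sqrt(((S - 1) / S * W + B_over_n) / pmax(W, .Machine$double.xmin))
  rhat[W == 0 & B_over_n == 0] <- 1
  frac_ok <- mean(rhat < limit)
  structure(list(rhat = rhat, pass = frac_ok >= pass_frac,
                 frac_ok = frac_ok, limit = limit, n_chains = M,
                 n_samples = S),
            class = "ckm_diagnostic")
}

#' @export
print.ckm_chain <- function(x, ...) {
  cat(sprintf(
    "<ckm_chain> K = %d, %d samples (burn %d, thin %d), final loglik %.1f\n",
    x$K, length(x$phi), x$n_burn, x$thin, utils::tail(x$loglik, 1)))
  invisible(x)
}

#' @export
print.ckm_selection <- function(x, ...) {
  cat(sprintf("<ckm_selection> selected K = %d over grid {%s}\n",
              x$K, paste(x$curve$K, collapse = ", ")))
  invisible(x)
}

#' @export
print.ckm_diagnostic <- function(x, ...) {
  cat(sprintf("<ckm_diagnostic> %s: %.1f%% of participants with R-hat < %.2f\n",
              if (x$pass) "PASS" else "FAIL", 100 * x$frac_ok, x$limit))
  invisible(x)
}
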