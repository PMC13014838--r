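#' Match topic labels between two chains by optimal transport
#'
#' Topic labels are arbitrary within each Markov chain (label switching), so
#' chains are aligned by solving the balanced optimal-transport problem with
#' uniform marginals between their topic sets, which reduces to a linear
#' assignment: the cost of pairing reference topic `a` with other topic `b`
#' is the squared Hellinger distance between their topic-level probability
#' rows, and the minimizing bijection is found by the Jonker-Volgenant
#' shortest augmenting path algorithm. Ties break deterministically by scan
#' order (lowest index).
#'
#' @param reference_phi,other_phi K x V probability matrices.
#' @return List: `perm` (integer vector; `perm[a]` is the topic of
#'   `other_phi` matched to reference topic `a`), `cost` (total transport
#'   cost), `cost_matrix`.
#' @export
#' @examples
#' phi <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' match_topics(phi, phi[2:1, ])$perm
match_topics <- function(reference_phi, other_phi) {
  if (!all(dim(reference_phi) == dim(other_phi))) {
    abort("phi matrices must have identical dimensions",
          class = "ckm_alignment_error")
  }
  K <- nrow(reference_phi)
  sr <- sqrt(pmax(reference_phi, 0))
  so <- sqrt(pmax(other_phi, 0))
  cost <- 1 - tcrossprod(sr, so)  # squared Hellinger distance
  perm <- cpp_lap(cost)
  list(perm = perm, cost = sum(cost[cbind(seq_len(K), perm)]),
       cost_matrix = cost)
}

#' Align an ensemble of chains and pool posterior samples
#'
#' The first chain is the reference. Every other chain's posterior-mean
#' topic-level matrix is matched to the reference's with [match_topics()],
#' and all of that chain's samples (phi rows, theta columns) are relabeled
#' by the matched permutation. Relabeled samples from all chains are then
#' pooled: posterior means come from the Rao-Blackwellized per-sweep
#' estimates, while 95% equal-tailed credible intervals are taken over the
#' exact conditional Dirichlet draws of phi, which carry the full posterior
#' width.
#'
#' @param chains List of >= 2 `ckm_chain` fits with equal K on the same
#'   cohort.
#' @param ci Credible-interval mass (default 0.95).
#' @return An object of class `ckm_ensemble`: `chains` (relabeled),
#'   `permutations`, `costs`, `pooled` (tibble: `topic`, `entry`,
#'   `feature`, `level`, `mean`, `lower`, `upper`), `theta_mean` (pooled
#'   n x K posterior-mean loadings), `K`, plus `silhouette` and
#'   `robust_topics` slots filled by [silhouette_filter()].
#' @export
align_ensemble <- function(chains, ci = 0.95) {
  if (length(chains) < 2) {
    abort("need at least 2 chains", class = "ckm_alignment_error")
  }
  Ks <- vapply(chains, `[[`, integer(1), "K")
  if (length(unique(Ks)) != 1) {
    abort("chains disagree on K", class = "ckm_alignment_error")
  }
  K <- Ks[1]
  ref <- phi_mean(chains[[1]])
  perms <- vector("list", length(chains))
  costs <- numeric(length(chains))
  perms[[1]] <- seq_len(K)
  aligned <- chains
  for (c in seq_along(chains)[-1]) {
    m <- match_topics(ref, phi_mean(chains[[c]]))
    perms[[c]] <- m$perm
    costs[c] <- m$cost
    relab <- function(p) {
      out <- p[m$perm, , drop = FALSE]
      rownames(out) <- rownames(p)
      out
    }
    aligned[[c]]$phi <- lapply(chains[[c]]$phi, relab)
    if (!is.null(chains[[c]]$phi_draw)) {
      aligned[[c]]$phi_draw <- lapply(chains[[c]]$phi_draw, relab)
    }
    aligned[[c]]$theta <- lapply(chains[[c]]$theta, function(t_) {
      out <- t_[, m$perm, drop = FALSE]
      colnames(out) <- colnames(t_)
      out
    })
  }
  all_phi <- unlist(lapply(aligned, `[[`, "phi"), recursive = FALSE)
  draws <- unlist(lapply(aligned, function(ch)
    ch$phi_draw %||% ch$phi), recursive = FALSE)
  arr <- simplify2array(all_phi)            # K x V x S_total
  arr_d <- simplify2array(draws)
  a <- (1 - ci) / 2
  pooled <- tibble::tibble(
    topic = rep(seq_len(K), times = dim(arr)[2]),
    entry = rep(colnames(all_phi[[1]]), each = K),
    mean = as.vector(apply(arr, c(1, 2), mean)),
    lower = as.vector(apply(arr_d, c(1, 2), quantile, probs = a)),
    upper = as.vector(apply(arr_d, c(1, 2), quantile, probs = 1 - a))
  )
  pooled$feature <- sub(":[0-9]+$", "", pooled$entry)
  pooled$level <- as.integer(sub("^.*:", "", pooled$entry))
  all_theta <- unlist(lapply(aligned, `[[`, "theta"), recursive = FALSE)
  th_mean <- Reduce(`+`, all_theta) / length(all_theta)
  structure(list(chains = aligned, permutations = perms, costs = costs,
                 pooled = pooled, theta_mean = th_mean, K = K,
                 silhouette = NULL, robust_topics = seq_len(K)),
            class = "ckm_ensemble")
}

#' Filter non-identifiable topics by silhouette score
#'
#' After alignment, each chain contributes one posterior-mean phi row per
#' topic; the rows form K clusters of `n_chains` points each. A topic that
#' replicates across chains has a tight, well-separated cluster (silhouette
#' near 1); a topic that each chain filled with something different has a
#' poor one. Topics are retained when their mean silhouette (Euclidean
#' distance) reaches `threshold`. Zero-width clusters (identical points)
#' score 1.
#'
#' @param ensemble A [align_ensemble()] result.
#' @param threshold Minimum mean silhouette to keep a topic (default 0.1).
#' @return The ensemble, with `silhouette` (tibble: `topic`, `silhouette`,
#'   `robust`) and `robust_topics` filled in.
#' @export
silhouette_filter <- function(ensemble, threshold = 0.1) {
  stopifnot(inherits(ensemble, "ckm_ensemble"))
  K <- ensemble$K
  if (K == 1) {
    warn("silhouette undefined for K = 1; retaining the single topic")
    ensemble$silhouette <- tibble::tibble(topic = 1L, silhouette = NA_real_,
                                          robust = TRUE)
    ensemble$robust_topics <- 1L
    return(ensemble)
  }
  pts <- do.call(rbind, lapply(ensemble$chains, phi_mean))
  labels <- rep(seq_len(K), times = length(ensemble$chains))
  d <- stats::dist(pts)
  sil <- cluster::silhouette(labels, d)
  widths <- sil[, "sil_width"]
  # degenerate zero-width clusters: a(i) = 0 handled by the (b-a)/max rule,
  # but all-identical points across clusters give 0/0 -> define as 1
  zero <- !is.finite(widths)
  widths[zero] <- 1
  per_topic <- tibble::tibble(topic = labels, width = widths) |>
    dplyr::group_by(.data$topic) |>
    dplyr::summarise(silhouette = mean(.data$width), .groups = "drop") |>
    dplyr::mutate(robust = .data$silhouette >= threshold)
  ensemble$silhouette <- per_topic
  ensemble$robust_topics <- per_topic$topic[per_topic$robust]
  ensemble
}

#' Pooled posterior-mean phi matrix of an ensemble
#'
#' @param ensemble A [align_ensemble()] result.
#' @return K x V matrix of pooled posterior means, columns named by
#'   vocabulary entry.
#' @export
pooled_phi <- function(ensemble) {
  stopifnot(inherits(ensemble, "ckm_ensemble"))
  entries <- unique(ensemble$pooled$entry)
  m <- matrix(ensemble$pooled$mean, nrow = ensemble$K,
              dimnames = list(paste0("topic", seq_len(ensemble$K)), entries))
  m
}

#' @export
print.ckm_ensemble <- function(x, ...) {
  cat(sprintf("<ckm_ensemble> %d chains, K = %d, %d robust topic(s)\n",
              length(x$chains), x$K, length(x$robust_topics)))
  invisible(x)
}
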