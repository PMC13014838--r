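# broom-style tidiers for fitted objects

#' Tidy a fitted chain
#'
#' @param x A `ckm_chain`.
#' @param matrix `"phi"` for topic-level probabilities (posterior mean per
#'   (topic, entry)) or `"theta"` for participant loadings.
#' @param ... Unused.
#' @return A tibble: for `"phi"`, columns `topic`, `entry`, `feature`,
#'   `level`, `estimate`; for `"theta"`, columns `id`, `topic`, `estimate`.
#' @export
tidy.ckm_chain <- function(x, matrix = c("phi", "theta"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "phi") {
    m <- phi_mean(x)
    tibble::tibble(
      topic = rep(seq_len(nrow(m)), ncol(m)),
      entry = rep(colnames(m), each = nrow(m)),
      feature = rep(x$vocab$feature, each = nrow(m)),
      level = rep(x$vocab$level, each = nrow(m)),
      estimate = as.vector(m))
  } else {
    m <- theta_mean(x)
    tibble::tibble(
      id = rep(rownames(m), ncol(m)),
      topic = rep(seq_len(ncol(m)), each = nrow(m)),
      estimate = as.vector(m))
  }
}

#' @rdname tidy.ckm_chain
#' @export
glance.ckm_chain <- function(x, ...) {
  tibble::tibble(K = x$K, alpha = x$alpha, beta_h = x$beta_h,
                 n_samples = length(x$phi), n_burn = x$n_burn,
                 thin = x$thin, seed = x$seed,
                 loglik = unname(x$loglik[length(x$loglik)]))
}

#' Tidy an aligned ensemble
#'
#' @param x A `ckm_ensemble`.
#' @param ... Unused.
#' @return The pooled profile tibble: `topic`, `entry`, `feature`, `level`,
#'   `mean`, `lower`, `upper`.
#' @export
tidy.ckm_ensemble <- function(x, ...) x$pooled

#' @rdname tidy.ckm_ensemble
#' @export
glance.ckm_ensemble <- function(x, ...) {
  tibble::tibble(K = x$K, n_chains = length(x$chains),
                 n_robust = length(x$robust_topics),
                 total_cost = sum(x$costs))
}

#' Tidy a GWAS table
#'
#' @param x A `ckm_gwas`.
#' @param ... Unused.
#' @return The per-variant tibble (meta-analysis columns included).
#' @export
tidy.ckm_gwas <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ckm_gwas")
  out
}

#' @rdname tidy.ckm_gwas
#' @export
glance.ckm_gwas <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_leads = if ("lead" %in% names(x)) sum(x$lead) else NA_integer_,
    lambda_gc = attr(x, "lambda"),
    sig_threshold = attr(x, "sig_threshold"))
}

#' Tidy a prevalence result
#' @param x A `ckm_prevalence`.
#' @param ... Unused.
#' @return The sensitivity-sweep tibble.
#' @export
tidy.ckm_prevalence <- function(x, ...) x$sensitivity

#' @rdname tidy.ckm_prevalence
#' @export
glance.ckm_prevalence <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, cases = x$overall$cases,
                 prevalence = x$overall$prevalence)
}
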