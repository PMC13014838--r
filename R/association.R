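#' Rank-transform topic loadings
#'
#' Fractional ranks with average ranks for ties, mapped to (0, 1) by
#' `(r - 0.5) / n`; with `method = "rint"` the ranks are additionally pushed
#' through the standard-normal quantile function (rank-based inverse normal
#' transform). Either way the result is invariant under any strictly
#' monotone re-scoring of the input.
#'
#' @param scores Numeric vector of loadings.
#' @param method `"fractional"` (default) or `"rint"`.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' rank_transform(c(0.1, 0.5, 0.9))
rank_transform <- function(scores, method = c("fractional", "rint")) {
  method <- match.arg(method)
  if (length(scores) == 0 || any(!is.finite(scores))) {
    abort("scores must be nonempty and finite", class = "ckm_invalid_config")
  }
  if (length(unique(scores)) == 1) {
    warn("all scores equal; rank transform returns 0.5 everywhere")
  }
  u <- (rank(scores, ties.method = "average") - 0.5) / length(scores)
  if (method == "rint") qnorm(u) else u
}

#' Associate topic loadings with covariates and disease indicators
#'
#' For each topic, fits an ordinary least squares regression of the
#' rank-transformed posterior-mean loading on all predictors jointly
#' (multivariate linear regression), with per-coefficient two-sided
#' t-tests. Rows with any missing predictor are dropped (complete-case).
#' Bonferroni correction uses a family of (topics x predictors) tests by
#' default.
#'
#' @param theta_mean n x K matrix of posterior-mean loadings (or a data
#'   frame of loading columns).
#' @param design Data frame of predictors for the same participants;
#'   factors/characters are dummy-coded via [stats::model.matrix()].
#' @param method Rank transform passed to [rank_transform()].
#' @param family_size Number of tests for Bonferroni; default
#'   topics x predictors.
#' @param alpha_family Family-wise error level (default 0.05).
#' @return A tibble of class `ckm_assoc` with columns `topic`, `predictor`,
#'   `beta`, `se`, `p`, `p_bonf`, `significant`, `direction`.
#' @export
associate <- function(theta_mean, design, method = "fractional",
                      family_size = NULL, alpha_family = 0.05) {
  theta_mean <- as.matrix(theta_mean)
  design <- as.data.frame(design)
  stopifnot(nrow(theta_mean) == nrow(design))
  cc <- complete.cases(design)
  design <- design[cc, , drop = FALSE]
  theta_mean <- theta_mean[cc, , drop = FALSE]
  X <- model.matrix(~ ., data = design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "ckm_collinearity_error")
  }
  K <- ncol(theta_mean)
  topics <- colnames(theta_mean) %||% paste0("topic", seq_len(K))
  preds <- colnames(X)[-1]
  XtXinv <- chol2inv(chol(crossprod(X)))
  res <- purrr::map_dfr(seq_len(K), function(k) {
    y <- rank_transform(theta_mean[, k], method = method)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- nrow(X) - fit$rank
    se <- sqrt(diag(XtXinv) * rss / df)
    tval <- fit$coefficients / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    tibble::tibble(topic = topics[k], predictor = colnames(X),
                   beta = unname(fit$coefficients), se = unname(se),
                   p = unname(p))
  }) |>
    dplyr::filter(.data$predictor != "(Intercept)")
  m <- family_size %||% nrow(res)
  res <- res |>
    dplyr::mutate(p_bonf = pmin(1, .data$p * m),
                  significant = .data$p <= alpha_family / m,
                  direction = sign(.data$beta))
  class(res) <- c("ckm_assoc", class(res))
  attr(res, "family_size") <- m
  attr(res, "alpha_family") <- alpha_family
  res
}

#' Classify topics into candidate CKM subtypes
#'
#' A topic is a candidate cardiovascular-kidney-metabolic subtype when it is
#' simultaneously, significantly (after multiple-testing correction) and
#' positively associated with all three of self-reported kidney disease,
#' type 2 diabetes, and cardiovascular disease; a protective profile when
#' all three associations are significant and negative; otherwise neither.
#'
#' @param assoc A [associate()] result.
#' @param diseases Names of the three disease predictors.
#' @return Tibble: `topic`, `call` in
#'   `{"candidate_CKM", "protective", "neither"}`.
#' @export
classify_subtypes <- function(assoc,
                              diseases = c("kidney_disease", "t2dm", "cvd")) {
  stopifnot(inherits(assoc, "ckm_assoc"))
  present <- vapply(diseases, function(d)
    any(startsWith(assoc$predictor, d)), logical(1))
  if (!all(present)) {
    abort(paste0("association table lacks disease predictor(s): ",
                 paste(diseases[!present], collapse = ", ")),
          class = "ckm_classification_error")
  }
  keep <- purrr::map_lgl(assoc$predictor,
                         function(p) any(startsWith(p, diseases)))
  assoc[keep, ] |>
    dplyr::group_by(.data$topic) |>
    dplyr::summarise(
      call = dplyr::case_when(
        all(.data$significant) && all(.data$beta > 0) ~ "candidate_CKM",
        all(.data$significant) && all(.data$beta < 0) ~ "protective",
        TRUE ~ "neither"),
      .groups = "drop")
}

#' Subtype prevalence under a loading threshold
#'
#' A participant is a per-topic case when their loading on that topic
#' reaches `threshold`, and an overall CKM case when their summed loading
#' over the candidate subtype topics reaches it. A sensitivity sweep over
#' `sensitivity` thresholds is always included; prevalence is monotone
#' nonincreasing in the threshold.
#'
#' @param theta_mean n x K loading matrix (rows on the simplex).
#' @param topics Candidate subtype topic indices or names.
#' @param threshold Loading threshold in (0, 1] (default 0.5).
#' @param sensitivity Thresholds for the sensitivity sweep.
#' @return List of class `ckm_prevalence`: `per_topic` (tibble `topic`,
#'   `cases`, `prevalence`), `overall` (tibble `cases`, `prevalence`),
#'   `sensitivity` (tibble `threshold`, `cases`, `prevalence`).
#' @export
prevalence <- function(theta_mean, topics, threshold = 0.5,
                       sensitivity = c(0.5, 0.4, 0.3)) {
  theta_mean <- as.matrix(theta_mean)
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "ckm_invalid_config")
  }
  if (is.character(topics)) topics <- match(topics, colnames(theta_mean))
  n <- nrow(theta_mean)
  sub <- theta_mean[, topics, drop = FALSE]
  per_topic <- tibble::tibble(
    topic = colnames(sub) %||% paste0("topic", topics),
    cases = unname(colSums(sub >= threshold)),
    prevalence = unname(colSums(sub >= threshold)) / n
  )
  total <- rowSums(sub)
  overall <- tibble::tibble(cases = sum(total >= threshold),
                            prevalence = mean(total >= threshold))
  sens <- tibble::tibble(
    threshold = sensitivity,
    cases = vapply(sensitivity, function(t) sum(total >= t), numeric(1)),
    prevalence = vapply(sensitivity, function(t) mean(total >= t), numeric(1))
  )
  structure(list(per_topic = per_topic, overall = overall,
                 sensitivity = sens, threshold = threshold),
            class = "ckm_prevalence")
}

#' @export
print.ckm_prevalence <- function(x, ...) {
  cat(sprintf("<ckm_prevalence> overall: %d cases (%.1f%%) at threshold %.2f\n",
              x$overall$cases, 100 * x$overall$prevalence, x$threshold))
  invisible(x)
}
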