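#' Fit sex-stratified percentile bin thresholds
#'
#' Computes, per biomarker and per sex, the empirical 10th, 30th, 70th and
#' 90th percentiles of the observed values (linear interpolation between
#' order statistics, the type-7 default). These four thresholds define five
#' bins that keep resolution at both tails of each biomarker distribution.
#'
#' @param data Data frame with one row per participant.
#' @param features Character vector of biomarker column names to fit.
#' @param sex Name of the sex column in `data` (default `"sex"`).
#' @param probs Percentile probabilities for the thresholds.
#' @return A tibble of class `ckm_bin_spec` with columns `feature`, `sex`,
#'   and `q10`, `q30`, `q70`, `q90` (named after the default probs).
#' @export
#' @examples
#' d <- data.frame(sex = rep(c("f", "m"), each = 50),
#'                 glucose = c(rnorm(50, 5), rnorm(50, 6)))
#' fit_bins(d, "glucose")
fit_bins <- function(data, features, sex = "sex",
                     probs = c(0.1, 0.3, 0.7, 0.9)) {
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            sex %in% names(data))
  sx <- as.character(data[[sex]])
  out <- tidyr::expand_grid(feature = features, sex = unique(sx))
  qs <- purrr::pmap(out, function(feature, sex) {
    v <- data[[feature]][sx == sex]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(sprintf("feature '%s' has no observed values for sex '%s'",
                    feature, sex), class = "ckm_fit_error")
    }
    if (length(v) < 10) {
      warn(sprintf("feature '%s' has < 10 observed values for sex '%s'",
                   feature, sex))
    }
    quantile(v, probs = probs, names = FALSE, type = 7)
  })
  qmat <- do.call(rbind, qs)
  colnames(qmat) <- paste0("q", round(100 * probs))
  spec <- dplyr::bind_cols(out, tibble::as_tibble(qmat))
  class(spec) <- c("ckm_bin_spec", class(spec))
  spec
}

#' Apply fitted bin thresholds to a cohort
#'
#' Assigns each observed biomarker value the number of thresholds strictly
#' below it (0--4); a value exactly equal to a threshold falls in the lower
#' bin. Blood pressure, when `bp_cols` is given, is categorized with
#' [categorize_bp()] into a three-level feature named `bp`. Missing values
#' stay missing.
#'
#' @param data Data frame with one row per participant; must contain an
#'   `id` column, the sex column, and every feature in `spec`.
#' @param spec A [fit_bins()] result.
#' @param sex Name of the sex column.
#' @param bp_cols Optional length-2 character vector naming the systolic and
#'   diastolic pressure columns.
#' @return A [binned_cohort].
#' @export
apply_bins <- function(data, spec, sex = "sex", bp_cols = NULL) {
  stopifnot(inherits(spec, "ckm_bin_spec"), is.data.frame(data))
  features <- unique(spec$feature)
  missing_feats <- setdiff(features, names(data))
  if (length(missing_feats) > 0) {
    abort(paste0("features absent from data: ",
                 paste(missing_feats, collapse = ", ")),
          class = "ckm_apply_error")
  }
  sx <- as.character(data[[sex]])
  n <- nrow(data)
  qcols <- grep("^q", names(spec), value = TRUE)
  lev <- matrix(NA_integer_, n, length(features),
                dimnames = list(NULL, features))
  for (f in features) {
    v <- data[[f]]
    for (s in unique(sx)) {
      row <- spec[spec$feature == f & spec$sex == s, qcols]
      if (nrow(row) == 0) {
        abort(sprintf("no thresholds for feature '%s', sex '%s'", f, s),
              class = "ckm_apply_error")
      }
      thr <- as.numeric(row[1, ])
      sel <- sx == s & !is.na(v)
      # level = number of thresholds strictly below the value
      lev[sel, f] <- rowSums(outer(v[sel], thr, `>`))
    }
  }
  n_levels <- rep(length(qcols) + 1L, length(features))
  if (!is.null(bp_cols)) {
    stopifnot(length(bp_cols) == 2, all(bp_cols %in% names(data)))
    bp <- categorize_bp(data[[bp_cols[1]]], data[[bp_cols[2]]])
    lev <- cbind(lev, bp = bp)
    n_levels <- c(n_levels, 3L)
  }
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    sprintf("P%06d", seq_len(n))
  new_binned_cohort(lev, ids = ids, sex = sx, n_levels = n_levels)
}

#' Categorize blood pressure per clinical guideline cut-offs
#'
#' Uses the 2017 ACC/AHA categories collapsed to three levels:
#' normal (SBP < 120 and DBP < 80), elevated (120 <= SBP <= 129 and
#' DBP < 80), hypertensive (SBP >= 130 or DBP >= 80).
#'
#' @param sbp,dbp Systolic and diastolic pressures in mmHg.
#' @return Integer vector: 0 = normal, 1 = elevated, 2 = hypertensive;
#'   `NA` when either component is missing.
#' @export
#' @examples
#' categorize_bp(c(118, 124, 118, 135), c(76, 79, 85, 70))
categorize_bp <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  out <- rep(NA_integer_, length(sbp))
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(c(sbp[ok], dbp[ok]) <= 0)) {
    abort("blood pressures must be positive", class = "ckm_invalid_config")
  }
  out[which(ok & (sbp >= 130 | dbp >= 80))] <- 2L
  out[which(ok & is.na(out) & sbp >= 120)] <- 1L
  out[which(ok & is.na(out))] <- 0L
  out
}

#' Construct a binned cohort
#'
#' The participant-by-feature categorical container used by the topic model:
#' an integer level matrix (0-based levels, `NA` = unobserved) plus
#' participant ids, sex, and the number of levels per feature.
#'
#' @param levels Integer matrix (participants x features) with column names.
#' @param ids Participant identifiers.
#' @param sex Per-participant sex labels.
#' @param n_levels Integer vector: number of levels per feature.
#' @return An object of class `binned_cohort`.
#' @export
new_binned_cohort <- function(levels, ids, sex = NULL, n_levels) {
  stopifnot(is.matrix(levels), !is.null(colnames(levels)),
            length(ids) == nrow(levels),
            length(n_levels) == ncol(levels))
  storage.mode(levels) <- "integer"
  rng <- apply(levels, 2, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  bad <- is.finite(rng) & rng > n_levels - 1L
  if (any(bad)) {
    abort(paste0("levels out of range for: ",
                 paste(colnames(levels)[bad], collapse = ", ")),
          class = "ckm_invalid_config")
  }
  structure(list(levels = levels, ids = as.character(ids), sex = sex,
                 features = colnames(levels),
                 n_levels = as.integer(n_levels)),
            class = "binned_cohort")
}

#' @export
print.binned_cohort <- function(x, ...) {
  obs <- mean(!is.na(x$levels))
  cat(sprintf("<binned_cohort> %d participants x %d features (%.1f%% observed)\n",
              nrow(x$levels), ncol(x$levels), 100 * obs))
  invisible(x)
}

#' Long-format view of a binned cohort
#'
#' @param x A [binned_cohort].
#' @param ... Unused.
#' @return A tibble with columns `id`, `feature`, `level` (observed
#'   entries only).
#' @export
as_tibble.binned_cohort <- function(x, ...) {
  tibble::tibble(
    id = rep(x$ids, times = ncol(x$levels)),
    feature = rep(x$features, each = nrow(x$levels)),
    level = as.integer(x$levels)
  ) |>
    dplyr::filter(!is.na(.data$level))
}

# subset participants (used by train/validation splitting)
subset_binned <- function(x, idx) {
  new_binned_cohort(x$levels[idx, , drop = FALSE], ids = x$ids[idx],
                    sex = x$sex[idx], n_levels = x$n_levels)
}
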