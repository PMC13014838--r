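#' Per-platform GWAS of a quantitative topic loading
#'
#' Per variant, ordinary least squares of the (typically rank-inverse-normal
#' transformed) loading on additive dosage plus model covariates, with a
#' two-sided Wald t-test on the dosage slope. Computed by
#' Frisch-Waugh-Lovell residualization: both the response and every dosage
#' column are residualized on the covariate matrix, giving the exact joint
#' OLS slope and standard error for all variants in one pass. Monomorphic
#' variants are returned with `NA` effects and excluded downstream.
#'
#' @param loading Numeric response vector (one platform's participants).
#' @param dosage n x m matrix of 0/1/2 dosages.
#' @param covariates Data frame of covariates (dummy-coded internally);
#'   `NULL` for an intercept-only model.
#' @return Tibble: `variant`, `beta`, `se`, `p`, `n`.
#' @export
gwas_platform <- function(loading, dosage, covariates = NULL) {
  dosage <- as.matrix(dosage)
  n <- length(loading)
  stopifnot(nrow(dosage) == n)
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    model.matrix(~ ., data = as.data.frame(covariates))
  qx <- qr(X)
  yr <- qr.resid(qx, loading)
  Gr <- qr.resid(qx, dosage)
  gss <- colSums(Gr^2)
  mono <- apply(dosage, 2, function(g) length(unique(g)) == 1L) | gss < 1e-12
  beta <- colSums(Gr * yr) / gss
  df <- n - qx$rank - 1L
  rss <- sum(yr^2) - beta^2 * gss
  se <- sqrt(pmax(rss, 0) / df / gss)
  p <- 2 * pt(abs(beta / se), df, lower.tail = FALSE)
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_
  tibble::tibble(variant = colnames(dosage) %||% as.character(seq_len(ncol(dosage))),
                 beta = unname(beta), se = unname(se), p = unname(p), n = n)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines per-platform estimates with weights `w_i = 1/SE_i^2`:
#' `beta = sum(w b) / sum(w)`, `SE = 1/sqrt(sum(w))`, two-sided Wald p.
#' Platforms with undefined estimates contribute nothing; a record where
#' every platform is undefined stays undefined.
#'
#' @param beta,se Equal-length numeric vectors (or matrices with one row
#'   per variant and one column per platform) of per-platform estimates.
#' @return Tibble: `beta`, `se`, `p`.
#' @export
#' @examples
#' meta_fixed(c(0.2, 0.4), c(0.1, 0.1))  # beta 0.3, se 0.1/sqrt(2)
meta_fixed <- function(beta, se) {
  # a plain vector is read as one variant across platforms
  beta <- rbind(beta); se <- rbind(se)
  stopifnot(all(dim(beta) == dim(se)))
  w <- 1 / se^2
  w[!is.finite(w) | is.na(beta)] <- 0
  b0 <- beta; b0[w == 0] <- 0
  sw <- rowSums(w)
  mb <- rowSums(w * b0) / sw
  mse <- 1 / sqrt(sw)
  mb[sw == 0] <- NA_real_; mse[sw == 0] <- NA_real_
  mp <- 2 * pnorm(abs(mb / mse), lower.tail = FALSE)
  tibble::tibble(beta = unname(mb), se = unname(mse), p = unname(mp))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; values
#' near 1 indicate calibrated p-values, larger values inflation.
#'
#' @param p Vector of GWAS p-values.
#' @return Scalar lambda.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) warn("lambda_gc computed on fewer than 100 p-values")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Run a full per-platform + meta-analyzed GWAS
#'
#' Splits participants by genotyping platform, runs [gwas_platform()] per
#' platform, combines estimates with [meta_fixed()] to account for batch
#' effects, and attaches per-analysis genomic inflation factors.
#'
#' @param loading Response vector for all participants.
#' @param geno A [generate_genotypes()]-shaped list (`dosage`, `variants`,
#'   `platform`) or any list with those elements.
#' @param covariates Data frame of covariates for all participants, or
#'   `NULL`.
#' @param sig_threshold Genome-wide significance threshold (default 1e-8).
#' @return Tibble of class `ckm_gwas`: variant info columns plus
#'   `beta_p1..3`, `se_p1..3`, `beta`, `se`, `p`, `significant`; attributes
#'   `lambda` (meta) and `lambda_platform`.
#' @export
run_gwas <- function(loading, geno, covariates = NULL,
                     sig_threshold = 1e-8) {
  platforms <- sort(unique(geno$platform))
  per <- lapply(platforms, function(pl) {
    idx <- geno$platform == pl
    cv <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[idx, , drop = FALSE]
    gwas_platform(loading[idx], geno$dosage[idx, , drop = FALSE], cv)
  })
  bmat <- do.call(cbind, lapply(per, `[[`, "beta"))
  smat <- do.call(cbind, lapply(per, `[[`, "se"))
  meta <- meta_fixed(bmat, smat)
  out <- geno$variants
  for (i in seq_along(platforms)) {
    out[[paste0("beta_p", platforms[i])]] <- bmat[, i]
    out[[paste0("se_p", platforms[i])]] <- smat[, i]
  }
  out$beta <- meta$beta
  out$se <- meta$se
  out$p <- meta$p
  out$significant <- !is.na(out$p) & out$p < sig_threshold
  class(out) <- c("ckm_gwas", class(out))
  attr(out, "lambda") <- lambda_gc(out$p)
  attr(out, "lambda_platform") <-
    vapply(per, function(x) lambda_gc(x$p), numeric(1))
  attr(out, "sig_threshold") <- sig_threshold
  out
}

#' Greedy LD clumping of significant variants
#'
#' Repeatedly takes the smallest-p unclaimed genome-wide-significant variant
#' as a lead and claims every variant on the same chromosome within
#' `window_bp` whose sample dosage correlation with the lead satisfies
#' `r^2 >= r2_threshold`. A stand-in for web-based post-GWAS lead
#' assessment; deterministic given the table and genotypes.
#'
#' @param gwas A [run_gwas()] result.
#' @param dosage Dosage matrix used to estimate sample LD.
#' @param r2_threshold LD r-squared above which variants join a clump
#'   (default 0.1).
#' @param window_bp Physical window around the lead (default 500 kb).
#' @return The gwas tibble with a logical `lead` column.
#' @export
clump_leads <- function(gwas, dosage, r2_threshold = 0.1,
                        window_bp = 5e5) {
  stopifnot(inherits(gwas, "ckm_gwas"))
  gwas$lead <- FALSE
  sig <- which(gwas$significant)
  if (length(sig) == 0) return(gwas)
  claimed <- rep(FALSE, nrow(gwas))
  repeat {
    open <- sig[!claimed[sig]]
    if (length(open) == 0) break
    lead <- open[which.min(gwas$p[open])]
    gwas$lead[lead] <- TRUE
    claimed[lead] <- TRUE
    near <- which(gwas$chr == gwas$chr[lead] &
                    abs(gwas$pos - gwas$pos[lead]) <= window_bp &
                    !claimed)
    if (length(near) > 0) {
      r <- suppressWarnings(
        stats::cor(dosage[, lead], dosage[, near, drop = FALSE]))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      claimed[near[r2 >= r2_threshold]] <- TRUE
    }
  }
  gwas
}

#' Build, score, and validate a polygenic risk score
#'
#' `build_prs()` collects lead variants and their meta-analysis effects as
#' weights; `score_prs()` computes the weighted dosage sum per participant
#' and standardizes it to mean 0, variance 1; `validate_prs()` tests the
#' association between the score and each disease outcome by logistic
#' regression (default) or a linear-probability model, adjusted for
#' covariates.
#'
#' @param gwas A clumped [run_gwas()] result (with a `lead` column).
#' @param subtype Label stored on the model.
#' @return `build_prs`: list of class `ckm_prs` with `weights` (tibble
#'   `variant`, `weight`) and `subtype`.
#' @export
build_prs <- function(gwas, subtype = "subtype") {
  stopifnot(inherits(gwas, "ckm_gwas"), "lead" %in% names(gwas))
  leads <- gwas[gwas$lead, ]
  if (nrow(leads) == 0) {
    abort("no lead variants to build a PRS from", class = "ckm_prs_error")
  }
  structure(list(weights = tibble::tibble(variant = leads$id,
                                          weight = leads$beta),
                 subtype = subtype),
            class = "ckm_prs")
}

#' @rdname build_prs
#' @param prs A `ckm_prs` model.
#' @param dosage Validation-cohort dosage matrix with variant column names.
#' @export
score_prs <- function(prs, dosage) {
  stopifnot(inherits(prs, "ckm_prs"))
  idx <- match(prs$weights$variant, colnames(dosage))
  miss <- is.na(idx)
  if (any(miss)) {
    warn(sprintf("%d lead variant(s) absent from validation genotypes; dropped",
                 sum(miss)))
  }
  if (all(miss)) abort("no PRS variants present", class = "ckm_prs_error")
  raw <- as.vector(dosage[, idx[!miss], drop = FALSE] %*%
                     prs$weights$weight[!miss])
  if (sd(raw) == 0) return(rep(0, length(raw)))
  as.vector(scale(raw))
}

#' @rdname build_prs
#' @param scores Standardized PRS per validation participant.
#' @param outcomes Data frame of binary disease indicators.
#' @param covariates Optional covariate data frame.
#' @param family `"logistic"` or `"linear"` (linear-probability model).
#' @export
validate_prs <- function(scores, outcomes, covariates = NULL,
                         family = c("logistic", "linear")) {
  family <- match.arg(family)
  outcomes <- as.data.frame(outcomes)
  purrr::map_dfr(names(outcomes), function(dz) {
    d <- data.frame(y = outcomes[[dz]], prs = scores)
    if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
    if (family == "logistic") {
      fit <- glm(y ~ ., data = d, family = binomial())
    } else {
      fit <- lm(y ~ ., data = d)
    }
    sm <- unname(summary(fit)$coefficients["prs", ])
    tibble::tibble(outcome = dz, beta = sm[1], se = sm[2],
                   p = sm[4], direction = sign(sm[1]))
  })
}

#' Single biomarker-level indicator GWAS
#'
#' The comparison analysis behind the constellation-power argument: for
#' each (feature, level) vocabulary entry, a 0/1 indicator of whether the
#' participant's observed level equals it is regressed on dosage (plus
#' covariates) exactly like the loading GWAS. A variant whose effect is
#' spread over many level probabilities can reach genome-wide significance
#' on the topic loading while no single indicator does.
#'
#' @param binned A [binned_cohort].
#' @param dosage Single-variant dosage vector or one-column matrix.
#' @param covariates Optional covariate data frame.
#' @return Tibble: `feature`, `level`, `beta`, `se`, `p`.
#' @export
single_level_gwas <- function(binned, dosage, covariates = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == 1, nrow(dosage) == nrow(binned$levels))
  purrr::map_dfr(seq_along(binned$features), function(f) {
    lv <- binned$levels[, f]
    purrr::map_dfr(0:(binned$n_levels[f] - 1L), function(l) {
      ind <- as.numeric(lv == l)
      ok <- !is.na(ind)
      if (length(unique(ind[ok])) < 2) {
        # level never (or always) observed: no indicator variation to test
        return(tibble::tibble(feature = binned$features[f], level = l,
                              beta = NA_real_, se = NA_real_, p = NA_real_))
      }
      res <- gwas_platform(ind[ok], dosage[ok, 1, drop = FALSE],
                           if (is.null(covariates)) NULL else
                             as.data.frame(covariates)[ok, , drop = FALSE])
      tibble::tibble(feature = binned$features[f], level = l,
                     beta = res$beta, se = res$se, p = res$p)
    })
  })
}
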