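#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the full set of generative parameters for a synthetic
#' population cohort with the statistical structure the downstream analysis
#' assumes: `K_true` latent topics over discretized biomarkers, per-feature
#' missingness, self-reported disease risk that is logistic in the topic
#' loadings, and biallelic variants whose dosages tilt the loadings.
#'
#' @param n_participants Number of participants.
#' @param n_features Number of topic-driven biomarker features.
#' @param n_levels Number of discretized levels per feature (default 5,
#'   matching decile-tail percentile bins).
#' @param K_true Number of latent topics generating the data.
#' @param topic_sharpness Dirichlet concentration used to draw each topic's
#'   per-feature level distribution; small values give sharp, well-separated
#'   topics.
#' @param alpha_gen Dirichlet concentration vector (length `K_true`) for
#'   participant loadings.
#' @param missing_rates Per-feature missingness probability, recycled to
#'   `n_features`. Missingness is MCAR.
#' @param disease_specs A list of disease specifications, each created with
#'   [disease_spec()].
#' @param n_variants Number of biallelic variants to simulate (0 for none).
#' @param maf_range Interval in (0, 0.5) from which per-LD-block minor allele
#'   frequencies are drawn.
#' @param ld_block_size Number of variants per LD block.
#' @param ld_rho Haplotype copying probability within a block; pairwise
#'   dosage correlation within a block is about `ld_rho^2`.
#' @param platform_fractions Three nonnegative fractions summing to 1 giving
#'   the genotyping platform split.
#' @param genetic_effects Data frame with columns `variant`, `topic`,
#'   `gamma`: variant `j` multiplies participant `i`'s Dirichlet
#'   concentration for `topic` by `exp(gamma * dosage_ij)`.
#' @param seed Integer seed; the same config reproduces the cohort
#'   bit-for-bit.
#'
#' @return A validated `ckm_gen_config` list.
#' @seealso [generate_cohort()], [generate_genotypes()]
#' @export
#' @examples
#' cfg <- gen_config(n_participants = 200, n_features = 6, K_true = 3, seed = 1)
#' cfg$K_true
gen_config <- function(n_participants = 3000,
                       n_features = 20,
                       n_levels = 5,
                       K_true = 5,
                       topic_sharpness = 0.1,
                       alpha_gen = rep(0.3, K_true),
                       missing_rates = 0,
                       disease_specs = default_disease_specs(K_true),
                       n_variants = 0,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.9,
                       platform_fractions = c(0.12, 0.45, 0.43),
                       genetic_effects = NULL,
                       seed = 1L) {
  n_participants <- assert_count(n_participants, "n_participants")
  n_features <- assert_count(n_features, "n_features")
  n_levels <- assert_count(n_levels, "n_levels", min = 2L)
  K_true <- assert_count(K_true, "K_true")
  if (!is.numeric(topic_sharpness) || topic_sharpness <= 0) {
    abort("`topic_sharpness` must be positive", class = "ckm_invalid_config")
  }
  if (length(alpha_gen) != K_true || any(alpha_gen <= 0)) {
    abort("`alpha_gen` must be a positive vector of length K_true",
          class = "ckm_invalid_config")
  }
  missing_rates <- assert_prob(rep_len(missing_rates, n_features),
                               "missing_rates")
  if (n_variants > 0) {
    if (maf_range[1] <= 0 || maf_range[2] >= 0.5 + 1e-12 ||
        maf_range[1] > maf_range[2]) {
      abort("`maf_range` must lie within (0, 0.5]", class = "ckm_invalid_config")
    }
    ld_block_size <- assert_count(ld_block_size, "ld_block_size")
    if (length(platform_fractions) != 3 || any(platform_fractions < 0) ||
        abs(sum(platform_fractions) - 1) > 1e-12) {
      abort("`platform_fractions` must be 3 nonnegative values summing to 1",
            class = "ckm_invalid_config")
    }
  }
  if (!is.null(genetic_effects)) {
    genetic_effects <- tibble::as_tibble(genetic_effects)
    stopifnot(all(c("variant", "topic", "gamma") %in% names(genetic_effects)))
    if (any(genetic_effects$variant > n_variants) ||
        any(genetic_effects$topic > K_true)) {
      abort("genetic_effects reference out-of-range variant or topic",
            class = "ckm_invalid_config")
    }
  }
  for (ds in disease_specs) {
    if (length(ds$weights) != K_true) {
      abort("each disease_spec weights vector must have length K_true",
            class = "ckm_invalid_config")
    }
  }
  structure(
    list(n_participants = n_participants, n_features = n_features,
         n_levels = n_levels, K_true = K_true,
         topic_sharpness = topic_sharpness, alpha_gen = alpha_gen,
         missing_rates = missing_rates, disease_specs = disease_specs,
         n_variants = as.integer(n_variants), maf_range = maf_range,
         ld_block_size = ld_block_size, ld_rho = ld_rho,
         platform_fractions = platform_fractions,
         genetic_effects = genetic_effects, seed = as.integer(seed)),
    class = "ckm_gen_config"
  )
}

#' Specify one simulated disease
#'
#' @param name Disease name (column name in the phenotype table).
#' @param baseline Baseline log-odds of the disease.
#' @param weights Per-topic log-odds weights: a participant's disease
#'   probability is `plogis(baseline + sum(weights * theta))`.
#' @return A `disease_spec` list.
#' @export
disease_spec <- function(name, baseline, weights) {
  stopifnot(is.character(name), length(name) == 1, is.numeric(baseline))
  structure(list(name = name, baseline = baseline, weights = weights),
            class = "ckm_disease_spec")
}

#' @rdname disease_spec
#' @param K_true Number of topics (weights default to the null, all zero).
#' @export
default_disease_specs <- function(K_true) {
  list(
    disease_spec("kidney_disease", qlogis(0.01), rep(0, K_true)),
    disease_spec("t2dm", qlogis(0.04), rep(0, K_true)),
    disease_spec("cvd", qlogis(0.07), rep(0, K_true))
  )
}

# Topic-specific level distributions: K x n_levels matrix per feature,
# rows ~ Dirichlet(topic_sharpness).
draw_true_topics <- function(config) {
  lapply(seq_len(config$n_features), function(f) {
    rdirichlet_mat(config$K_true, rep(config$topic_sharpness, config$n_levels))
  })
}

#' Generate a synthetic phenotype cohort with recorded ground truth
#'
#' Draws participant topic loadings from a Dirichlet (optionally tilted by
#' genotype dosages), emits one categorical level per observed feature from
#' the loading-weighted mixture of topic level distributions, synthesizes
#' matching continuous biomarker values, simple demographics, blood
#' pressure, and Bernoulli disease indicators whose logit is linear in the
#' loadings. Everything the generator used is returned as ground truth.
#'
#' @param config A [gen_config()] object.
#' @return A list of class `ckm_cohort` with elements
#'   \describe{
#'     \item{pheno}{tibble, one row per participant: `id`, `sex`, `age`,
#'       `smoking`, `bmi`, `whr`, `weight`, `sbp`, `dbp`, one column per
#'       biomarker (continuous, `NA` where missing) and one 0/1 column per
#'       configured disease.}
#'     \item{binned}{a [binned_cohort] of the generated categorical levels.}
#'     \item{truth}{list: `phi` (K x V topic-level probabilities over the
#'       (feature, level) vocabulary), `phi_levels` (per-feature K x L level
#'       tables), `theta` (n x K loadings), `missing_mask`, `disease_specs`,
#'       `genetic_effects`.}
#'     \item{geno}{the [generate_genotypes()] output when
#'       `config$n_variants > 0`, else `NULL`.}
#'   }
#' @export
#' @examples
#' cfg <- gen_config(n_participants = 100, n_features = 5, K_true = 2, seed = 7)
#' coh <- generate_cohort(cfg)
#' dim(coh$truth$theta)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ckm_gen_config"))
  n <- config$n_participants
  F_ <- config$n_features
  L <- config$n_levels
  K <- config$K_true

  geno <- NULL
  if (config$n_variants > 0) geno <- generate_genotypes(config)

  set.seed(config$seed + 1L)

  # demographics, independent of topics by default
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  age <- round(runif(n, 18, 80))
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  male <- sex == "male"
  bmi <- rnorm(n, 26, 4)
  whr <- rnorm(n, 0.85 + 0.07 * male, 0.06)
  weight <- rnorm(n, 70 + 12 * male, 12)
  sbp <- rnorm(n, 122, 15)
  dbp <- rnorm(n, 76, 10)

  # loadings, with multiplicative genetic tilt on the Dirichlet concentration
  alpha_mat <- matrix(config$alpha_gen, n, K, byrow = TRUE)
  if (!is.null(config$genetic_effects) && !is.null(geno)) {
    ge <- config$genetic_effects
    for (r in seq_len(nrow(ge))) {
      g <- geno$dosage[, ge$variant[r]]
      alpha_mat[, ge$topic[r]] <-
        alpha_mat[, ge$topic[r]] * exp(ge$gamma[r] * g)
    }
  }
  theta <- rdirichlet_mat(n, alpha_mat)

  phi_levels <- draw_true_topics(config)

  # per feature: mixture draw of a level, then a continuous value placed in
  # the level's percentile band of a Gaussian biomarker scale
  bands <- percentile_bands(L)
  levels_mat <- matrix(NA_integer_, n, F_)
  values_mat <- matrix(NA_real_, n, F_)
  topic_pick <- sample_rows(theta)  # reused buffer shape; redrawn per feature
  for (f in seq_len(F_)) {
    topic_pick <- sample_rows(theta)
    lev <- sample_rows(phi_levels[[f]][topic_pick, , drop = FALSE])
    u <- runif(n, bands[lev], bands[lev + 1L])
    levels_mat[, f] <- lev - 1L
    values_mat[, f] <- 10 + f + qnorm(u) + 0.4 * male
  }

  missing_mask <- matrix(
    rbinom(n * F_, 1, rep(config$missing_rates, each = n)) == 1, n, F_)
  levels_mat[missing_mask] <- NA_integer_
  values_mat[missing_mask] <- NA_real_

  feature_names <- sprintf("bm%02d", seq_len(F_))
  colnames(levels_mat) <- feature_names
  colnames(values_mat) <- feature_names
  ids <- sprintf("P%06d", seq_len(n))

  diseases <- lapply(config$disease_specs, function(ds) {
    p <- plogis(ds$baseline + as.vector(theta %*% ds$weights))
    rbinom(n, 1, p)
  })
  names(diseases) <- vapply(config$disease_specs, `[[`, "", "name")

  pheno <- tibble::tibble(
    id = ids, sex = sex, age = age, smoking = smoking,
    bmi = bmi, whr = whr, weight = weight, sbp = sbp, dbp = dbp
  )
  pheno <- dplyr::bind_cols(pheno, tibble::as_tibble(values_mat),
                            tibble::as_tibble(diseases))

  binned <- new_binned_cohort(levels_mat, ids = ids, sex = sex,
                              n_levels = rep(L, F_))

  truth <- list(
    phi = topics_to_vocab_phi(phi_levels, feature_names),
    phi_levels = setNames(phi_levels, feature_names),
    theta = theta,
    missing_mask = missing_mask,
    disease_specs = config$disease_specs,
    genetic_effects = config$genetic_effects
  )

  structure(list(pheno = pheno, binned = binned, truth = truth,
                 geno = geno, config = config),
            class = "ckm_cohort")
}

# interior band edges for L percentile levels: 5 levels -> 0,.1,.3,.7,.9,1,
# otherwise equal-width
percentile_bands <- function(L) {
  if (L == 5) c(0, 0.1, 0.3, 0.7, 0.9, 1) else seq(0, 1, length.out = L + 1)
}

# Flatten per-feature level tables into a K x V probability table over the
# (feature, level) vocabulary: each feature contributes one token, so
# p((f, l) | k) = levelprob / n_features.
topics_to_vocab_phi <- function(phi_levels, feature_names) {
  K <- nrow(phi_levels[[1]])
  F_ <- length(phi_levels)
  cols <- do.call(cbind, phi_levels) / F_
  colnames(cols) <- unlist(lapply(seq_len(F_), function(f) {
    paste0(feature_names[f], ":", seq_len(ncol(phi_levels[[f]])) - 1L)
  }))
  rownames(cols) <- paste0("topic", seq_len(K))
  cols
}

#' Generate synthetic genotypes in LD blocks across three platforms
#'
#' Variants are organized in blocks sharing a latent block allele frequency;
#' within a block each haplotype copies the block's latent allele with
#' probability `ld_rho` (else draws independently), producing within-block
#' dosage correlation of about `ld_rho^2` and independence between blocks.
#'
#' @param config A [gen_config()] with `n_variants > 0`.
#' @return A list of class `ckm_genotypes`: `dosage` (n x m matrix in
#'   0/1/2), `variants` (tibble: `id`, `chr`, `pos`, `ea`, `nea`, `maf`,
#'   `block`), `platform` (integer 1..3 per participant).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "ckm_gen_config"))
  if (config$n_variants < 1) {
    abort("config has n_variants = 0", class = "ckm_invalid_config")
  }
  set.seed(config$seed)
  n <- config$n_participants
  m <- config$n_variants
  bs <- config$ld_block_size
  rho <- config$ld_rho
  blocks <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  n_block <- max(blocks)
  block_maf <- runif(n_block, config$maf_range[1], config$maf_range[2])

  dosage <- matrix(0L, n, m)
  for (b in seq_len(n_block)) {
    idx <- which(blocks == b)
    f <- block_maf[b]
    # two latent haplotype alleles per participant
    h1 <- rbinom(n, 1, f)
    h2 <- rbinom(n, 1, f)
    for (j in idx) {
      copy1 <- rbinom(n, 1, rho)
      copy2 <- rbinom(n, 1, rho)
      a1 <- ifelse(copy1 == 1, h1, rbinom(n, 1, f))
      a2 <- ifelse(copy2 == 1, h2, rbinom(n, 1, f))
      dosage[, j] <- as.integer(a1 + a2)
    }
  }

  platform <- sample.int(3L, n, replace = TRUE,
                         prob = config$platform_fractions)
  maf_emp <- colMeans(dosage) / 2
  maf_emp <- pmin(maf_emp, 1 - maf_emp)
  variants <- tibble::tibble(
    id = sprintf("rs%06d", seq_len(m)),
    chr = blocks %% 22L + 1L,
    pos = (seq_len(m) - 1L) %% config$ld_block_size * 10000L +
      (blocks - 1L) %/% 22L * 10000000L + 1L,
    ea = "A", nea = "G",
    maf = maf_emp,
    block = blocks
  )
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, platform = platform),
            class = "ckm_genotypes")
}

#' @export
print.ckm_cohort <- function(x, ...) {
  cat(sprintf("<ckm_cohort> %d participants, %d biomarkers, K_true = %d\n",
              nrow(x$pheno), x$config$n_features, x$config$K_true))
  if (!is.null(x$geno)) {
    cat(sprintf("  genotypes: %d variants, 3 platforms\n",
                ncol(x$geno$dosage)))
  }
  invisible(x)
}
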