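#' Pipeline configuration
#'
#' Collects every stage parameter of the subtype-discovery pipeline with
#' the package defaults: percentile bin probabilities, topic-count grid,
#' eight Markov chains, MCMC schedule, silhouette threshold, loading
#' threshold 0.5 with sensitivity list (0.5, 0.4, 0.3), genome-wide
#' significance 1e-8, and clumping parameters. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults, or `yaml` = path to a YAML file
#'   whose keys override them.
#' @return A validated `ckm_pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    cohort = list(n_participants = 3000, n_features = 20, K_true = 5,
                  n_variants = 0),
    bin_probs = c(0.1, 0.3, 0.7, 0.9),
    K_grid = 2:8,
    n_chains = 8L,
    alpha = NULL,           # NULL -> 1/K
    beta_h = 0.1,
    n_burn = 500L, n_samples = 100L, thin = 5L,
    train_frac = 1 / 3,
    silhouette_threshold = 0.1,
    loading_threshold = 0.5,
    sensitivity_thresholds = c(0.5, 0.4, 0.3),
    gwas_threshold = 1e-8,
    clump_r2 = 0.1, clump_window_bp = 5e5,
    rank_method = "fractional",
    diseases = c("kidney_disease", "t2dm", "cvd")
  )
  over <- list(...)
  if (!is.null(over$yaml)) {
    yml <- yaml::read_yaml(over$yaml)
    over$yaml <- NULL
    over <- utils::modifyList(yml, over)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ckm_invalid_config")
  }
  cfg <- utils::modifyList(defaults, over)
  if (cfg$loading_threshold <= 0 || cfg$loading_threshold > 1) {
    abort("loading_threshold must be in (0, 1]", class = "ckm_invalid_config")
  }
  if (cfg$gwas_threshold <= 0 || cfg$gwas_threshold >= 1) {
    abort("gwas_threshold must be in (0, 1)", class = "ckm_invalid_config")
  }
  if (cfg$n_chains < 2) {
    abort("n_chains must be at least 2", class = "ckm_invalid_config")
  }
  structure(cfg, class = "ckm_pipeline_config")
}

stage_artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' needs missing upstream artifact: %s",
                  stage, path),
          class = "ckm_missing_artifact")
  }
  path
}

write_manifest <- function(out_dir, stage, cfg, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    config = unclass(cfg),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("ckmtopics"))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' Run one pipeline stage
#'
#' Executes one named stage of the end-to-end pipeline on a working
#' directory of plain-text artifacts, writing the stage outputs plus a
#' machine-readable run manifest (seeds, config, input checksums).
#' Stages: `simulate` (synthetic cohort + genotypes), `discretize` (fit and
#' apply percentile bins to the continuous phenotype table), `fit`
#' (K selection and the multi-chain topic model), `align` (chain alignment,
#' silhouette filter, pooled profiles), `associate` (loading-covariate and
#' loading-disease regressions, subtype calls, prevalence), `gwas`
#' (per-platform GWAS + meta-analysis + clumping per candidate subtype),
#' `prs` (PRS construction and within-run validation split), `report`
#' (collates everything into `report.json`).
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param out_dir Working directory for artifacts.
#' @return Invisibly, a character vector of written artifact paths.
#' @export
run_stage <- function(stage = c("simulate", "discretize", "fit", "align",
                                "associate", "gwas", "prs", "report"),
                      config = pipeline_config(), out_dir = ".") {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "ckm_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
               simulate = stage_simulate, discretize = stage_discretize,
               fit = stage_fit, align = stage_align,
               associate = stage_associate, gwas = stage_gwas,
               prs = stage_prs, report = stage_report)
  fn(config, out_dir)
}

stage_simulate <- function(cfg, out) {
  gc_args <- cfg$cohort
  gc_args$seed <- cfg$seed
  gcfg <- do.call(gen_config, gc_args)
  coh <- generate_cohort(gcfg)
  paths <- c(pheno = stage_artifact(out, "pheno.csv"),
             binned = stage_artifact(out, "binned.tsv"),
             truth = stage_artifact(out, "truth.json"))
  write_pheno(coh$pheno, paths["pheno"])
  write_binned(coh$binned, paths["binned"])
  jsonlite::write_json(
    list(theta = coh$truth$theta, phi = coh$truth$phi,
         vocab = colnames(coh$truth$phi)),
    paths["truth"], digits = NA)
  if (!is.null(coh$geno)) {
    gp <- c(dosage = stage_artifact(out, "dosage.tsv"),
            platform = stage_artifact(out, "platforms.tsv"),
            variants = stage_artifact(out, "variants.tsv"),
            vcf = stage_artifact(out, "genotypes.vcf"))
    write_genotypes(coh$geno, gp["dosage"], gp["platform"], gp["variants"])
    write_vcf(coh$geno, gp["vcf"])
    paths <- c(paths, gp)
  }
  write_manifest(out, "simulate", cfg, character(), as.list(paths))
  invisible(paths)
}

stage_discretize <- function(cfg, out) {
  ph_path <- require_artifact(stage_artifact(out, "pheno.csv"), "discretize")
  pheno <- read_pheno(ph_path)
  feats <- grep("^bm[0-9]+$", names(pheno), value = TRUE)
  spec <- fit_bins(pheno, feats, probs = cfg$bin_probs)
  binned <- apply_bins(pheno, spec, bp_cols = c("sbp", "dbp"))
  paths <- c(spec = stage_artifact(out, "bin_spec.json"),
             binned = stage_artifact(out, "binned_refit.tsv"))
  write_bin_spec(spec, paths["spec"])
  write_binned(binned, paths["binned"])
  write_manifest(out, "discretize", cfg, list(ph_path), as.list(paths))
  invisible(paths)
}

stage_fit <- function(cfg, out) {
  b_path <- require_artifact(stage_artifact(out, "binned.tsv"), "fit")
  binned <- read_binned(b_path)
  sel <- select_K(binned, cfg$K_grid, split_seed = cfg$seed,
                  train_frac = cfg$train_frac, beta_h = cfg$beta_h,
                  n_burn = cfg$n_burn, n_samples = cfg$n_samples,
                  thin = cfg$thin)
  K <- sel$K
  chains <- fit_chains(binned, K, n_chains = cfg$n_chains,
                       base_seed = cfg$seed, alpha = cfg$alpha %||% 1 / K,
                       beta_h = cfg$beta_h, n_burn = cfg$n_burn,
                       n_samples = cfg$n_samples, thin = cfg$thin)
  diag <- entropy_diagnostic(chains)
  paths <- c(chains = stage_artifact(out, "chain_phi_means.tsv"),
             curve = stage_artifact(out, "k_selection.tsv"),
             fitjson = stage_artifact(out, "fit.json"))
  # chains themselves are kept in-memory-reconstructible: store per-chain
  # posterior-mean tables plus enough metadata to refit identically
  pm <- purrr::imap_dfr(chains, function(ch, i) {
    m <- phi_mean(ch)
    tibble::tibble(chain = i, topic = rep(seq_len(K), ncol(m)),
                   entry = rep(colnames(m), each = K), phi = as.vector(m))
  })
  utils::write.table(pm, paths["chains"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sel$curve, paths["curve"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(K = K, n_chains = cfg$n_chains, seed = cfg$seed,
         alpha = cfg$alpha %||% 1 / K, beta_h = cfg$beta_h,
         n_burn = cfg$n_burn, n_samples = cfg$n_samples, thin = cfg$thin,
         diagnostic_pass = diag$pass, diagnostic_frac = diag$frac_ok),
    paths["fitjson"], auto_unbox = TRUE, digits = NA)
  write_manifest(out, "fit", cfg, list(b_path), as.list(paths))
  invisible(paths)
}

refit_chains_from_manifest <- function(cfg, out) {
  fj <- jsonlite::read_json(
    require_artifact(stage_artifact(out, "fit.json"), "align"),
    simplifyVector = TRUE)
  binned <- read_binned(require_artifact(stage_artifact(out, "binned.tsv"),
                                         "align"))
  chains <- fit_chains(binned, fj$K, n_chains = fj$n_chains,
                       base_seed = fj$seed, alpha = fj$alpha,
                       beta_h = fj$beta_h, n_burn = fj$n_burn,
                       n_samples = fj$n_samples, thin = fj$thin)
  list(chains = chains, K = fj$K)
}

stage_align <- function(cfg, out) {
  ck <- refit_chains_from_manifest(cfg, out)
  ens <- align_ensemble(ck$chains)
  ens <- silhouette_filter(ens, cfg$silhouette_threshold)
  paths <- c(pooled = stage_artifact(out, "pooled_profiles.tsv"),
             theta = stage_artifact(out, "theta_mean.tsv"),
             align = stage_artifact(out, "alignment.json"))
  utils::write.table(ens$pooled, paths["pooled"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(id = rownames(ens$theta_mean), ens$theta_mean,
               check.names = FALSE),
    paths["theta"], sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(permutations = ens$permutations, costs = ens$costs,
         silhouette = ens$silhouette, robust_topics = ens$robust_topics),
    paths["align"], digits = NA)
  write_manifest(out, "align", cfg,
                 list(stage_artifact(out, "fit.json")), as.list(paths))
  invisible(paths)
}

read_theta_mean <- function(out, stage) {
  tm <- utils::read.delim(
    require_artifact(stage_artifact(out, "theta_mean.tsv"), stage),
    check.names = FALSE)
  m <- as.matrix(tm[, -1, drop = FALSE])
  rownames(m) <- tm$id
  m
}

stage_associate <- function(cfg, out) {
  theta <- read_theta_mean(out, "associate")
  pheno <- read_pheno(require_artifact(stage_artifact(out, "pheno.csv"),
                                       "associate"))
  robust <- jsonlite::read_json(
    require_artifact(stage_artifact(out, "alignment.json"), "associate"),
    simplifyVector = TRUE)$robust_topics
  theta <- theta[, robust, drop = FALSE]
  design <- pheno[, c("sex", "age", "smoking", "bmi", "whr", "weight",
                      cfg$diseases)]
  assoc <- associate(theta, design, method = cfg$rank_method)
  calls <- classify_subtypes(assoc, cfg$diseases)
  ckm_topics <- calls$topic[calls$call == "candidate_CKM"]
  paths <- c(assoc = stage_artifact(out, "associations.tsv"),
             calls = stage_artifact(out, "subtype_calls.tsv"),
             prev = stage_artifact(out, "prevalence.json"))
  utils::write.table(assoc, paths["assoc"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(calls, paths["calls"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  prev <- if (length(ckm_topics) > 0) {
    prevalence(theta, ckm_topics, cfg$loading_threshold,
               cfg$sensitivity_thresholds)
  } else NULL
  jsonlite::write_json(
    if (is.null(prev)) list(note = "no candidate subtypes called") else
      list(per_topic = prev$per_topic, overall = prev$overall,
           sensitivity = prev$sensitivity),
    paths["prev"], digits = NA)
  write_manifest(out, "associate", cfg,
                 list(stage_artifact(out, "theta_mean.tsv")), as.list(paths))
  invisible(paths)
}

stage_gwas <- function(cfg, out) {
  theta <- read_theta_mean(out, "gwas")
  require_artifact(stage_artifact(out, "fit.json"), "gwas")
  dosage <- read_dosage(require_artifact(stage_artifact(out, "dosage.tsv"),
                                         "gwas"))
  platform <- utils::read.delim(
    require_artifact(stage_artifact(out, "platforms.tsv"), "gwas"))$platform
  variants <- tibble::as_tibble(utils::read.delim(
    require_artifact(stage_artifact(out, "variants.tsv"), "gwas")))
  pheno <- read_pheno(require_artifact(stage_artifact(out, "pheno.csv"),
                                       "gwas"))
  calls <- utils::read.delim(
    require_artifact(stage_artifact(out, "subtype_calls.tsv"), "gwas"))
  targets <- calls$topic[calls$call == "candidate_CKM"]
  if (length(targets) == 0) targets <- colnames(theta)[1]
  geno <- list(dosage = dosage, variants = variants, platform = platform)
  covs <- pheno[, c("age", "sex", "smoking", "bmi", "whr", "weight")]
  paths <- character()
  for (tp in targets) {
    y <- rank_transform(theta[, tp], method = "rint")
    gw <- run_gwas(y, geno, covs, sig_threshold = cfg$gwas_threshold)
    gw <- clump_leads(gw, dosage, cfg$clump_r2, cfg$clump_window_bp)
    pth <- stage_artifact(out, paste0("gwas_", tp, ".tsv"))
    write_sumstats(gw, pth, n = nrow(dosage))
    paths <- c(paths, setNames(pth, paste0("gwas_", tp)))
  }
  jsonlite::write_json(list(targets = targets),
                       stage_artifact(out, "gwas_targets.json"),
                       digits = NA)
  paths <- c(paths, targets = stage_artifact(out, "gwas_targets.json"))
  write_manifest(out, "gwas", cfg,
                 list(stage_artifact(out, "theta_mean.tsv")), as.list(paths))
  invisible(paths)
}

stage_prs <- function(cfg, out) {
  targets <- jsonlite::read_json(
    require_artifact(stage_artifact(out, "gwas_targets.json"), "prs"),
    simplifyVector = TRUE)$targets
  dosage <- read_dosage(require_artifact(stage_artifact(out, "dosage.tsv"),
                                         "prs"))
  pheno <- read_pheno(require_artifact(stage_artifact(out, "pheno.csv"),
                                       "prs"))
  paths <- character()
  res <- purrr::map_dfr(targets, function(tp) {
    ss <- utils::read.delim(
      require_artifact(stage_artifact(out, paste0("gwas_", tp, ".tsv")),
                       "prs"))
    leads <- ss[ss$LEAD, ]
    if (nrow(leads) == 0) return(tibble::tibble())
    prs <- structure(list(weights = tibble::tibble(variant = leads$rsID,
                                                   weight = leads$BETA),
                          subtype = tp), class = "ckm_prs")
    sc <- score_prs(prs, dosage)
    val <- validate_prs(sc, pheno[, cfg$diseases],
                        pheno[, c("age", "sex", "smoking")])
    dplyr::mutate(val, subtype = tp, n_leads = nrow(leads))
  })
  pth <- stage_artifact(out, "prs_validation.tsv")
  if (nrow(res) == 0) {
    res <- tibble::tibble(outcome = character(), beta = numeric(),
                          se = numeric(), p = numeric(),
                          direction = numeric(), subtype = character(),
                          n_leads = integer())
  }
  utils::write.table(res, pth, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(out, "prs", cfg,
                 list(stage_artifact(out, "gwas_targets.json")),
                 list(prs = pth))
  invisible(c(prs = pth))
}

stage_report <- function(cfg, out) {
  calls <- utils::read.delim(
    require_artifact(stage_artifact(out, "subtype_calls.tsv"), "report"))
  prev <- jsonlite::read_json(
    require_artifact(stage_artifact(out, "prevalence.json"), "report"),
    simplifyVector = TRUE)
  fj <- jsonlite::read_json(
    require_artifact(stage_artifact(out, "fit.json"), "report"),
    simplifyVector = TRUE)
  report <- list(K = fj$K, diagnostic_pass = fj$diagnostic_pass,
                 subtype_calls = calls, prevalence = prev)
  prs_path <- stage_artifact(out, "prs_validation.tsv")
  if (file.exists(prs_path)) {
    report$prs_validation <- utils::read.delim(prs_path)
  }
  pth <- stage_artifact(out, "report.json")
  jsonlite::write_json(report, pth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  summary_path <- stage_artifact(out, "report.txt")
  lines <- c(sprintf("Topics: K = %d", fj$K),
             sprintf("Convergence diagnostic pass: %s", fj$diagnostic_pass),
             sprintf("Candidate CKM subtypes: %s",
                     paste(calls$topic[calls$call == "candidate_CKM"],
                           collapse = ", ") %||% "none"))
  writeLines(lines, summary_path)
  write_manifest(out, "report", cfg,
                 list(stage_artifact(out, "subtype_calls.tsv")),
                 list(report = pth, summary = summary_path))
  invisible(c(report = pth))
}
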