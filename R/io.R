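# Readers and writers for the plain-text interchange formats used by the
# pipeline stages: phenotype CSV, dosage/platform TSV, VCF, bin-spec JSON,
# binned-cohort TSV, and posterior/alignment artifacts.

#' Write and read the phenotype table
#'
#' Phenotype CSV with a header, one row per participant, missing values as
#' empty fields.
#'
#' @param pheno Phenotype tibble.
#' @param path Output file.
#' @export
write_pheno <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, na = "")
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  tibble::as_tibble(read.csv(path, na.strings = ""))
}

#' Write and read dosage / platform tables
#'
#' The dosage table is transposed (variants x participants) TSV with an
#' `id` column of variant ids; platform labels go to a two-column TSV.
#'
#' @param geno A `ckm_genotypes` list.
#' @param dosage_path,platform_path,variants_path Output files.
#' @export
write_genotypes <- function(geno, dosage_path, platform_path = NULL,
                            variants_path = NULL) {
  tab <- data.frame(id = colnames(geno$dosage), t(geno$dosage),
                    check.names = FALSE)
  utils::write.table(tab, dosage_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(platform_path)) {
    utils::write.table(
      data.frame(participant = rownames(geno$dosage) %||%
                   sprintf("P%06d", seq_len(nrow(geno$dosage))),
                 platform = geno$platform),
      platform_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(variants_path)) {
    utils::write.table(geno$variants, variants_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dosage_path)
}

#' @rdname write_genotypes
#' @param path Dosage TSV path.
#' @export
read_dosage <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- tab$id
  storage.mode(m) <- "integer"
  m
}

#' Write genotypes as a minimal unphased-GT VCF
#'
#' @param geno A `ckm_genotypes` list.
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  n <- nrow(geno$dosage)
  ids <- rownames(geno$dosage) %||% sprintf("P%06d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ckmtopics-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    gt <- gt_codes[geno$dosage[, j] + 1L]
    writeLines(paste(c(v$chr[j], v$pos[j], v$id[j], v$nea[j], v$ea[j], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-format VCF into a dosage matrix
#'
#' Counts ALT alleles per unphased genotype. Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @return List: `dosage` (n x m), `variants` tibble.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1))
  }
  dosage <- t(apply(gt, 1, count_alt))
  fix <- vcfR::getFIX(vcf)
  variants <- tibble::tibble(id = fix[, "ID"], chr = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             ea = fix[, "ALT"], nea = fix[, "REF"])
  list(dosage = t(dosage), variants = variants)
}

#' Bin-spec JSON round trip
#' @param spec A `ckm_bin_spec`.
#' @param path JSON path.
#' @export
write_bin_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, digits = NA)
  invisible(path)
}

#' @rdname write_bin_spec
#' @export
read_bin_spec <- function(path) {
  spec <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(spec) <- c("ckm_bin_spec", class(spec))
  spec
}

#' Binned-cohort TSV round trip
#'
#' Integer levels with empty fields for missing entries.
#' @param binned A [binned_cohort].
#' @param path TSV path.
#' @export
write_binned <- function(binned, path) {
  tab <- data.frame(id = binned$ids,
                    sex = binned$sex %||% NA,
                    binned$levels, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_binned
#' @param n_levels Per-feature level counts (default: inferred as max + 1,
#'   with a floor of 5 for ordinary features).
#' @export
read_binned <- function(path, n_levels = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, na.strings = "")
  feats <- setdiff(names(tab), c("id", "sex"))
  lev <- as.matrix(tab[, feats, drop = FALSE])
  if (is.null(n_levels)) {
    n_levels <- pmax(apply(lev, 2, max, na.rm = TRUE) + 1L, 5L)
    n_levels[feats == "bp"] <- 3L
  }
  new_binned_cohort(lev, ids = tab$id, sex = tab$sex, n_levels = n_levels)
}

#' Write GWAS summary statistics
#'
#' TSV with the conventional column set `rsID, CHR, POS, EA, NEA, MAF,
#' BETA, SE, P, LOG10P, N, LEAD`.
#'
#' @param gwas A [run_gwas()] (optionally [clump_leads()]) result.
#' @param path TSV path.
#' @param n Analysis sample size recorded in the `N` column.
#' @export
write_sumstats <- function(gwas, path, n = NA_integer_) {
  out <- data.frame(
    rsID = gwas$id, CHR = gwas$chr, POS = gwas$pos, EA = gwas$ea,
    NEA = gwas$nea, MAF = gwas$maf, BETA = gwas$beta, SE = gwas$se,
    P = gwas$p, LOG10P = -log10(gwas$p), N = n,
    LEAD = if ("lead" %in% names(gwas)) gwas$lead else FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
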