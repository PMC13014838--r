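# ggplot2 helpers for the main result types.

#' Plot pooled topic profiles with credible intervals
#'
#' Bar panels of the per-(feature, level) probabilities of each robust
#' topic, with the pooled 95% credible intervals as error bars — the
#' standard way these mixed-membership profiles are read.
#'
#' @param ensemble A [align_ensemble()] (optionally filtered) result.
#' @param topics Topics to show (default: robust topics).
#' @return A ggplot object.
#' @export
plot_profiles <- function(ensemble, topics = ensemble$robust_topics) {
  d <- dplyr::filter(ensemble$pooled, .data$topic %in% topics)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level),
                                  y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.3) +
    ggplot2::facet_grid(topic ~ feature) +
    ggplot2::labs(x = "level", y = "probability") +
    ggplot2::theme_minimal(base_size = 8)
}

#' @rdname plot_profiles
#' @param object A `ckm_ensemble`.
#' @param ... Passed on.
#' @export
autoplot.ckm_ensemble <- function(object, ...) plot_profiles(object, ...)

#' QQ plot of GWAS p-values
#'
#' Observed versus expected -log10 p under the uniform null, annotated with
#' the genomic inflation factor.
#'
#' @param gwas A [run_gwas()] result.
#' @return A ggplot object.
#' @export
plot_qq <- function(gwas) {
  p <- sort(gwas$p[!is.na(gwas$p)])
  d <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p))
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda[GC] = %.3f", attr(gwas, "lambda"))) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a GWAS table
#'
#' @param gwas A [run_gwas()] result.
#' @param threshold Significance line (default the table's threshold).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(gwas,
                           threshold = attr(gwas, "sig_threshold") %||% 1e-8) {
  d <- dplyr::arrange(tibble::as_tibble(gwas), .data$chr, .data$pos) |>
    dplyr::mutate(index = dplyr::row_number(),
                  logp = -log10(.data$p))
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$logp,
                                  colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "variant", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @param object A `ckm_gwas`.
#' @param type `"qq"` or `"manhattan"`.
#' @param ... Unused.
#' @export
autoplot.ckm_gwas <- function(object, type = c("qq", "manhattan"), ...) {
  type <- match.arg(type)
  if (type == "qq") plot_qq(object) else plot_manhattan(object)
}

#' Plot a K-selection score curve
#'
#' @param selection A [select_K()] result.
#' @return A ggplot object.
#' @export
plot_score_curve <- function(selection) {
  ggplot2::ggplot(selection$curve, ggplot2::aes(.data$K, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = selection$K, linetype = "dashed") +
    ggplot2::labs(y = "held-out per-token log-likelihood") +
    ggplot2::theme_minimal()
}
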