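#' Manhattan-style plot of a genome-wide scan
#'
#' Plots `-log10(p)` against genomic position, faceted or colored by
#' chromosome, with an optional significance line.
#'
#' @param stats Summary-stat tibble (from [run_scan()] or
#'   [meta_analyze()]).
#' @param significance Optional threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_scan <- function(stats, significance = NULL) {
  d <- dplyr::mutate(stats, neglog_p = -log10(pmax(.data$p, 1e-300)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$neglog_p,
                                       color = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = length(unique(d$chrom)) > 1) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(significance)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(significance),
                                 linetype = "dashed")
  }
  p
}

#' Plot stratified phenotype means by genotype and exposure bin
#'
#' Companion display for [stratified_means()]: points with standard-error
#' bars per genotype class, colored by exposure bin. A crossing or fanning
#' pattern across bins is the visual signature of a gene-environment
#' interaction.
#'
#' @param cells Output of [stratified_means()].
#' @return A ggplot object.
#' @export
plot_stratified_means <- function(cells) {
  d <- dplyr::filter(cells, .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$genotype), y = .data$mean,
                                  color = factor(.data$bin),
                                  group = factor(.data$bin))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3),
                       alpha = 0.5) +
    ggplot2::labs(x = "genotype (alt-allele count)", y = "phenotype mean",
                  color = "exposure bin") +
    ggplot2::theme_minimal()
}

#' Loadings plot for an exposure PCA
#'
#' @param x An `exposure_pca`.
#' @param components Two component indices (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposure_pca <- function(x, components = c(1, 2), ...) {
  ld <- tibble::as_tibble(x$loadings[, components, drop = FALSE],
                          rownames = "exposure")
  names(ld)[2:3] <- c("x", "y")
  pct <- 100 * x$sdev^2 / sum(x$sdev^2)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$x, y = .data$y,
                                   label = .data$exposure)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], pct[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2], pct[components[2]])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
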