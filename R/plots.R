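#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of differential-expression results
#'
#' @param object A `deg_results` tibble from [call_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deg_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglogq <- -log10(pmax(df$q, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglogq,
                                   colour = .data$mode)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_threshold"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(activated = "#2166ac",
                                            repressed = "#b2182b",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (mutant / wild type)",
                  y = "-log10 BH q", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of peak genomic contexts
#'
#' @param object Output of [classify_peaks()] or a `regulon_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_peak_context <- function(object, ...) {
  df <- if (inherits(object, "regulon_summary")) {
    object$category_counts
  } else {
    dplyr::count(object, .data$category, name = "n")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = "peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Coverage tracks around a genomic region
#'
#' @param tracks List with `ip` and `input` per-base vectors.
#' @param from,to 1-based region bounds.
#' @param peaks Optional peaks tibble; summits in range are marked.
#' @return A ggplot.
#' @export
plot_coverage <- function(tracks, from, to, peaks = NULL) {
  idx <- from:to
  df <- tibble::tibble(
    position = rep(idx, 2),
    coverage = c(tracks$ip[idx], tracks$input[idx]),
    track = rep(c("IP", "input"), each = length(idx)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$coverage,
                                        colour = .data$track)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(IP = "#b2182b",
                                            input = "grey40")) +
    ggplot2::labs(x = "position (bp)", y = "coverage", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    s <- peaks$summit[peaks$summit + 1 >= from & peaks$summit + 1 <= to]
    if (length(s) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = s + 1, linetype = "dotted",
                                   colour = "#2166ac")
    }
  }
  p
}

#' Sequence-logo style information-content profile of a motif
#'
#' @param consensus Output of [consensus_from_sites()].
#' @return A ggplot of per-column information content (bits).
#' @export
plot_motif_information <- function(consensus) {
  df <- tibble::tibble(
    position = seq_along(consensus$information),
    bits = consensus$information,
    base = strsplit(consensus$consensus, "")[[1]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), vjust = -0.3,
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(x = "motif position", y = "information (bits)") +
    ggplot2::theme_minimal()
}
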