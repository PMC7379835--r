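#' Plot an alignment set
#'
#' Query coverage against identity for a nucleotide alignment tibble, with
#' the mapped threshold drawn as a reference line.
#'
#' @param aln alignment tibble from [align_nt()]
#' @param threshold mapped-coverage threshold
#' @return a ggplot object
#' @export
plot_alignments <- function(aln, threshold = 0.8) {
  d <- dplyr::mutate(aln, coverage = (.data$qend - .data$qstart) / .data$qlen)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coverage, y = .data$identity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "query coverage", y = "alignment identity") +
    ggplot2::theme_minimal()
}

#' Anchor layout along a query
#'
#' Shows anchors as segments over the query axis, one row per edge; useful
#' for eyeballing filtering and chaining decisions.
#'
#' @param anchors anchor tibble
#' @export
plot_anchors <- function(anchors) {
  ggplot2::ggplot(anchors,
                  ggplot2::aes(x = .data$qs, xend = .data$qe,
                               y = .data$edge_name,
                               yend = .data$edge_name)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::labs(x = "query position (bp)", y = "edge") +
    ggplot2::theme_minimal()
}
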