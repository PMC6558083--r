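#' Stacked per-class inbreeding plot for a fitted HBD model
#'
#' One bar per individual, partitioned into the realized inbreeding mass of
#' each HBD class (rate labels double as age labels: rate R corresponds to
#' common ancestors roughly R/2 generations back).
#'
#' @param object An `hbd_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hbd_fit <- function(object, ...) {
  pc <- global_and_class_inbreeding(object)$per_class
  pc$rate <- factor(pc$rate, levels = sort(unique(pc$rate)))
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$individual, y = .data$f,
                                   fill = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "HBD class rate") +
    ggplot2::labs(x = NULL, y = expression(F[G]~"(per-class decomposition)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the ROH length distribution per breed
#'
#' @param dist Output of [roh_length_distribution()].
#' @return A ggplot.
#' @export
plot_roh_length_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$breed, y = .data$proportion,
                                     fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "ROH length (Mb)") +
    ggplot2::labs(x = NULL, y = "Proportion of ROH") +
    ggplot2::theme_minimal()
}

#' Scatter plots between inbreeding metrics
#'
#' @param metrics Tibble with an `individual` column and exactly the metric
#'   columns to compare.
#' @param x,y Column names to plot.
#' @return A ggplot with the fitted least-squares line.
#' @export
plot_metric_scatter <- function(metrics, x, y) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::theme_minimal()
}

#' Plot BAF/LRR evidence for a genomic region
#'
#' The diagnostic view for distinguishing a genuine ROH (LRR centred on 0,
#' BAF at the homozygous poles) from a hemizygous deletion miscalled as ROH
#' (LRR depressed below the -0.3 copy-loss line).
#'
#' @param intensity Intensity tibble.
#' @param map Marker map.
#' @param individual Individual id.
#' @param chrom,start,end Region (0-based half-open).
#' @param lrr_threshold Reference line (default -0.3).
#' @return A ggplot with LRR and BAF panels.
#' @export
plot_region_evidence <- function(intensity, map, individual, chrom, start,
                                 end, lrr_threshold = -0.3) {
  mk <- map[map$chrom == chrom & map$bp - 1 >= start & map$bp - 1 < end, ]
  sub <- intensity[intensity$individual == individual &
                   intensity$marker %in% mk$marker, ]
  sub$bp <- mk$bp[match(sub$marker, mk$marker)]
  long <- tidyr::pivot_longer(sub, c("lrr", "baf"), names_to = "signal")
  ref <- tibble(signal = c("lrr", "baf"), y = c(lrr_threshold, NA))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bp / 1e6, y = .data$value)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(data = ref[!is.na(ref$y), ],
                        ggplot2::aes(yintercept = .data$y),
                        colour = "blue", linetype = 2) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
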