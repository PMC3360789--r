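# ggplot2 views of the main result types.

#' Plot an A/B/H genotype matrix as a tile map
#'
#' @param object An `abh_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.abh_matrix <- function(object, ...) {
  df <- abh_long(object)
  df$sample_id <- factor(df$sample_id, levels = abh_samples(object))
  df$snp_id <- factor(df$snp_id, levels = object$snp_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$snp_id,
                                   fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(A = "#d95f02", B = "#1b9e77", H = "#7570b3"),
      na.value = "grey85", name = "genotype") +
    ggplot2::labs(x = "sample", y = "SNP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a linkage map (marker positions per group, colored by stability)
#'
#' @param object An `sbg_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sbg_map <- function(object, ...) {
  df <- object$markers
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$position,
                                   colour = .data$stability)) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "linkage group", y = "position (cM)",
                  colour = "stability") +
    ggplot2::theme_minimal()
}

#' Plot demultiplexing accounting: reads per sample and rejection reasons
#'
#' @param object A `demux_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.demux_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$per_sample, panel = "assigned per sample",
                  key = .data$sample_id),
    dplyr::mutate(object$rejected, panel = "rejected by reason",
                  key = .data$reason))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5))
}
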