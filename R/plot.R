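.config_palette <- c(AABB = "grey85", AAAA = "#D55E00", BBBB = "#0072B2")

#' Chromosome-paint plot of genome configurations
#'
#' Draws one horizontal track per chromosome pair per sample, with each
#' diagnostic locus colored by its genome configuration (balanced `AABB`
#' neutral grey, `AAAA` and `BBBB` in contrasting colors, unresolved loci
#' left blank) on a bp-proportional x-axis, reproducing the mosaic view of a
#' converted genome. Block segments, when supplied, are outlined.
#'
#' @param config Wide configuration tibble from [classify_configurations()].
#' @param markers Marker map of the diagnostic loci.
#' @param segments Optional segment tibble from [segment_all()]; `BLOCK`
#'   rows are outlined.
#' @param samples Optional character vector restricting/ordering the samples
#'   shown (default: all, in column order).
#' @return A `ggplot` object (one facet row per sample); `NULL` with a
#'   warning when the matrix has no samples or loci.
#' @export
plot_chromosome_paint <- function(config, markers, segments = NULL,
                                  samples = NULL) {
  cols <- .sample_cols(config)
  if (is.null(samples)) samples <- cols
  samples <- intersect(samples, cols)
  if (length(samples) == 0L || nrow(config) == 0L) {
    warn("empty configuration matrix: nothing to paint")
    return(invisible(NULL))
  }
  mk <- markers[match(config$marker_id, markers$marker_id), ]
  long <- config[c("marker_id", samples)] %>%
    tidyr::pivot_longer(-"marker_id", names_to = "sample_id",
                        values_to = "config") %>%
    dplyr::left_join(mk[c("marker_id", "pair_index", "pos_bp")], by = "marker_id") %>%
    dplyr::filter(!is.na(.data$config)) %>%
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = samples))
  p <- ggplot2::ggplot(long) +
    ggplot2::geom_tile(
      ggplot2::aes(x = .data$pos_bp, y = factor(.data$pair_index),
                   fill = .data$config),
      height = 0.75) +
    ggplot2::scale_fill_manual(values = .config_palette, name = "configuration") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$sample_id)) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f Mb", x / 1e6)) +
    ggplot2::labs(x = "position on B pseudomolecule", y = "chromosome pair") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    blocks <- segments %>%
      dplyr::filter(.data$kind == "BLOCK",
                    .data$sample_id %in% .env$samples) %>%
      dplyr::mutate(sample_id = factor(.data$sample_id, levels = samples))
    if (nrow(blocks) > 0) {
      p <- p + ggplot2::geom_rect(
        data = blocks,
        ggplot2::aes(xmin = .data$start_bp, xmax = .data$end_bp,
                     ymin = as.integer(factor(.data$pair_index,
                                              levels = sort(unique(long$pair_index)))) - 0.45,
                     ymax = as.integer(factor(.data$pair_index,
                                              levels = sort(unique(long$pair_index)))) + 0.45),
        fill = NA, color = "black", linewidth = 0.3)
    }
  }
  p
}

#' Plot the generational accumulation trend
#'
#' Scatter of per-sample detected exchange rates against selfing generation
#' with the fitted Theil-Sen line.
#'
#' @param x An `he_trend` object from [generation_trend()].
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot he_trend
#' @export
autoplot.he_trend <- function(x, ...) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$generation, y = .data$he_rate_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         color = "#D55E00") +
    ggplot2::labs(
      x = "selfing generation",
      y = "detected homoeologous-exchange rate (%)",
      subtitle = sprintf("Spearman rho = %.2f, permutation p = %.3g",
                         x$rho, x$p_perm)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.he_trend
#' @param trend An `he_trend` object.
#' @export
plot_generation_trend <- function(trend) autoplot(trend)
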