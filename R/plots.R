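#' @export
autoplot.vcf_summary <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::count(.data$class, wt = .data$count, name = "count")
  df$class <- factor(df$class, levels = variant_classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Distribution of variant types",
                  subtitle = object$source_name) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.indel_dist <- function(object, max_abs_size = 50, ...) {
  df <- object$sizes
  df <- df[abs(df$size) <= max_abs_size, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$count)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "INDEL size (bp; deletions negative)", y = "count",
                  title = "INDEL size distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vcf_cmp <- function(object, ...) {
  ggplot2::ggplot(object$venn,
                  ggplot2::aes(x = .data$set, y = .data$count)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "variants", title = "Variant set overlap") +
    ggplot2::theme_minimal()
}

#' Plot windowed variant density
#'
#' Bar chart of variant counts per fixed-size genomic window, faceted by
#' contig — the static counterpart of an interactive density histogram.
#' Highly polymorphic windows and variant-free gaps stand out directly.
#'
#' @param density A tibble from [window_density()].
#' @param contig Optional single contig to restrict to.
#' @return A ggplot object.
#' @export
plot_window_density <- function(density, contig = NULL) {
  if (!is.null(contig)) {
    density <- density[density$contig %in% contig, , drop = FALSE]
  }
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$start, y = .data$count)) +
    ggplot2::geom_col(width = density$end - density$start + 1,
                      just = 0, fill = "#e6550d") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "variants / window",
                  title = "Variant density") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
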