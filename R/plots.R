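#' Plot a unigene accumulation curve
#'
#' Mean detected unigenes against reads sampled, with the percentile
#' confidence ribbon and dashed milestone markers.
#'
#' @param object An [accumulation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  cv <- object$curve
  ms <- object$milestones
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$draw, y = .data$mean_detected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(data = ms[!is.na(ms$draw), ],
                        ggplot2::aes(xintercept = .data$draw),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Reads sampled", y = "Unigenes detected",
                  title = sprintf("Unigene accumulation (%d replicates)",
                                  object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Length-distribution histogram for a sequence set
#'
#' @param x Sequences (data frame, character vector) or numeric lengths.
#' @param bin_width Bin width in bp.
#' @param clip Optional pooling range, see [bin_histogram()].
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(x, bin_width = 50, clip = NULL) {
  lengths <- if (is.data.frame(x)) nchar(x$sequence)
             else if (is.character(x)) nchar(x) else as.numeric(x)
  h <- bin_histogram(lengths, bin_width, clip)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.95, fill = "steelblue",
                      just = 0) +
    ggplot2::labs(x = "Length (bp)", y = "Sequences") +
    ggplot2::theme_minimal()
}

#' Plot GO-slim enrichment results
#'
#' Bars of -log10 FDR-adjusted p for the most significant terms, coloured
#' by direction.
#'
#' @param object An [enrichment()] result.
#' @param n_terms Number of top terms to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, n_terms = 20, ...) {
  df <- as_tibble(object) |>
    arrange(.data$q) |>
    head(n_terms) |>
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$q, 1e-300)),
                                   y = .data$term_id,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "FDR q"), y = NULL,
                  fill = "Direction") +
    ggplot2::theme_minimal()
}
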