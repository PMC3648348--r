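#' Plot an insert-size distribution
#' @param stats An `insert_stats` object.
#' @return A ggplot.
#' @export
plot_insert_distribution <- function(stats) {
  h <- stats$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_end - h$bin_start, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = stats$median, linetype = 2) +
    ggplot2::labs(x = "insert size (bp)", y = "pairs",
                  title = sprintf("median %s bp",
                                  format(round(stats$median), big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot complexity_curve
#' @export
autoplot.complexity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sampled_pairs,
                                       y = .data$unique_nonclonal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "sampled pairs", y = "unique non-clonal pairs") +
    ggplot2::theme_minimal()
}

#' Plot repeat-bridging profiles
#'
#' Fraction of repeat elements bridged versus element size (binned), one
#' panel per repeat class; colour distinguishes libraries when profiles
#' from several libraries are row-bound.
#'
#' @param profile A `bridging_profile` (optionally with a `library` column).
#' @return A ggplot.
#' @export
plot_bridging_profile <- function(profile) {
  aes <- if ("library" %in% names(profile)) {
    ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                 y = .data$fraction, colour = .data$library)
  } else {
    ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                 y = .data$fraction)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) {
      paste0(100 * x, "%")
    }) +
    ggplot2::labs(x = "element size (bp)", y = "elements bridged") +
    ggplot2::theme_minimal()
}

#' Plot a combination sweep (N50 versus scaffold count)
#' @param sweep Output of [combination_sweep()].
#' @return A ggplot.
#' @export
plot_scaffold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_scaffolds, y = .data$n50,
                                      label = .data$combination)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_libraries))) +
    ggplot2::geom_text(size = 2.5, vjust = -0.8, check_overlap = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of scaffolds", y = "scaffold N50 (bp)",
                  colour = "libraries") +
    ggplot2::theme_minimal()
}

#' @method autoplot restriction_map
#' @export
autoplot.restriction_map <- function(object, ...) {
  pos <- cumsum(c(0, object$length))
  df <- tibble::tibble(start = utils::head(pos, -1), end = pos[-1])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = 1, yend = 1), linewidth = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$end, y = 1), shape = "|",
                        size = 6, colour = "red") +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%d fragments, %s bp", nrow(object),
                                  format(sum(object$length), big.mark = ",")))
}
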