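#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for matescaffold result objects
#'
#' Broom-style methods: `tidy()` returns the per-element table of a result
#' (alignment blocks, per-window counts, saturation-fit terms); `glance()`
#' returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name matescaffold-tidiers
NULL

#' @rdname matescaffold-tidiers
#' @method glance insert_stats
#' @export
glance.insert_stats <- function(x, ...) {
  tibble::tibble(median = x$median, p1 = x$p1, p99 = x$p99, n = x$n)
}

#' @rdname matescaffold-tidiers
#' @method tidy complexity_fit
#' @export
tidy.complexity_fit <- function(x, ...) {
  tibble::tibble(term = "C", estimate = x$C_fit,
                 lower_bound = x$lower_bound)
}

#' @rdname matescaffold-tidiers
#' @method glance complexity_fit
#' @export
glance.complexity_fit <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, lower_bound = x$lower_bound,
                 C_fit = x$C_fit, max_observed = x$max_observed)
}

#' @rdname matescaffold-tidiers
#' @method tidy map_alignment
#' @export
tidy.map_alignment <- function(x, ...) x$blocks

#' @rdname matescaffold-tidiers
#' @method glance map_alignment
#' @export
glance.map_alignment <- function(x, ...) {
  tibble::tibble(score = x$score,
                 concordant_fraction = x$concordant_fraction,
                 n_blocks = nrow(x$blocks), n_a = x$n_a, n_b = x$n_b)
}

#' @rdname matescaffold-tidiers
#' @method tidy window_report
#' @export
tidy.window_report <- function(x, ...) x$windows

#' @rdname matescaffold-tidiers
#' @method glance window_report
#' @export
glance.window_report <- function(x, ...) x$totals
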