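#' Estimate the insert-size distribution of a library
#'
#' Uses only non-clonal pairs with uniquely mapped tags in facing-in
#' orientation on the same chromosome with an outer span below
#' `max_span` (100 kb), mirroring single-best-hit proper-pair filtering.
#'
#' @param pairs A pair tibble; a missing `clonal` column is computed.
#' @param max_span Upper span limit (bp) for qualifying pairs.
#' @param bins Number of histogram bins.
#' @return An `insert_stats` object: `median`, `p1`, `p99` (1st/99th
#'   percentiles), `n`, and a `histogram` tibble (`bin_start`, `bin_end`,
#'   `count`).
#' @export
estimate_insert_distribution <- function(pairs, max_span = 1e5, bins = 50) {
  if (!"clonal" %in% names(pairs)) pairs <- mark_duplicates(pairs)
  uq <- col_or(pairs, "fwd_unique", TRUE) & col_or(pairs, "rev_unique", TRUE)
  fwd_left <- pairs$fwd_pos <= pairs$rev_pos
  s_left <- ifelse(fwd_left, pairs$fwd_strand, pairs$rev_strand)
  s_right <- ifelse(fwd_left, pairs$rev_strand, pairs$fwd_strand)
  span <- pair_span(pairs)
  ok <- !pairs$clonal & uq & !is.na(span) & span < max_span &
    s_left == "+" & s_right == "-"
  spans <- span[ok]
  if (length(spans) < 100) {
    stop(sprintf("only %d qualifying pairs (>= 100 needed) for insert estimation",
                 length(spans)), call. = FALSE)
  }
  q <- stats::quantile(spans, c(0.01, 0.5, 0.99), names = FALSE)
  brk <- seq(min(spans), max(spans), length.out = bins + 1)
  if (min(spans) == max(spans)) brk <- c(min(spans) - 0.5, max(spans) + 0.5)
  h <- graphics::hist(spans, breaks = brk, plot = FALSE)
  structure(list(median = q[2], p1 = q[1], p99 = q[3], n = length(spans),
                 histogram = tibble::tibble(bin_start = utils::head(h$breaks, -1),
                                            bin_end = h$breaks[-1],
                                            count = h$counts)),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf("<insert_stats> median %s bp [p1 %s, p99 %s], n = %s pairs\n",
              format(x$median, big.mark = ","), format(x$p1, big.mark = ","),
              format(x$p99, big.mark = ","), format(x$n, big.mark = ",")))
  invisible(x)
}

#' Insert bounds (1st-99th percentile) from fitted insert stats
#' @param stats An `insert_stats` object.
#' @return Numeric length-2 vector `(p1, p99)`.
#' @export
insert_bounds <- function(stats) c(stats$p1, stats$p99)

#' Library complexity (saturation) curve
#'
#' Random subsamples of increasing size are drawn from the library and the
#' number of distinct (non-clonal) coordinate signatures is counted,
#' producing the unique-pairs-versus-sequenced-pairs saturation curve. A
#' plateau indicates the library has been sequenced to saturation.
#'
#' @param pairs A pair tibble.
#' @param grid Ascending sample sizes; defaults to 10 evenly spaced points
#'   up to the library size.
#' @param replicates Subsample replicates per grid point (mean and
#'   Monte-Carlo SE are reported).
#' @param seed Optional integer seed.
#' @return A `complexity_curve` tibble: `sampled_pairs`,
#'   `unique_nonclonal`, `se`.
#' @export
complexity_curve <- function(pairs, grid = NULL, replicates = 3, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      complexity_curve(pairs, grid, replicates, NULL)))
  }
  n <- nrow(pairs)
  grid <- grid %||% unique(round(seq(n / 10, n, length.out = 10)))
  grid <- as.integer(grid)
  if (is.unsorted(grid, strictly = FALSE) || max(grid) > n || min(grid) < 1) {
    stop("grid must be ascending sample sizes within the library size",
         call. = FALSE)
  }
  sig <- pair_signature(pairs)
  reps <- vapply(seq_len(replicates), function(i) {
    cum_unique <- cumsum(!duplicated(sig[sample.int(n)]))
    cum_unique[grid]
  }, numeric(length(grid)))
  reps <- matrix(reps, nrow = length(grid))
  out <- tibble::tibble(
    sampled_pairs = grid,
    unique_nonclonal = rowMeans(reps),
    se = apply(reps, 1, stats::sd) / sqrt(replicates))
  class(out) <- c("complexity_curve", class(out))
  out
}

#' Estimate the maximum number of unique molecules in a library
#'
#' Fits the saturation model `unique(n) = C * (1 - exp(-n/C))` (random
#' sampling from `C` equally likely distinct molecules) to a complexity
#' curve by least squares. If the curve has reached at least 90% of the
#' fitted plateau, `C` is reported as the library complexity; otherwise the
#' library is not saturated and the observed unique count is returned as a
#' lower bound (the ">x" style of reporting).
#'
#' @param curve A `complexity_curve` (>= 3 grid points).
#' @return A `complexity_fit`: `estimate`, `lower_bound` (logical), `C_fit`,
#'   `max_observed`, plus the input curve. Supports [tidy()] and [glance()].
#' @export
estimate_max_unique <- function(curve) {
  if (nrow(curve) < 3) {
    stop("at least 3 grid points are needed to fit the saturation curve",
         call. = FALSE)
  }
  u <- curve$unique_nonclonal
  n <- curve$sampled_pairs
  if (any(diff(diff(u)) > pmax(6 * utils::tail(curve$se, -2), 0.005 * max(u)))) {
    warning("complexity curve is not concave (sampling noise?); fitting anyway",
            call. = FALSE)
  }
  umax <- max(u)
  ss <- function(logC) {
    C <- exp(logC)
    sum((u - C * (1 - exp(-n / C)))^2)
  }
  opt <- stats::optimize(ss, interval = c(log(umax * 0.8), log(umax * 1e3)))
  C <- exp(opt$minimum)
  saturated <- umax >= 0.9 * C
  structure(list(estimate = if (saturated) C else umax,
                 lower_bound = !saturated, C_fit = C, max_observed = umax,
                 curve = curve),
            class = "complexity_fit")
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat(sprintf("<complexity_fit> %s%s unique molecules (fit C = %s)\n",
              if (x$lower_bound) "> " else "~",
              format(round(x$estimate), big.mark = ","),
              format(round(x$C_fit), big.mark = ",")))
  invisible(x)
}

#' Physical coverage represented by qualifying read pairs
#'
#' Sums the outer spans of non-clonal, uniquely mapped, consistent pairs
#' whose span lies within the library's 1st-99th insert percentiles, and
#' divides by the genome length (clone-coverage arithmetic).
#'
#' @param pairs A classified pair tibble (see [classify_pairs()]).
#' @param genome_length Genome length in bp (> 0).
#' @param insert_stats Optional `insert_stats` for percentile trimming; if
#'   `NULL`, no trimming is applied.
#' @return One-row tibble: `physical_coverage`, `pairs_used`,
#'   `genome_length`.
#' @export
physical_coverage <- function(pairs, genome_length, insert_stats = NULL) {
  if (genome_length <= 0) stop("genome_length must be > 0", call. = FALSE)
  q <- qualifying_pairs(pairs, insert_stats)
  tibble::tibble(physical_coverage = sum(q$span) / genome_length,
                 pairs_used = nrow(q),
                 genome_length = genome_length)
}

qualifying_pairs <- function(pairs, insert_stats = NULL) {
  assert_cols(pairs, c("class", "span"))
  q <- dplyr::filter(pairs, .data$class == "consistent")
  if (!is.null(insert_stats)) {
    q <- dplyr::filter(q, .data$span >= insert_stats$p1,
                       .data$span <= insert_stats$p99)
  }
  q
}

#' Expected physical coverage from pair count and nominal insert size
#'
#' Closed form `n_pairs * nominal_insert / effective_genome`; no data
#' needed. The default effective genome length (2.47 Gb) is the mappable
#' chromosome span of the rat reference; the full assembly is 2.51 Gb
#' ([rat_genome_bp]) -- both constants are exported.
#'
#' @param n_pairs Number of read pairs.
#' @param nominal_insert Nominal insert size in bp.
#' @param effective_genome Effective genome length in bp.
#' @return Expected x-fold physical coverage (vectorized).
#' @export
expected_coverage <- function(n_pairs, nominal_insert,
                              effective_genome = rat_effective_genome_bp) {
  stopifnot(all(n_pairs > 0), all(nominal_insert > 0),
            all(effective_genome > 0))
  n_pairs * nominal_insert / effective_genome
}

#' Subsample a library to a target physical coverage
#'
#' Randomly draws qualifying pairs (the [physical_coverage()] filter) until
#' the cumulative span first reaches `target` x-fold coverage -- the
#' coverage-normalization step that makes libraries of different insert
#' sizes comparable (e.g. all at 8.5x).
#'
#' @param pairs Classified pair tibble.
#' @param genome_length Genome length in bp.
#' @param target Target x-fold physical coverage.
#' @param insert_stats Optional `insert_stats` for percentile trimming.
#' @param seed Optional integer seed.
#' @return The subsampled pair tibble (qualifying pairs only), in
#'   `pair_id` order.
#' @export
normalize_to_coverage <- function(pairs, genome_length, target,
                                  insert_stats = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      normalize_to_coverage(pairs, genome_length, target, insert_stats, NULL)))
  }
  q <- qualifying_pairs(pairs, insert_stats)
  full <- sum(q$span) / genome_length
  if (full < target) {
    stop(sprintf("insufficient data: attainable coverage is %.3fx (target %.3fx)",
                 full, target), call. = FALSE)
  }
  perm <- sample.int(nrow(q))
  k <- which(cumsum(q$span[perm]) / genome_length >= target)[1]
  dplyr::arrange(q[sort(perm[seq_len(k)]), ], .data$pair_id)
}

#' One-row QC summary for a library
#'
#' @param pairs Classified pair tibble for one library.
#' @param genome_length Genome length in bp.
#' @param insert_stats Optional precomputed `insert_stats`.
#' @return One-row tibble: library, pair counts, non-duplicate fraction,
#'   unique-consistent fraction (of non-clonal pairs), insert median and
#'   percentiles, physical coverage.
#' @export
qc_summary <- function(pairs, genome_length, insert_stats = NULL) {
  assert_cols(pairs, c("class", "span"))
  insert_stats <- insert_stats %||% estimate_insert_distribution(pairs)
  nonclonal <- sum(pairs$class != "clonal")
  cov <- physical_coverage(pairs, genome_length, insert_stats)
  tibble::tibble(
    library = col_or(pairs, "library", NA_character_)[1],
    n_pairs = nrow(pairs),
    nonduplicate_fraction = nonclonal / nrow(pairs),
    consistent_fraction = sum(pairs$class == "consistent") / nonclonal,
    insert_median = insert_stats$median,
    insert_p1 = insert_stats$p1,
    insert_p99 = insert_stats$p99,
    physical_coverage = cov$physical_coverage,
    pairs_used = cov$pairs_used)
}

#' Write a per-library QC report (JSON + TSV)
#'
#' @param summary One-row tibble from [qc_summary()].
#' @param curve Optional `complexity_curve`.
#' @param path_prefix Output prefix; writes `<prefix>.json` and
#'   `<prefix>.tsv` (plus `<prefix>_complexity.tsv` when a curve is given).
#' @export
write_qc_report <- function(summary, curve = NULL, path_prefix) {
  readr::write_tsv(summary, paste0(path_prefix, ".tsv"))
  payload <- as.list(summary)
  if (!is.null(curve)) {
    payload$complexity <- curve
    readr::write_tsv(curve, paste0(path_prefix, "_complexity.tsv"))
  }
  jsonlite::write_json(payload, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
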