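# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Truncated-normal sampler via inverse CDF; sd = 0 degenerates to the mean.
rtrunc_normal <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Lognormal parameterized by median and an absolute spread (bp); sdlog = spread/median.
rtrunc_lognormal <- function(n, median, spread, lo, hi) {
  sdlog <- spread / median
  if (sdlog <= 0) return(rep(median, n))
  meanlog <- log(median)
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# Mean of a normal truncated to [lo, hi] (closed form).
tnorm_mean <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(mean)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Coordinate signature of a pair; identical signatures define clonal copies.
pair_signature <- function(pairs) {
  paste(pairs$fwd_chrom, pairs$fwd_pos, pairs$fwd_strand,
        pairs$rev_chrom, pairs$rev_pos, pairs$rev_strand, sep = "\r")
}

# Outer span of a pair (0-based, half-open tags): rightmost tag end - leftmost start.
# NA across chromosomes.
pair_span <- function(pairs) {
  ifelse(pairs$fwd_chrom == pairs$rev_chrom,
         pmax(pairs$fwd_pos, pairs$rev_pos) + pairs$read_len -
           pmin(pairs$fwd_pos, pairs$rev_pos),
         NA_real_)
}

# Column accessor with default for optional columns (avoids tibble's
# unknown-column warning).
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}
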