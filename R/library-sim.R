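#' Parameters of one paired-read library
#'
#' Encodes a paired-end or mate-pair library: insert-size distribution,
#' number of pairs, tag length, and the artifact rates the simulator plants
#' (clonal duplicates, remote/chimeric pairs, inverted and everted pairs).
#' Tag orientation is normalized to forward/reverse facing-in for both PE
#' and MP libraries, so one consistency rule serves both.
#'
#' @param name Library name (e.g. `"8kb"`).
#' @param insert_median Median insert size in bp (>= `2 * read_length`).
#' @param insert_spread Scale of the insert distribution in bp (sd for
#'   `"normal"`; `spread/median` is the sdlog for `"lognormal"`). 0 gives a
#'   fixed insert size.
#' @param n_pairs Number of read pairs to emit.
#' @param read_length Tag length in bp.
#' @param distribution_shape `"normal"` (truncated to
#'   `[2*read_length, 1e5]`) or `"lognormal"`.
#' @param duplicate_fraction,remote_fraction,inverted_fraction,everted_fraction
#'   Expected fractions of clonal duplicates, remotely mapped (chimeric)
#'   pairs, single-tag-flipped and both-tags-flipped pairs. Must sum to < 1.
#' @param seed Optional integer seed stored with the spec and used by
#'   [simulate_library()] when no explicit seed is given.
#' @return A `library_spec` object.
#' @export
library_spec <- function(name, insert_median, insert_spread, n_pairs,
                         read_length = 50L,
                         distribution_shape = c("normal", "lognormal"),
                         duplicate_fraction = 0, remote_fraction = 0,
                         inverted_fraction = 0, everted_fraction = 0,
                         seed = NULL) {
  distribution_shape <- match.arg(distribution_shape)
  fr <- c(duplicate_fraction, remote_fraction, inverted_fraction,
          everted_fraction)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1) {
    stop("artifact fractions must lie in [0, 1) and sum to < 1", call. = FALSE)
  }
  if (insert_median < 2 * read_length) {
    stop("insert_median must be at least 2 * read_length", call. = FALSE)
  }
  structure(list(name = name, insert_median = insert_median,
                 insert_spread = insert_spread,
                 distribution_shape = distribution_shape,
                 n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 duplicate_fraction = duplicate_fraction,
                 remote_fraction = remote_fraction,
                 inverted_fraction = inverted_fraction,
                 everted_fraction = everted_fraction,
                 seed = seed),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(paste0("<library_spec> %s: insert %s +/- %s bp (%s), %s pairs, ",
                     "tags %d bp\n  duplicates %.1f%%, remote %.1f%%, ",
                     "inverted %.2f%%, everted %.2f%%\n"),
              x$name, format(x$insert_median, big.mark = ","),
              format(x$insert_spread, big.mark = ","), x$distribution_shape,
              format(x$n_pairs, big.mark = ","), x$read_length,
              100 * x$duplicate_fraction, 100 * x$remote_fraction,
              100 * x$inverted_fraction, 100 * x$everted_fraction))
  invisible(x)
}

#' Paper-profile parameters for the seven library insert sizes
#'
#' The seven-library design: one paired-end library (170 bp median insert)
#' and six mate-pair libraries (3/5/8/15/20/25 kb). Duplication levels span
#' the observed range of non-duplicate fractions (95% for PE down to 4-5%
#' for the most saturated large-insert libraries), remote pairs ~10%, and
#' inverted/everted pairs < 1% combined. Insert spreads are set to ~10% of
#' the median (the study reports only medians and distribution shapes).
#'
#' @param error_free If `TRUE`, zero all artifact fractions (duplicates,
#'   remote, inverted, everted) while keeping the insert-size design --
#'   useful for scaffolding experiments with error-free links.
#' @return A tibble with one row per library; rows can be passed to
#'   [library_spec()] via [purrr::pmap()] after adding `n_pairs`.
#' @export
paper_library_profiles <- function(error_free = FALSE) {
  prof <- tibble::tibble(
    name = c("PE", "3kb", "5kb", "8kb", "15kb", "20kb", "25kb"),
    insert_median = c(170, 3000, 5000, 8000, 15000, 20000, 25000),
    insert_spread = c(30, 300, 500, 800, 1500, 2000, 2500),
    read_length = 50L,
    duplicate_fraction = c(0.05, 0.08, 0.12, 0.05, 0.95, 0.49, 0.96),
    remote_fraction = 0.10,
    inverted_fraction = 0.005,
    everted_fraction = 0.004)
  if (error_free) {
    prof$duplicate_fraction <- 0
    prof$remote_fraction <- 0
    prof$inverted_fraction <- 0
    prof$everted_fraction <- 0
  }
  prof
}

#' Simulate a mapped paired-read library over a genome
#'
#' Emits `spec$n_pairs` read pairs with mapped coordinates (no base-level
#' sequences): consistent pairs have facing-in tags separated by an insert
#' drawn from the configured distribution; duplicates are exact coordinate
#' clones of previously emitted pairs (PCR model); remote pairs have one tag
#' repositioned uniformly at least 100 kb away; inverted pairs have one tag
#' strand flipped; everted pairs have both flipped (wrong tag order). Each
#' tag's uniqueness flag is `FALSE` iff the tag lies entirely within a
#' repeat copy whose family has >= 2 copies and whose divergence amounts to
#' less than one mismatch over the tag.
#'
#' @param genome A `genome_model`.
#' @param spec A [library_spec()].
#' @param seed Optional integer seed (defaults to `spec$seed`).
#' @return A pair tibble: `pair_id`, `library`, `fwd_chrom`, `fwd_pos`,
#'   `fwd_strand`, `rev_chrom`, `rev_pos`, `rev_strand` (0-based leftmost
#'   tag coordinates), `read_len`, `truth_category`, `duplicate_of`,
#'   `fwd_unique`, `rev_unique`.
#' @export
simulate_library <- function(genome, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "library_spec"))
  if (!is.null(seed)) {
    sp <- spec; sp$seed <- NULL
    return(withr::with_seed(as.integer(seed), simulate_library(genome, sp)))
  }
  G <- genome$length
  n <- spec$n_pairs
  r <- spec$read_length
  if (spec$remote_fraction > 0 && G < 2e5 + r) {
    stop("remote pairs need a genome of at least 200 kb", call. = FALSE)
  }

  probs <- c(duplicate = spec$duplicate_fraction,
             remote = spec$remote_fraction,
             inverted = spec$inverted_fraction,
             everted = spec$everted_fraction)
  probs <- c(probs, consistent = 1 - sum(probs))
  cat_ <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (cat_[1] == "duplicate") cat_[1] <- "consistent"  # nothing emitted yet

  mol <- which(cat_ != "duplicate")
  m <- length(mol)
  span <- draw_insert_sizes(m, spec)
  span <- pmin(span, G)  # safety on tiny genomes
  left <- floor(stats::runif(m) * (G - span + 1))
  right <- left + span - r

  fwd_pos <- left
  rev_pos <- right
  fwd_strand <- rep("+", m)
  rev_strand <- rep("-", m)
  mcat <- cat_[mol]

  inv <- which(mcat == "inverted")
  if (length(inv)) {
    flip_fwd <- stats::runif(length(inv)) < 0.5
    fwd_strand[inv[flip_fwd]] <- "-"
    rev_strand[inv[!flip_fwd]] <- "+"
  }
  ev <- which(mcat == "everted")
  if (length(ev)) {
    fwd_strand[ev] <- "-"
    rev_strand[ev] <- "+"
  }
  rem <- which(mcat == "remote")
  if (length(rem)) {
    p <- floor(stats::runif(length(rem)) * (G - r + 1))
    for (it in 1:100) {
      bad <- abs(p - fwd_pos[rem]) < 1e5
      if (!any(bad)) break
      p[bad] <- floor(stats::runif(sum(bad)) * (G - r + 1))
    }
    rev_pos[rem] <- p
    # keep facing-in orientation with respect to genomic order
    swap <- p < fwd_pos[rem]
    fwd_strand[rem] <- ifelse(swap, "-", "+")
    rev_strand[rem] <- ifelse(swap, "+", "-")
  }

  pairs <- tibble::tibble(
    pair_id = seq_len(n), library = spec$name,
    fwd_chrom = "chr1", fwd_pos = NA_real_, fwd_strand = NA_character_,
    rev_chrom = "chr1", rev_pos = NA_real_, rev_strand = NA_character_,
    read_len = r,
    truth_category = cat_, duplicate_of = NA_integer_)
  pairs$fwd_pos[mol] <- fwd_pos
  pairs$fwd_strand[mol] <- fwd_strand
  pairs$rev_pos[mol] <- rev_pos
  pairs$rev_strand[mol] <- rev_strand

  dup <- which(cat_ == "duplicate")
  if (length(dup)) {
    src <- mol[sample.int(m, length(dup), replace = TRUE)]
    pairs$fwd_pos[dup] <- pairs$fwd_pos[src]
    pairs$fwd_strand[dup] <- pairs$fwd_strand[src]
    pairs$rev_pos[dup] <- pairs$rev_pos[src]
    pairs$rev_strand[dup] <- pairs$rev_strand[src]
    pairs$duplicate_of[dup] <- src
  }

  amb <- ambiguous_ranges(genome$repeats, r)
  pairs$fwd_unique <- tag_is_unique(pairs$fwd_pos, r, amb)
  pairs$rev_unique <- tag_is_unique(pairs$rev_pos, r, amb)
  pairs
}

draw_insert_sizes <- function(n, spec) {
  lo <- 2 * spec$read_length
  hi <- 1e5
  x <- switch(spec$distribution_shape,
              normal = rtrunc_normal(n, spec$insert_median, spec$insert_spread,
                                     lo, hi),
              lognormal = rtrunc_lognormal(n, spec$insert_median,
                                           spec$insert_spread, lo, hi))
  pmax(round(x), lo)
}

# Repeat copies a single-best-hit mapper cannot resolve: family has >= 2
# copies and per-copy divergence is under one mismatch-equivalent per tag.
ambiguous_ranges <- function(repeats, read_len) {
  if (is.null(repeats) || nrow(repeats) == 0) return(IRanges::IRanges())
  div <- if ("divergence" %in% names(repeats)) repeats$divergence else 0
  fam <- if ("family_size" %in% names(repeats)) repeats$family_size else 1L
  amb <- fam >= 2 & div * read_len < 1
  IRanges::IRanges(start = repeats$start[amb] + 1, end = repeats$end[amb])
}

tag_is_unique <- function(pos, read_len, amb) {
  if (length(amb) == 0) return(rep(TRUE, length(pos)))
  tags <- IRanges::IRanges(start = pos + 1, width = read_len)
  !IRanges::overlapsAny(tags, amb, type = "within")
}
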