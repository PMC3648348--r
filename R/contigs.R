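#' Fragment a genome into an assembly-like contig layout
#'
#' Splits the genome into `n_contigs` contigs separated by gaps (truth layout
#' for scaffolding experiments). Gap sizes are exponential with the requested
#' mean; contig sizes are a gamma-weighted partition of the remaining
#' sequence with a minimum contig size, so contig bp + gap bp equals the
#' genome length exactly.
#'
#' @param genome A `genome_model` or a numeric genome length (bp).
#' @param n_contigs Number of contigs (>= 1).
#' @param gap_model List with `mean_gap` (bp), the mean inter-contig gap.
#' @param seed Optional integer seed (same seed, identical layout).
#' @param min_contig Minimum contig length (bp).
#' @param size_shape Gamma shape for contig-size variability (larger = more
#'   even contigs).
#' @return A `contig_layout` tibble: `contig_id`, `chrom`, `start`, `end`
#'   (0-based half-open genome coordinates), `length`, `orientation`, `rank`
#'   (truth order), `gap_after` (bp to next contig; `NA` for the last).
#' @export
fragment_into_contigs <- function(genome, n_contigs,
                                  gap_model = list(mean_gap = 500),
                                  seed = NULL, min_contig = 200,
                                  size_shape = 3) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      fragment_into_contigs(genome, n_contigs, gap_model, NULL,
                            min_contig, size_shape)))
  }
  G <- if (inherits(genome, "genome_model")) genome$length else as.numeric(genome)
  n_contigs <- as.integer(n_contigs)
  stopifnot(n_contigs >= 1)

  if (n_contigs == 1L) {
    gaps <- numeric(0)
  } else {
    gaps <- pmax(1, round(stats::rexp(n_contigs - 1L,
                                      rate = 1 / gap_model$mean_gap)))
  }
  if (sum(gaps) + n_contigs * min_contig > G) {
    stop(sprintf("cannot fit %d contigs (>= %d bp each) plus %.0f bp of gaps into %.0f bp",
                 n_contigs, min_contig, sum(gaps), G), call. = FALSE)
  }

  avail <- G - sum(gaps) - n_contigs * min_contig
  w <- stats::rgamma(n_contigs, shape = size_shape)
  len <- min_contig + floor(avail * w / sum(w))
  rem <- G - sum(gaps) - sum(len)
  if (rem > 0) len[seq_len(rem)] <- len[seq_len(rem)] + 1

  start <- cumsum(c(0, len[-n_contigs] + gaps))
  layout <- tibble::tibble(
    contig_id = sprintf("ctg%05d", seq_len(n_contigs)),
    chrom = "chr1",
    start = start,
    end = start + len,
    length = len,
    orientation = "+",
    rank = seq_len(n_contigs),
    gap_after = c(gaps, NA_real_))
  class(layout) <- c("contig_layout", class(layout))
  attr(layout, "genome_length") <- G
  layout
}

#' Contig lengths of a layout as a named vector
#' @param layout A `contig_layout` or `scaffold_set`-compatible tibble with
#'   `contig_id` and `length` columns.
#' @return Named numeric vector of contig lengths.
#' @export
contig_lengths <- function(layout) {
  assert_cols(layout, c("contig_id", "length"))
  stats::setNames(layout$length, layout$contig_id)
}

#' Write / read the AGP-like truth layout table
#'
#' Plain TSV with columns `contig_id`, `chrom`, `start`, `end`,
#' `orientation`, `rank`, `gap_after` (0-based half-open coordinates).
#'
#' @param layout A `contig_layout` tibble.
#' @param path File path.
#' @export
write_layout_agp <- function(layout, path) {
  readr::write_tsv(layout[, c("contig_id", "chrom", "start", "end",
                              "orientation", "rank", "gap_after")], path)
  invisible(path)
}

#' @rdname write_layout_agp
#' @export
read_layout_agp <- function(path) {
  layout <- readr::read_tsv(path, col_types = readr::cols(
    contig_id = "c", chrom = "c", start = "d", end = "d",
    orientation = "c", rank = "i", gap_after = "d"))
  layout$length <- layout$end - layout$start
  layout <- layout[, c("contig_id", "chrom", "start", "end", "length",
                       "orientation", "rank", "gap_after")]
  class(layout) <- c("contig_layout", class(layout))
  layout
}

#' Assign read-pair tags to contigs of a layout
#'
#' Adds contig assignments and contig-local coordinates for each tag. A tag
#' is assigned only when its interval lies entirely within one contig; tags
#' falling in gaps or across a contig boundary get `NA` (unmapped in a
#' contig-level mapping). Local coordinates and strands respect the layout
#' orientation.
#'
#' @param pairs A pair tibble (see [simulate_library()]).
#' @param layout A `contig_layout`.
#' @return `pairs` with added columns `fwd_contig`, `fwd_lpos`,
#'   `fwd_lstrand`, `rev_contig`, `rev_lpos`, `rev_lstrand`.
#' @export
map_pairs_to_contigs <- function(pairs, layout) {
  assert_cols(pairs, c("fwd_chrom", "fwd_pos", "rev_chrom", "rev_pos",
                       "fwd_strand", "rev_strand", "read_len"))
  ctg <- GenomicRanges::GRanges(layout$chrom,
                                IRanges::IRanges(layout$start + 1, layout$end))

  locate <- function(chrom, pos, strand) {
    tag <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(pos + 1, width = pairs$read_len))
    idx <- GenomicRanges::findOverlaps(tag, ctg, type = "within", select = "first")
    plus <- !is.na(idx) & layout$orientation[idx] == "+"
    lpos <- ifelse(plus, pos - layout$start[idx],
                   layout$end[idx] - (pos + pairs$read_len))
    lstr <- ifelse(plus, strand, ifelse(strand == "+", "-", "+"))
    list(contig = ifelse(is.na(idx), NA_character_, layout$contig_id[idx]),
         lpos = ifelse(is.na(idx), NA_real_, lpos),
         lstrand = ifelse(is.na(idx), NA_character_, lstr))
  }

  f <- locate(pairs$fwd_chrom, pairs$fwd_pos, pairs$fwd_strand)
  r <- locate(pairs$rev_chrom, pairs$rev_pos, pairs$rev_strand)
  dplyr::mutate(pairs,
                fwd_contig = f$contig, fwd_lpos = f$lpos, fwd_lstrand = f$lstrand,
                rev_contig = r$contig, rev_lpos = r$lpos, rev_lstrand = r$lstrand)
}

#' Extract contig sequences from a genome given a layout
#'
#' @param genome A `genome_model` with sequence.
#' @param layout A `contig_layout`.
#' @return A [Biostrings::DNAStringSet] named by `contig_id` (in layout
#'   orientation: reverse-complemented for `"-"` rows).
#' @export
extract_contig_seqs <- function(genome, layout) {
  if (is.null(genome$sequence)) stop("genome has no sequence", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(layout)), function(i) {
      s <- Biostrings::subseq(genome$sequence, layout$start[i] + 1, layout$end[i])
      if (layout$orientation[i] == "-") Biostrings::reverseComplement(s) else s
    }))
  names(seqs) <- layout$contig_id
  seqs
}

#' View a truth layout as a scaffold arrangement
#'
#' Turns a `contig_layout` into the `scaffold_set` form (one scaffold per
#' chromosome, contigs in truth order) so it can serve as the reference
#' arrangement in [window_inconsistency()] or [evaluate_against_truth()].
#'
#' @param layout A `contig_layout`.
#' @return A `scaffold_set` tibble (`scaffold_id`, `position`, `contig_id`,
#'   `orientation`, `gap_after`).
#' @export
layout_as_scaffolds <- function(layout) {
  sc <- layout |>
    dplyr::arrange(.data$chrom, .data$rank) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(position = dplyr::row_number(),
                  gap_after = ifelse(dplyr::row_number() == dplyr::n(),
                                     NA_real_, .data$gap_after)) |>
    dplyr::ungroup() |>
    dplyr::transmute(scaffold_id = .data$chrom, position = .data$position,
                     contig_id = .data$contig_id,
                     orientation = .data$orientation,
                     gap_after = .data$gap_after)
  new_scaffold_set(sc, contig_lengths(layout))
}
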