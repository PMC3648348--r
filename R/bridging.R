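#' Which repeat elements are bridged by at least one read pair?
#'
#' An element is *bridged* when some qualifying pair fully contains it
#' within its outer span with both tags mapped in the flanking sequence:
#' the leftmost tag ends at or before the element start and the rightmost
#' tag begins at or after the element end. Qualifying pairs are consistent
#' (facing-in, unique, non-clonal) with span at most the 99th insert
#' percentile. Implemented as an interval containment query, not an
#' all-pairs scan.
#'
#' @param pairs Classified pair tibble.
#' @param repeats Repeat tibble (`class`, `start`, `end`, `length`; 0-based
#'   half-open), e.g. `genome$repeats` or [read_repeats_bed()] output.
#' @param insert_p99 99th percentile of the insert distribution (bp);
#'   `NULL` for no span cap.
#' @param chrom Chromosome of the repeat annotation.
#' @return `repeats` with a logical `bridged` column.
#' @export
bridged_elements <- function(pairs, repeats, insert_p99 = NULL,
                             chrom = "chr1") {
  assert_cols(pairs, c("class", "span", "read_len"))
  q <- dplyr::filter(pairs, .data$class == "consistent",
                     .data$fwd_chrom == chrom)
  if (!is.null(insert_p99)) q <- dplyr::filter(q, .data$span <= insert_p99)
  if (nrow(q) == 0) return(dplyr::mutate(repeats, bridged = FALSE))
  lp <- pmin(q$fwd_pos, q$rev_pos)
  rp <- pmax(q$fwd_pos, q$rev_pos)
  inner_start <- lp + q$read_len  # 0-based: first base after the left tag
  ok <- rp > inner_start
  inner <- IRanges::IRanges(start = inner_start[ok] + 1, end = rp[ok])
  elem <- IRanges::IRanges(start = repeats$start + 1, end = repeats$end)
  dplyr::mutate(repeats,
                bridged = IRanges::overlapsAny(elem, inner, type = "within"))
}

#' Aggregate bridging flags into element-size windows per repeat class
#'
#' Elements are binned by their own length into contiguous windows
#' (default 500 bp) and the fraction bridged is reported per class and bin
#' -- the per-library repeat-bridging profile. Empty bins are omitted.
#'
#' @param flagged Output of [bridged_elements()].
#' @param window Bin width in bp.
#' @param library Optional library name recorded in the profile.
#' @return A `bridging_profile` tibble: `class`, `bin_start`, `bin_end`,
#'   `n_elements`, `n_bridged`, `fraction` (and `library` if given).
#' @export
bridging_profile <- function(flagged, window = 500, library = NULL) {
  assert_cols(flagged, c("class", "length", "bridged"))
  prof <- flagged |>
    dplyr::mutate(bin_start = floor(.data$length / window) * window) |>
    dplyr::group_by(.data$class, .data$bin_start) |>
    dplyr::summarise(n_elements = dplyr::n(),
                     n_bridged = sum(.data$bridged), .groups = "drop") |>
    dplyr::mutate(bin_end = .data$bin_start + window,
                  fraction = .data$n_bridged / .data$n_elements) |>
    dplyr::select("class", "bin_start", "bin_end", "n_elements",
                  "n_bridged", "fraction") |>
    dplyr::arrange(.data$class, .data$bin_start)
  if (!is.null(library)) prof <- dplyr::mutate(prof, library = library)
  class(prof) <- c("bridging_profile", class(prof))
  prof
}

#' Closed-form bridging probability for an isolated element
#'
#' Clone-coverage (Lander-Waterman style) oracle: with `n_pairs` fragments
#' of fixed `insert` length placed uniformly on a genome, an isolated
#' element of length `element_length` with uniquely mappable flanks is
#' bridged with probability
#' `1 - exp(-n_pairs * max(0, insert - element_length - 2*read_length + 1) / genome_length)`.
#'
#' @param n_pairs Number of fragments.
#' @param insert Fragment (insert) length in bp.
#' @param element_length Element length in bp.
#' @param read_length Tag length in bp.
#' @param genome_length Genome length in bp.
#' @return Bridging probability (vectorized).
#' @export
theoretical_bridging_prob <- function(n_pairs, insert, element_length,
                                      read_length, genome_length) {
  stopifnot(all(n_pairs > 0), all(insert > 0), all(element_length > 0),
            all(read_length > 0), all(genome_length > 0))
  window <- pmax(0, insert - element_length - 2 * read_length + 1)
  1 - exp(-n_pairs * window / genome_length)
}
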