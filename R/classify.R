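#' Mark clonal (PCR-duplicate) read pairs
#'
#' Read pairs with exactly the same mapping coordinates and strands of both
#' tags are clonal amplification copies; for every coordinate signature
#' exactly one pair (the one with the smallest `pair_id`, so the choice does
#' not depend on input order) is left unmarked.
#'
#' @param pairs A pair tibble.
#' @return `pairs` with a logical `clonal` column.
#' @export
mark_duplicates <- function(pairs) {
  assert_cols(pairs, c("pair_id", "fwd_chrom", "fwd_pos", "fwd_strand",
                       "rev_chrom", "rev_pos", "rev_strand"))
  sig <- pair_signature(pairs)
  keep <- !duplicated(sig[order(pairs$pair_id)])[order(order(pairs$pair_id))]
  dplyr::mutate(pairs, clonal = !keep)
}

#' Classify read pairs by orientation and distance consistency
#'
#' Applies the filtering cascade used for paired-tag genome structure
#' analysis. Classes are mutually exclusive and exhaustive:
#'
#' * `clonal` -- marked duplicate (see [mark_duplicates()]; run first).
#' * `ambiguous` -- at least one tag without a unique mapping; such pairs
#'   never enter coverage or scaffolding.
#' * `remote` -- tags on different chromosomes, or facing-in orientation but
#'   outer span outside `insert_bounds`.
#' * `consistent` -- facing-in orientation (leftmost tag `+`, rightmost `-`),
#'   same chromosome, outer span within `insert_bounds`.
#' * `inverted` -- tags on the same strand (one tag flipped).
#' * `everted` -- leftmost tag `-`, rightmost `+` (both flipped, wrong tag
#'   order).
#'
#' @param pairs A pair tibble; a missing `clonal` column is computed.
#' @param insert_bounds Length-2 numeric `(low, high)` span bounds in bp,
#'   typically the 1st/99th percentiles of the fitted insert distribution
#'   (see [estimate_insert_distribution()]).
#' @param max_distance Maximum span (bp) a consistent pair may have; bounds
#'   wider than this are an error.
#' @return `pairs` with added `span` (outer span, `NA` across chromosomes)
#'   and `class` columns.
#' @export
classify_pairs <- function(pairs, insert_bounds, max_distance = 1e5) {
  stopifnot(length(insert_bounds) == 2)
  lo <- insert_bounds[[1]]; hi <- insert_bounds[[2]]
  if (!(lo < hi)) stop("insert_bounds must satisfy low < high", call. = FALSE)
  if (hi > max_distance) {
    stop(sprintf("insert_bounds upper limit (%s) exceeds max_distance (%s)",
                 format(hi), format(max_distance)), call. = FALSE)
  }
  if (!"clonal" %in% names(pairs)) pairs <- mark_duplicates(pairs)
  if (!"fwd_unique" %in% names(pairs)) pairs$fwd_unique <- TRUE
  if (!"rev_unique" %in% names(pairs)) pairs$rev_unique <- TRUE

  fwd_left <- pairs$fwd_pos <= pairs$rev_pos
  s_left <- ifelse(fwd_left, pairs$fwd_strand, pairs$rev_strand)
  s_right <- ifelse(fwd_left, pairs$rev_strand, pairs$fwd_strand)
  span <- pair_span(pairs)
  same <- pairs$fwd_chrom == pairs$rev_chrom
  proper <- s_left == "+" & s_right == "-"

  cls <- dplyr::case_when(
    pairs$clonal ~ "clonal",
    !pairs$fwd_unique | !pairs$rev_unique ~ "ambiguous",
    !same ~ "remote",
    proper & span >= lo & span <= hi ~ "consistent",
    proper ~ "remote",
    s_left == "-" & s_right == "+" ~ "everted",
    .default = "inverted")
  dplyr::mutate(pairs, span = span, class = cls)
}

#' Cluster inconsistent read pairs by shared breakpoints
#'
#' Chimeric library molecules produce stochastic remote/inverted/everted
#' pairs supported by a single molecule, while genuine structural
#' differences (or reference misassemblies) are supported by multiple
#' independent pairs with nearby breakpoints. Pairs of the same class whose
#' left-tag starts and right-tag starts each lie within `max_gap` are
#' single-linkage clustered; clusters below `min_support` are dropped.
#'
#' @param pairs A classified pair tibble (see [classify_pairs()]).
#' @param min_support Minimum number of pairs per reported cluster (>= 2).
#' @param max_gap Breakpoint co-location tolerance in bp on both sides;
#'   sensible default is the library insert median.
#' @param types Classes to cluster.
#' @return A tibble of clusters (`cluster_id`, `type`, `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `support`, `inter_chromosomal`)
#'   with attributes `fraction_clustered` (share of inconsistent pairs in
#'   reported clusters) and `fraction_clustered_interchromosomal`.
#' @export
cluster_inconsistent <- function(pairs, min_support = 2L, max_gap,
                                 types = c("remote", "inverted", "everted")) {
  stopifnot(min_support >= 2)
  assert_cols(pairs, c("class", "read_len"))
  inc <- dplyr::filter(pairs, .data$class %in% types)
  empty <- tibble::tibble(cluster_id = integer(), type = character(),
                          chrom1 = character(), start1 = numeric(),
                          end1 = numeric(), chrom2 = character(),
                          start2 = numeric(), end2 = numeric(),
                          support = integer(), inter_chromosomal = logical())
  if (nrow(inc) == 0) {
    attr(empty, "fraction_clustered") <- NA_real_
    attr(empty, "fraction_clustered_interchromosomal") <- NA_real_
    return(empty)
  }

  # canonical side 1 = lexicographically smaller (chrom, pos) tag
  fwd_first <- inc$fwd_chrom < inc$rev_chrom |
    (inc$fwd_chrom == inc$rev_chrom & inc$fwd_pos <= inc$rev_pos)
  inc$chrom1 <- ifelse(fwd_first, inc$fwd_chrom, inc$rev_chrom)
  inc$pos1 <- ifelse(fwd_first, inc$fwd_pos, inc$rev_pos)
  inc$chrom2 <- ifelse(fwd_first, inc$rev_chrom, inc$fwd_chrom)
  inc$pos2 <- ifelse(fwd_first, inc$rev_pos, inc$fwd_pos)
  inc$grp <- paste(inc$class, inc$chrom1, inc$chrom2, sep = "\r")

  inc$cluster <- NA_integer_
  next_id <- 0L
  for (g in split(seq_len(nrow(inc)), inc$grp)) {
    sub <- inc[g, ]
    ir <- IRanges::IRanges(start = sub$pos1 + 1, width = 1L)
    hits <- IRanges::findOverlaps(ir, ir, maxgap = max_gap)
    i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
    ok <- i < j & abs(sub$pos2[i] - sub$pos2[j]) <= max_gap
    gph <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
    gph <- igraph::add_vertices(gph, max(0L, nrow(sub) - igraph::vcount(gph)))
    comp <- igraph::components(gph)$membership
    inc$cluster[g] <- next_id + comp
    next_id <- next_id + max(comp)
  }

  res <- inc |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      type = .data$class[1],
      chrom1 = .data$chrom1[1],
      start1 = min(.data$pos1), end1 = max(.data$pos1) + .data$read_len[1],
      chrom2 = .data$chrom2[1],
      start2 = min(.data$pos2), end2 = max(.data$pos2) + .data$read_len[1],
      support = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(inter_chromosomal = .data$chrom1 != .data$chrom2) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$support)) |>
    dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"cluster")

  attr(res, "fraction_clustered") <- sum(res$support) / nrow(inc)
  attr(res, "fraction_clustered_interchromosomal") <-
    sum(res$support[res$inter_chromosomal]) / nrow(inc)
  res
}

#' Write classification and cluster results
#'
#' `write_classification()` writes the classified pair table as TSV;
#' `write_clusters_bedpe()` writes clusters in a BEDPE-like layout
#' (`chrom1 start1 end1 chrom2 start2 end2 type support`).
#'
#' @param pairs Classified pair tibble.
#' @param clusters Cluster tibble from [cluster_inconsistent()].
#' @param path Output path.
#' @export
write_classification <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname write_classification
#' @export
write_clusters_bedpe <- function(clusters, path) {
  readr::write_tsv(clusters[, c("chrom1", "start1", "end1", "chrom2",
                                "start2", "end2", "type", "support")], path)
  invisible(path)
}
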