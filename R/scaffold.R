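#' Build a contig-link graph from inter-contig read pairs
#'
#' Pairs from coverage-normalized libraries whose tags map (uniquely,
#' non-clonally) to two different contigs become links between contig ends.
#' The contig end a tag links is the end its mate points past (the 3' end
#' for a locally forward tag). Per (contig end, contig end, library) the
#' links are aggregated into an edge with their count as support and a gap
#' estimate: the median over supporting pairs of
#' `insert_median - d_a - d_b`, where `d` is the distance from each tag's
#' outer start to its contig end; negative estimates (overlap candidates)
#' are floored at `gap_floor` in `gap_estimate` with the raw median kept in
#' `gap_raw`.
#'
#' @param pairs A pair tibble (or list of tibbles, one per library) with
#'   contig assignments from [map_pairs_to_contigs()].
#' @param layout The `contig_layout` the pairs were mapped to.
#' @param insert_medians Named numeric vector of insert medians per library
#'   (fitted medians; names must cover `pairs$library`).
#' @param min_support Minimum supporting pairs per edge.
#' @param gap_floor Floor for `gap_estimate` in bp.
#' @return A `scaffold_graph` tibble: `contig_a`, `end_a`, `contig_b`,
#'   `end_b`, `library`, `support`, `gap_raw`, `gap_estimate`; attributes
#'   `contig_lengths` and `insert_medians`.
#' @export
build_link_graph <- function(pairs, layout, insert_medians,
                             min_support = 5L, gap_floor = 1) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- dplyr::bind_rows(pairs)
  assert_cols(pairs, c("library", "read_len", "fwd_contig", "fwd_lpos",
                       "fwd_lstrand", "rev_contig", "rev_lpos", "rev_lstrand"))
  lens <- contig_lengths(layout)

  p <- dplyr::filter(pairs,
                     !col_or(pairs, "clonal", FALSE),
                     col_or(pairs, "fwd_unique", TRUE),
                     col_or(pairs, "rev_unique", TRUE),
                     !is.na(.data$fwd_contig), !is.na(.data$rev_contig),
                     .data$fwd_contig != .data$rev_contig)
  unknown <- setdiff(unique(c(p$fwd_contig, p$rev_contig)), names(lens))
  if (length(unknown)) {
    stop("pairs reference contigs absent from the layout: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  missing_lib <- setdiff(unique(p$library), names(insert_medians))
  if (length(missing_lib)) {
    stop("insert_medians missing for library: ",
         paste(missing_lib, collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(contig_a = character(), end_a = character(),
                          contig_b = character(), end_b = character(),
                          library = character(), support = integer(),
                          gap_raw = numeric(), gap_estimate = numeric())
  if (nrow(p) == 0) {
    return(new_scaffold_graph(empty, lens, insert_medians))
  }

  ins <- insert_medians[p$library]
  end_f <- ifelse(p$fwd_lstrand == "+", "R", "L")
  end_r <- ifelse(p$rev_lstrand == "+", "R", "L")
  d_f <- ifelse(p$fwd_lstrand == "+", lens[p$fwd_contig] - p$fwd_lpos,
                p$fwd_lpos + p$read_len)
  d_r <- ifelse(p$rev_lstrand == "+", lens[p$rev_contig] - p$rev_lpos,
                p$rev_lpos + p$read_len)
  gap <- ins - d_f - d_r

  swap <- p$fwd_contig > p$rev_contig
  edges <- tibble::tibble(
    contig_a = ifelse(swap, p$rev_contig, p$fwd_contig),
    end_a = ifelse(swap, end_r, end_f),
    contig_b = ifelse(swap, p$fwd_contig, p$rev_contig),
    end_b = ifelse(swap, end_f, end_r),
    library = p$library, gap = gap) |>
    dplyr::group_by(.data$contig_a, .data$end_a, .data$contig_b,
                    .data$end_b, .data$library) |>
    dplyr::summarise(support = dplyr::n(),
                     gap_raw = stats::median(.data$gap), .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::mutate(gap_estimate = pmax(gap_floor, round(.data$gap_raw)))
  new_scaffold_graph(edges, lens, insert_medians)
}

new_scaffold_graph <- function(edges, lens, insert_medians) {
  class(edges) <- c("scaffold_graph", setdiff(class(edges), "scaffold_graph"))
  attr(edges, "contig_lengths") <- lens
  attr(edges, "insert_medians") <- insert_medians
  edges
}

#' Greedy end-joining scaffolder
#'
#' A simplified SSPACE-like scaffolder: libraries are processed from the
#' smallest to the largest insert size; within a library, edges are
#' processed by descending support (ties broken lexicographically on contig
#' ids, so output is deterministic). An edge may join two scaffold ends only
#' if (a) both its contig ends are currently exposed scaffold ends, (b) the
#' contigs belong to different scaffolds, and (c) the edge is unambiguous at
#' both of its ends: it carries the highest support there and the
#' second-best competing support is at most `ratio` times its own (the
#' best/second-best ambiguity rule). Processing small inserts first lets
#' large-insert edges act on grown scaffold ends instead of producing
#' skip-a-contig joins.
#'
#' @param graph A `scaffold_graph`.
#' @param library_order Library names, smallest insert first; defaults to
#'   the graph's `insert_medians` sorted ascending.
#' @param ratio Maximum second-best/best support ratio tolerated before an
#'   end is declared ambiguous and skipped (SSPACE-like default 0.7).
#' @param contig_lens Named contig lengths; defaults to the graph attribute.
#' @return A `scaffold_set` tibble: `scaffold_id`, `position`, `contig_id`,
#'   `orientation`, `gap_after` (bp; `NA` after the last contig), carrying
#'   `contig_lengths` as an attribute. Every contig appears exactly once;
#'   contigs without joins become singleton scaffolds.
#' @export
greedy_scaffold <- function(graph, library_order = NULL, ratio = 0.7,
                            contig_lens = attr(graph, "contig_lengths")) {
  if (is.null(contig_lens)) stop("contig lengths unavailable", call. = FALSE)
  if (is.null(library_order)) {
    med <- attr(graph, "insert_medians")
    if (is.null(med)) stop("library_order or insert_medians required",
                           call. = FALSE)
    library_order <- names(sort(med))
  }

  ids <- names(contig_lens)
  scaf_of <- stats::setNames(seq_along(ids), ids)
  scafs <- lapply(seq_along(ids), function(i) {
    list(contig = ids[i], orient = "+", gap = numeric(0))
  })

  exposed_side <- function(s, contig, end) {
    # which side (left/right) of scaffold s currently exposes (contig, end)?
    n <- length(s$contig)
    if (s$contig[1] == contig &&
        end == (if (s$orient[1] == "+") "L" else "R")) return("left")
    if (s$contig[n] == contig &&
        end == (if (s$orient[n] == "+") "R" else "L")) return("right")
    NA_character_
  }
  reverse_scaf <- function(s) {
    list(contig = rev(s$contig),
         orient = rev(ifelse(s$orient == "+", "-", "+")),
         gap = rev(s$gap))
  }

  for (lib in library_order) {
    e <- dplyr::filter(graph, .data$library == lib)
    if (nrow(e) == 0) next
    # ambiguity rule per contig end: an edge survives only where it is the
    # single best link and the runner-up is clearly weaker
    keys <- rbind(
      data.frame(key = paste(e$contig_a, e$end_a), i = seq_len(nrow(e)),
                 support = e$support),
      data.frame(key = paste(e$contig_b, e$end_b), i = seq_len(nrow(e)),
                 support = e$support))
    ok <- rep(TRUE, nrow(e))
    for (grp in split(keys, keys$key)) {
      if (nrow(grp) == 1) next
      o <- order(grp$support, decreasing = TRUE)
      best <- grp$support[o[1]]; second <- grp$support[o[2]]
      ok[grp$i[o[-1]]] <- FALSE
      if (second / best > ratio) ok[grp$i[o[1]]] <- FALSE
    }
    e <- e[ok, ]
    if (nrow(e) == 0) next
    e <- dplyr::arrange(e, dplyr::desc(.data$support), .data$contig_a,
                        .data$contig_b)

    for (i in seq_len(nrow(e))) {
      sa <- scaf_of[[e$contig_a[i]]]
      sb <- scaf_of[[e$contig_b[i]]]
      if (sa == sb) next
      side_a <- exposed_side(scafs[[sa]], e$contig_a[i], e$end_a[i])
      side_b <- exposed_side(scafs[[sb]], e$contig_b[i], e$end_b[i])
      if (is.na(side_a) || is.na(side_b)) next  # occupied end
      A <- scafs[[sa]]
      B <- scafs[[sb]]
      if (side_a == "left") A <- reverse_scaf(A)
      if (side_b == "right") B <- reverse_scaf(B)
      scafs[[sa]] <- list(contig = c(A$contig, B$contig),
                          orient = c(A$orient, B$orient),
                          gap = c(A$gap, e$gap_estimate[i], B$gap))
      scaf_of[B$contig] <- sa
      scafs[[sb]] <- list(contig = character(0), orient = character(0),
                          gap = numeric(0))
    }
  }

  alive <- which(vapply(scafs, function(s) length(s$contig) > 0, logical(1)))
  out <- purrr::map_dfr(seq_along(alive), function(k) {
    s <- scafs[[alive[k]]]
    tibble::tibble(scaffold_id = sprintf("scf%05d", k),
                   position = seq_along(s$contig),
                   contig_id = s$contig,
                   orientation = s$orient,
                   gap_after = c(s$gap, NA_real_))
  })
  new_scaffold_set(out, contig_lens)
}

new_scaffold_set <- function(df, contig_lens) {
  class(df) <- c("scaffold_set", setdiff(class(df), "scaffold_set"))
  attr(df, "contig_lengths") <- contig_lens
  df
}

#' Scaffold N50
#'
#' The largest length `L` in the list such that elements of length >= `L`
#' together contain at least half of the total length.
#'
#' @param lengths Non-empty vector of positive lengths.
#' @return The N50 value (bp).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summary metrics of a scaffold arrangement
#'
#' Scaffold spans are contig lengths plus estimated gaps.
#'
#' @param scaffolds A `scaffold_set`.
#' @param contig_lens Named contig lengths (defaults to the attribute).
#' @return One-row tibble: `n_scaffolds`, `n50`, `total_span`,
#'   `largest_span`.
#' @export
scaffold_metrics <- function(scaffolds,
                             contig_lens = attr(scaffolds, "contig_lengths")) {
  spans <- scaffolds |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::summarise(span = sum(contig_lens[.data$contig_id]) +
                       sum(.data$gap_after, na.rm = TRUE), .groups = "drop")
  tibble::tibble(n_scaffolds = nrow(spans), n50 = n50(spans$span),
                 total_span = sum(spans$span), largest_span = max(spans$span))
}

#' @method glance scaffold_set
#' @export
glance.scaffold_set <- function(x, ...) scaffold_metrics(x)

#' Score scaffold joins against the simulation truth
#'
#' Every adjacent contig pair in the scaffolds is compared with the truth
#' layout: a join is *correct* when the two contigs are adjacent in truth
#' order with compatible orientations (the join or its reverse complement
#' equals the truth adjacency); *orientation_error* when the contigs are
#' truth-adjacent but order/orientation is wrong; otherwise a *misjoin*.
#' `missed_joins` counts truth adjacencies not realized as correct joins.
#'
#' @param scaffolds A `scaffold_set`.
#' @param layout The truth `contig_layout`.
#' @return One-row tibble: `n_joins`, `correct_joins`, `misjoins`,
#'   `orientation_errors`, `missed_joins`.
#' @export
evaluate_against_truth <- function(scaffolds, layout) {
  if (!setequal(scaffolds$contig_id, layout$contig_id)) {
    stop("scaffolds and layout cover different contig sets", call. = FALSE)
  }
  truth <- layout |>
    dplyr::arrange(.data$chrom, .data$rank) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(a = utils::head(.data$contig_id, -1),
                   oa = utils::head(.data$orientation, -1),
                   b = utils::tail(.data$contig_id, -1),
                   ob = utils::tail(.data$orientation, -1))
  flip <- function(o) ifelse(o == "+", "-", "+")
  truth_fwd <- paste(truth$a, truth$oa, truth$b, truth$ob)
  truth_rev <- paste(truth$b, flip(truth$ob), truth$a, flip(truth$oa))
  truth_adj <- c(paste(truth$a, truth$b), paste(truth$b, truth$a))

  joins <- scaffolds |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::reframe(x = utils::head(.data$contig_id, -1),
                   ox = utils::head(.data$orientation, -1),
                   y = utils::tail(.data$contig_id, -1),
                   oy = utils::tail(.data$orientation, -1))
  if (nrow(joins) == 0) {
    return(tibble::tibble(n_joins = 0L, correct_joins = 0L, misjoins = 0L,
                          orientation_errors = 0L,
                          missed_joins = nrow(truth)))
  }
  sig <- paste(joins$x, joins$ox, joins$y, joins$oy)
  adj <- paste(joins$x, joins$y)
  correct <- sig %in% c(truth_fwd, truth_rev)
  orient_err <- !correct & adj %in% truth_adj
  tibble::tibble(
    n_joins = nrow(joins),
    correct_joins = sum(correct),
    misjoins = sum(!correct & !orient_err),
    orientation_errors = sum(orient_err),
    missed_joins = nrow(truth) - sum(correct))
}

#' Scaffold every combination of libraries and compare N50
#'
#' Each library is classified, coverage-normalized to `target_coverage`
#' and mapped to contigs once; each requested combination is then
#' scaffolded independently from the same contig set (libraries processed
#' smallest insert first) and its scaffold count, N50 and truth accuracy
#' are tabulated.
#'
#' @param libraries Named list of pair tibbles (genome coordinates, as from
#'   [simulate_library()]).
#' @param layout The `contig_layout` to scaffold.
#' @param genome_length Genome length in bp.
#' @param target_coverage Normalization target (x-fold physical coverage).
#' @param combinations List of character vectors of library names; default
#'   all non-empty combinations (only when <= 5 libraries).
#' @param min_support,ratio Scaffolder parameters.
#' @param seed Optional integer seed for the normalization subsampling.
#' @return A tibble sorted by decreasing N50: `combination`, `n_libraries`,
#'   `n_scaffolds`, `n50`, `total_span`, `correct_joins`, `misjoins`,
#'   `orientation_errors`.
#' @export
combination_sweep <- function(libraries, layout, genome_length,
                              target_coverage = 8.5, combinations = NULL,
                              min_support = 5L, ratio = 0.7, seed = NULL) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  if (is.null(combinations)) {
    if (length(libraries) > 5) {
      stop("give explicit `combinations` for more than 5 libraries",
           call. = FALSE)
    }
    nm <- names(libraries)
    combinations <- unlist(lapply(seq_along(nm), function(k) {
      utils::combn(nm, k, simplify = FALSE)
    }), recursive = FALSE)
  }

  prepped <- prepare_libraries(libraries, layout, genome_length,
                               target_coverage, seed)
  purrr::map_dfr(combinations, function(combo) {
    combo <- unique(combo)
    run <- scaffold_combination(prepped[combo], layout, min_support, ratio)
    acc <- evaluate_against_truth(run, layout)
    dplyr::bind_cols(
      tibble::tibble(combination = paste(combo, collapse = "+"),
                     n_libraries = length(combo)),
      scaffold_metrics(run)[, c("n_scaffolds", "n50", "total_span")],
      acc[, c("correct_joins", "misjoins", "orientation_errors")])
  }) |>
    dplyr::arrange(dplyr::desc(.data$n50))
}

# classify + normalize + map each library once; returns a list of
# list(pairs, insert_median) entries
prepare_libraries <- function(libraries, layout, genome_length,
                              target_coverage, seed = NULL) {
  purrr::imap(libraries, function(pp, nm) {
    pp <- mark_duplicates(pp)
    st <- estimate_insert_distribution(pp)
    cl <- classify_pairs(pp, insert_bounds(st))
    sub <- normalize_to_coverage(cl, genome_length, target_coverage, st,
                                 seed = if (is.null(seed)) NULL else
                                   seed + match(nm, names(libraries)))
    list(pairs = map_pairs_to_contigs(sub, layout),
         insert_median = st$median)
  })
}

scaffold_combination <- function(prepped, layout, min_support = 5L,
                                 ratio = 0.7) {
  med <- vapply(prepped, `[[`, numeric(1), "insert_median")
  names(med) <- vapply(prepped, function(x) x$pairs$library[1], character(1))
  g <- build_link_graph(lapply(prepped, `[[`, "pairs"), layout, med,
                        min_support = min_support)
  greedy_scaffold(g, library_order = names(sort(med)), ratio = ratio)
}

#' Scaffold a single library at increasing coverage
#'
#' Coverage-escalation companion to [combination_sweep()]: how much does
#' more depth of one insert size buy compared with combining insert sizes?
#'
#' @param pairs A pair tibble for one library.
#' @param layout The `contig_layout`.
#' @param genome_length Genome length in bp.
#' @param coverages Ascending x-fold targets.
#' @param min_support,ratio Scaffolder parameters.
#' @param seed Optional integer seed.
#' @return A tibble with one row per coverage level.
#' @export
coverage_escalation <- function(pairs, layout, genome_length, coverages,
                                min_support = 5L, ratio = 0.7, seed = NULL) {
  pairs <- mark_duplicates(pairs)
  st <- estimate_insert_distribution(pairs)
  cl <- classify_pairs(pairs, insert_bounds(st))
  purrr::map_dfr(coverages, function(cv) {
    sub <- normalize_to_coverage(cl, genome_length, cv, st, seed = seed)
    mapped <- map_pairs_to_contigs(sub, layout)
    med <- stats::setNames(st$median, mapped$library[1])
    g <- build_link_graph(mapped, layout, med, min_support = min_support)
    run <- greedy_scaffold(g, library_order = names(med), ratio = ratio)
    dplyr::bind_cols(tibble::tibble(coverage = cv),
                     scaffold_metrics(run)[, c("n_scaffolds", "n50")])
  })
}
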