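#' In-silico restriction digest of a sequence
#'
#' Digests a nucleotide sequence with a blunt-cutting enzyme (default SwaI,
#' recognition site `ATTTAAAT`, palindromic, cutting at the centre of the
#' 8-mer: ATTT^AAAT). Fragment lengths are the distances between successive
#' cut positions plus the two terminal fragments, so they sum exactly to
#' the sequence length. Runs of `N` (assembly gaps) never match the site.
#'
#' @param sequence A character string, [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param site Recognition sequence; must be palindromic (only the forward
#'   strand is searched).
#' @param cut_offset Bases before the cut within the site (centre of the
#'   8-mer = 4). In 0-based terms the cut coordinate is `site_start + 4`.
#' @return A `restriction_map` tibble (`fragment`, `length`) with
#'   attributes `site`, `source = "in_silico"` and `total_length`.
#' @export
in_silico_digest <- function(sequence, site = "ATTTAAAT", cut_offset = 4L) {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1)
    sequence <- sequence[[1]]
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  L <- length(sequence)
  if (L == 0) stop("empty sequence", call. = FALSE)
  pat <- Biostrings::DNAString(site)
  if (as.character(Biostrings::reverseComplement(pat)) != site) {
    warning("site is not palindromic; only forward-strand occurrences are cut",
            call. = FALSE)
  }
  m <- Biostrings::matchPattern(pat, sequence, fixed = TRUE)
  cuts <- sort(unique(Biostrings::start(m) - 1L + cut_offset))  # 0-based
  cuts <- cuts[cuts > 0 & cuts < L]
  new_restriction_map(diff(c(0, cuts, L)), site, "in_silico", L)
}

new_restriction_map <- function(lengths, site, source, total = sum(lengths)) {
  out <- tibble::tibble(fragment = seq_along(lengths),
                        length = as.numeric(lengths))
  class(out) <- c("restriction_map", class(out))
  attr(out, "site") <- site
  attr(out, "source") <- source
  attr(out, "total_length") <- total
  out
}

#' Simulate an optical-map-like noisy restriction map
#'
#' Applies an error model of single-molecule optical mapping to a true
#' restriction map: each true cut is retained with probability
#' `1 - miss_rate` (a missed cut merges neighbouring fragments), false
#' cuts arise as a Poisson process along the molecule, fragment sizes are
#' perturbed multiplicatively by `Normal(1, sizing_cv)`, and fragments
#' below the detection limit are lost.
#'
#' @param map A `restriction_map` (in-silico truth).
#' @param sizing_cv Coefficient of variation of fragment sizing.
#' @param miss_rate Probability a true cut is not observed.
#' @param false_cut_rate Expected false cuts per bp (e.g. `1e-6`).
#' @param min_detectable Fragments shorter than this (bp) are dropped.
#' @param seed Optional integer seed.
#' @return A `restriction_map` with `source = "simulated_optical"`. Size
#'   conservation no longer holds (by design).
#' @export
simulate_optical_map <- function(map, sizing_cv = 0.05, miss_rate = 0,
                                 false_cut_rate = 0, min_detectable = 0,
                                 seed = NULL) {
  stopifnot(sizing_cv >= 0, miss_rate >= 0, miss_rate <= 1,
            false_cut_rate >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      simulate_optical_map(map, sizing_cv, miss_rate, false_cut_rate,
                           min_detectable, NULL)))
  }
  lens <- map$length
  L <- sum(lens)
  cuts <- utils::head(cumsum(lens), -1)
  cuts <- cuts[stats::runif(length(cuts)) >= miss_rate]
  n_false <- stats::rpois(1, false_cut_rate * L)
  if (n_false > 0) {
    cuts <- sort(unique(c(cuts, floor(stats::runif(n_false) * (L - 1)) + 1)))
  }
  frag <- diff(c(0, cuts, L))
  if (sizing_cv > 0) {
    frag <- pmax(1, round(frag * pmax(0.01, stats::rnorm(length(frag), 1,
                                                         sizing_cv))))
  }
  frag <- frag[frag >= min_detectable]
  new_restriction_map(frag, attr(map, "site"), "simulated_optical", L)
}

#' Align two ordered restriction maps by dynamic programming
#'
#' Global alignment of two ordered fragment-length lists, allowing blocks
#' of up to `max_merge` consecutive fragments on either side to be matched
#' against each other when their summed lengths agree within
#' `size_tolerance_rel` (this absorbs missed/false cuts), and unmatched
#' fragments to be skipped at a per-bp penalty. The score maximizes matched
#' bp minus skipped bp; `concordant_fraction` is the matched fraction of
#' map `a`'s total length.
#'
#' @param a,b `restriction_map`s (or bare length vectors).
#' @param size_tolerance_rel Relative tolerance on block-size agreement.
#' @param max_merge Maximum fragments merged into one block per side.
#' @param gap_penalty Per-bp penalty for skipped fragments.
#' @return A `map_alignment`: list with `blocks` (tibble: `a_start`,
#'   `a_end`, `b_start`, `b_end`, `size_a`, `size_b`, `size_diff`),
#'   `score`, `concordant_fraction`. Supports [tidy()] and [glance()].
#' @export
align_maps <- function(a, b, size_tolerance_rel = 0.05, max_merge = 3L,
                       gap_penalty = 1) {
  av <- if (is.data.frame(a)) a$length else as.numeric(a)
  bv <- if (is.data.frame(b)) b$length else as.numeric(b)
  if (!length(av) || !length(bv)) stop("both maps must be nonempty",
                                       call. = FALSE)
  n <- length(av); m <- length(bv)
  ca <- c(0, cumsum(av)); cb <- c(0, cumsum(bv))

  NEG <- -Inf
  dp <- matrix(NEG, n + 1, m + 1)
  bk_i <- matrix(0L, n + 1, m + 1)   # fragments of a consumed by the move
  bk_j <- matrix(0L, n + 1, m + 1)
  dp[1, ] <- -gap_penalty * cb
  dp[, 1] <- -gap_penalty * ca
  bk_j[1, 2:(m + 1)] <- 1L
  bk_i[2:(n + 1), 1] <- 1L

  for (i in 1:n) {
    for (j in 1:m) {
      best <- dp[i, j + 1] - gap_penalty * av[i]
      bi <- 1L; bj <- 0L
      alt <- dp[i + 1, j] - gap_penalty * bv[j]
      if (alt > best) { best <- alt; bi <- 0L; bj <- 1L }
      for (k in 1:min(max_merge, i)) {
        sa <- ca[i + 1] - ca[i + 1 - k]
        for (l in 1:min(max_merge, j)) {
          sb <- cb[j + 1] - cb[j + 1 - l]
          if (abs(sa - sb) <= size_tolerance_rel * max(sa, sb)) {
            alt <- dp[i + 1 - k, j + 1 - l] + (sa + sb) / 2
            if (alt > best) { best <- alt; bi <- k; bj <- l }
          }
        }
      }
      dp[i + 1, j + 1] <- best
      bk_i[i + 1, j + 1] <- bi
      bk_j[i + 1, j + 1] <- bj
    }
  }

  # traceback
  blocks <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    k <- bk_i[i + 1, j + 1]; l <- bk_j[i + 1, j + 1]
    if (k > 0 && l > 0) {
      sa <- ca[i + 1] - ca[i + 1 - k]
      sb <- cb[j + 1] - cb[j + 1 - l]
      blocks[[length(blocks) + 1]] <-
        tibble::tibble(a_start = i - k + 1L, a_end = i,
                       b_start = j - l + 1L, b_end = j,
                       size_a = sa, size_b = sb, size_diff = sa - sb)
    }
    i <- i - k; j <- j - l
  }
  blocks <- if (length(blocks)) {
    dplyr::arrange(dplyr::bind_rows(blocks), .data$a_start)
  } else {
    tibble::tibble(a_start = integer(), a_end = integer(),
                   b_start = integer(), b_end = integer(),
                   size_a = numeric(), size_b = numeric(),
                   size_diff = numeric())
  }
  structure(list(blocks = blocks, score = dp[n + 1, m + 1],
                 concordant_fraction = sum(blocks$size_a) / sum(av),
                 n_a = n, n_b = m),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<map_alignment> %d blocks, score %.0f, concordant fraction %.3f\n",
              nrow(x$blocks), x$score, x$concordant_fraction))
  invisible(x)
}

#' Build scaffold sequences from contig sequences
#'
#' Concatenates contig sequences in scaffold order/orientation with runs of
#' `N` of the estimated gap length between neighbours (AGP-style; gaps are
#' floored at `gap_floor`).
#'
#' @param scaffolds A `scaffold_set`.
#' @param contig_seqs Named [Biostrings::DNAStringSet] of contig sequences.
#' @param gap_floor Minimum emitted gap (bp).
#' @return A [Biostrings::DNAStringSet], one sequence per scaffold.
#' @export
scaffold_sequence <- function(scaffolds, contig_seqs, gap_floor = 1) {
  ids <- unique(scaffolds$scaffold_id)
  seqs <- Biostrings::DNAStringSet(vapply(ids, function(sid) {
    sc <- dplyr::arrange(scaffolds[scaffolds$scaffold_id == sid, ],
                         .data$position)
    parts <- character(2 * nrow(sc) - 1)
    for (i in seq_len(nrow(sc))) {
      s <- contig_seqs[[sc$contig_id[i]]]
      if (sc$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      parts[2 * i - 1] <- as.character(s)
      if (i < nrow(sc)) {
        parts[2 * i] <- strrep("N", max(gap_floor, sc$gap_after[i]))
      }
    }
    paste(parts, collapse = "")
  }, character(1)))
  names(seqs) <- ids
  seqs
}

#' Windowed inconsistency tally between two scaffold arrangements
#'
#' Compares contig adjacencies of an alternative arrangement against a
#' reference arrangement over the same contigs: every adjacent contig
#' junction in `alternative` is consistent iff the two contigs are also
#' adjacent in `reference` with the same order and relative orientation (a
#' whole-scaffold flip is consistent). Inconsistent junctions are counted
#' once and attributed to the fixed-size reference window containing the
#' junction midpoint in reference coordinates, split by whether both
#' contigs lie in one reference scaffold (`within_scaffold`) or in two
#' (`between_scaffold`).
#'
#' @param reference,alternative `scaffold_set`s (or `contig_layout`s,
#'   converted via [layout_as_scaffolds()]) over the same contig set.
#' @param window Window size in bp (default 100 kb).
#' @return A `window_report`: list with `windows` (per-window tibble:
#'   `window`, `window_start`, `window_end`, `within_scaffold`,
#'   `between_scaffold`), `totals` (one-row tibble with the window counts
#'   and link totals) and `window_size`. Supports [tidy()] and [glance()].
#' @export
window_inconsistency <- function(reference, alternative, window = 1e5) {
  if (inherits(reference, "contig_layout")) {
    reference <- layout_as_scaffolds(reference)
  }
  if (inherits(alternative, "contig_layout")) {
    alternative <- layout_as_scaffolds(alternative)
  }
  if (!setequal(reference$contig_id, alternative$contig_id)) {
    stop("arrangements cover different contig sets", call. = FALSE)
  }
  lens <- attr(reference, "contig_lengths") %||%
    attr(alternative, "contig_lengths")
  if (is.null(lens)) stop("contig lengths unavailable", call. = FALSE)

  ref <- reference |>
    dplyr::arrange(.data$scaffold_id, .data$position) |>
    dplyr::mutate(length = lens[.data$contig_id],
                  gap = dplyr::coalesce(.data$gap_after, 0))
  ref$ref_start <- cumsum(dplyr::lag(ref$length + ref$gap, default = 0))
  ref$ref_end <- ref$ref_start + ref$length
  total_len <- max(ref$ref_end)

  alt <- dplyr::arrange(alternative, .data$scaffold_id, .data$position)
  look <- function(col) ref[[col]][match(alt$contig_id, ref$contig_id)]
  alt$ref_scaffold <- look("scaffold_id")
  alt$ref_position <- look("position")
  alt$ref_orient <- look("orientation")
  alt$ref_start <- look("ref_start")
  alt$ref_end <- look("ref_end")

  jn <- alt |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::reframe(
      x = utils::head(.data$contig_id, -1),
      ox = utils::head(.data$orientation, -1),
      y = utils::tail(.data$contig_id, -1),
      oy = utils::tail(.data$orientation, -1),
      sx = utils::head(.data$ref_scaffold, -1),
      sy = utils::tail(.data$ref_scaffold, -1),
      px = utils::head(.data$ref_position, -1),
      py = utils::tail(.data$ref_position, -1),
      rx = utils::head(.data$ref_orient, -1),
      ry = utils::tail(.data$ref_orient, -1),
      ex = utils::head(.data$ref_end, -1),
      ey = utils::tail(.data$ref_end, -1),
      bx = utils::head(.data$ref_start, -1),
      by = utils::tail(.data$ref_start, -1))

  totals0 <- tibble::tibble(
    n_junctions = nrow(jn), n_inconsistent = 0L,
    n_within_scaffold = 0L, n_between_scaffold = 0L,
    bins_within = 0L, bins_between = 0L, bins_any = 0L,
    n_windows = as.integer(ceiling(total_len / window)))
  grid <- tibble::tibble(
    window = seq_len(max(1L, totals0$n_windows)),
    window_start = (seq_len(max(1L, totals0$n_windows)) - 1) * window,
    window_end = pmin(total_len,
                      seq_len(max(1L, totals0$n_windows)) * window),
    within_scaffold = 0L, between_scaffold = 0L)
  if (nrow(jn) == 0) {
    return(new_window_report(grid, totals0, window))
  }

  same_scaf <- jn$sx == jn$sy
  rel_x <- jn$ox == jn$rx
  rel_y <- jn$oy == jn$ry
  order_ok <- ifelse(rel_x, jn$py == jn$px + 1, jn$py == jn$px - 1)
  consistent <- same_scaf & (rel_x == rel_y) & order_ok

  bad <- jn[!consistent, ]
  if (nrow(bad)) {
    first_left <- bad$bx <= bad$by
    left_end <- ifelse(first_left, bad$ex, bad$ey)
    right_start <- ifelse(first_left, bad$by, bad$bx)
    mid <- floor((pmax(left_end, right_start) + pmin(left_end, right_start)) / 2)
    win <- pmin(floor(mid / window) + 1, nrow(grid))
    within <- bad$sx == bad$sy
    for (i in seq_len(nrow(bad))) {
      if (within[i]) {
        grid$within_scaffold[win[i]] <- grid$within_scaffold[win[i]] + 1L
      } else {
        grid$between_scaffold[win[i]] <- grid$between_scaffold[win[i]] + 1L
      }
    }
  }
  totals <- tibble::tibble(
    n_junctions = nrow(jn),
    n_inconsistent = sum(!consistent),
    n_within_scaffold = sum(grid$within_scaffold),
    n_between_scaffold = sum(grid$between_scaffold),
    bins_within = sum(grid$within_scaffold > 0),
    bins_between = sum(grid$between_scaffold > 0),
    bins_any = sum(grid$within_scaffold + grid$between_scaffold > 0),
    n_windows = nrow(grid))
  new_window_report(grid, totals, window)
}

new_window_report <- function(windows, totals, window) {
  structure(list(windows = windows, totals = totals, window_size = window),
            class = "window_report")
}

#' @export
print.window_report <- function(x, ...) {
  cat(sprintf(paste0("<window_report> %d windows of %s bp: %d/%d with ",
                     "within-scaffold and %d/%d with between-scaffold ",
                     "inconsistencies (%d links)\n"),
              x$totals$n_windows, format(x$window_size, big.mark = ","),
              x$totals$bins_within, x$totals$n_windows,
              x$totals$bins_between, x$totals$n_windows,
              x$totals$n_inconsistent))
  invisible(x)
}

#' Write / read a restriction map as TSV
#' @param map A `restriction_map`.
#' @param path File path.
#' @export
write_restriction_map <- function(map, path) {
  readr::write_tsv(map[, c("fragment", "length")], path)
  invisible(path)
}

#' @rdname write_restriction_map
#' @export
read_restriction_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(fragment = "i",
                                                      length = "d"))
  new_restriction_map(df$length, site = NA_character_, source = "file")
}
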