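#' Describe one class of repeat elements for genome simulation
#'
#' A repeat class is a family-structured set of interspersed elements
#' (LINE-like, LTR-like, ...). Copies of one family share a consensus
#' sequence up to a per-copy divergence rate; element lengths are drawn from
#' a truncated normal, mimicking the 5'-truncation of real retroelement
#' insertions.
#'
#' @param class Class label, e.g. `"LINE"`, `"LTR"`, `"SINE"`, `"DNA"`, `"Other"`.
#' @param n_copies Number of element copies to place.
#' @param len_mean,len_sd Mean and sd (bp) of the element-length distribution.
#' @param len_min,len_max Truncation bounds (bp) for element lengths.
#' @param n_families Number of element families the copies are drawn from.
#' @param divergence Per-base divergence of each copy from its family
#'   consensus. Tags mapped fully inside a copy of a multi-copy family are
#'   flagged non-unique when `divergence * read_length < 1` (less than one
#'   mismatch-equivalent over the tag, i.e. copies indistinguishable to a
#'   single-best-hit mapper).
#' @return A one-row tibble; rows from several calls can be bound into a
#'   repeat configuration for [simulate_genome()].
#' @export
repeat_class <- function(class, n_copies, len_mean, len_sd,
                         len_min = 100, len_max = 8000,
                         n_families = max(1L, n_copies %/% 10L),
                         divergence = 0.02) {
  stopifnot(n_copies >= 1, len_min > 0, len_max >= len_min,
            n_families >= 1, divergence >= 0, divergence < 1)
  tibble::tibble(class = as.character(class), n_copies = as.integer(n_copies),
                 len_mean = len_mean, len_sd = len_sd,
                 len_min = len_min, len_max = len_max,
                 n_families = as.integer(n_families), divergence = divergence)
}

#' Rat-like repeat landscape configuration
#'
#' Builds a repeat configuration whose total repeat content and class shares
#' emulate a mammalian (rat-like) genome: ~49% of the genome repetitive, with
#' LINEs the largest class (38% of repeat bp, i.e. ~18.9% of the genome),
#' then LTR elements, and element sizes up to 8 kb for LINEs. Per-class copy
#' numbers are derived from the target bp share and the truncated-normal mean
#' element length, so the placed repeat fraction closely matches the target.
#'
#' Copies default to the package-wide 2% divergence: for 50-bp tags that is
#' one mismatch-equivalent per tag, so copies remain distinguishable to a
#' single-best-hit mapper and tags stay unique. Lower a class's divergence
#' below `1/read_length` (e.g. 0.01 for 50-bp tags) to emulate young,
#' unmappable repeat families.
#'
#' @param genome_length Genome length in bp.
#' @param repeat_fraction Target fraction of the genome covered by repeats.
#' @param divergence Per-copy divergence, recycled across the five classes
#'   (LINE, LTR, SINE, DNA, Other).
#' @return A repeat-configuration tibble (one row per class).
#' @export
rat_like_repeats <- function(genome_length, repeat_fraction = 0.49,
                             divergence = 0.02) {
  stopifnot(repeat_fraction > 0, repeat_fraction < 0.95)
  target_bp <- genome_length * repeat_fraction
  divergence <- rep_len(divergence, 5L)
  # shares of repeat bp: LINE and LTR from the annotated landscape
  # (474.6/1240 and 220.9/1240); remaining split over SINE/DNA/Other.
  cfg <- dplyr::bind_rows(
    repeat_class("LINE", 1L, 1000, 2500, 150, 8000, 25L, divergence[1]),
    repeat_class("LTR", 1L, 400, 350, 100, 3000, 40L, divergence[2]),
    repeat_class("SINE", 1L, 150, 60, 60, 400, 8L, divergence[3]),
    repeat_class("DNA", 1L, 250, 180, 80, 2000, 50L, divergence[4]),
    repeat_class("Other", 1L, 350, 400, 60, 4000, 80L, divergence[5])
  )
  share <- c(LINE = 474.6 / 1240, LTR = 220.9 / 1240,
             SINE = 0.20, DNA = 0.12, Other = 1 - 474.6 / 1240 - 220.9 / 1240 - 0.32)
  tmean <- purrr::pmap_dbl(cfg, function(len_mean, len_sd, len_min, len_max, ...) {
    tnorm_mean(len_mean, len_sd, len_min, len_max)
  })
  cfg$n_copies <- as.integer(round(share[cfg$class] * target_bp / tmean))
  cfg
}

#' Simulate a genome with an interspersed repeat landscape
#'
#' Places non-overlapping repeat copies uniformly at random (batched
#' rejection sampling) on a genome of the requested length and, optionally,
#' emits the nucleotide sequence, with each copy derived from its family
#' consensus at the configured divergence.
#'
#' @param length Genome length in bp (>= 10 kb).
#' @param repeat_config Tibble of repeat classes (see [repeat_class()],
#'   [rat_like_repeats()]), or `NULL` for a repeat-free genome.
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   genomes (and byte-identical FASTA/BED output).
#' @param emit_sequence Whether to generate the nucleotide sequence. Defaults
#'   to `TRUE` up to 5 Mb; annotation-only genomes are sufficient (and much
#'   cheaper) for coverage/scaffolding simulations.
#' @param max_rounds Safety cap on rejection-sampling rounds.
#' @return A `genome_model`: list with `sequence` ([Biostrings::DNAString] or
#'   `NULL`), `length`, `repeats` (tibble: `class`, `start`, `end`, `length`,
#'   `identity_group`, `divergence`, `family_size`; 0-based half-open
#'   coordinates), and `repeat_fraction`.
#' @export
simulate_genome <- function(length, repeat_config = NULL, seed = NULL,
                            emit_sequence = length <= 5e6, max_rounds = 200L) {
  stopifnot(length >= 1e4)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      simulate_genome(length, repeat_config, NULL, emit_sequence, max_rounds)))
  }
  length <- as.numeric(length)

  if (is.null(repeat_config) || nrow(repeat_config) == 0) {
    reps <- tibble::tibble(class = character(), start = numeric(),
                           end = numeric(), length = numeric(),
                           identity_group = integer(), divergence = numeric(),
                           family_size = integer())
    seq <- if (emit_sequence) {
      Biostrings::DNAString(paste(random_dna(length), collapse = ""))
    }
    return(new_genome_model(seq, length, reps))
  }

  assert_cols(repeat_config,
              c("class", "n_copies", "len_mean", "len_sd", "len_min",
                "len_max", "n_families", "divergence"), "repeat_config")

  expected_bp <- sum(purrr::pmap_dbl(repeat_config,
    function(n_copies, len_mean, len_sd, len_min, len_max, ...) {
      n_copies * tnorm_mean(len_mean, len_sd, len_min, len_max)
    }))
  if (expected_bp > 0.95 * length) {
    stop(sprintf(paste0("infeasible repeat configuration: requested ~%.0f bp ",
                        "of repeats on a %.0f bp genome (> 95%%)"),
                 expected_bp, length), call. = FALSE)
  }

  fam_counter <- 0L
  elems <- purrr::pmap_dfr(repeat_config,
    function(class, n_copies, len_mean, len_sd, len_min, len_max,
             n_families, divergence) {
      len <- round(rtrunc_normal(n_copies, len_mean, len_sd, len_min, len_max))
      fam <- fam_counter + sample.int(n_families, n_copies, replace = TRUE)
      fam_counter <<- fam_counter + n_families
      tibble::tibble(class = class, length = pmin(pmax(len, len_min), len_max),
                     identity_group = as.integer(fam), divergence = divergence)
    })

  elems$start <- place_without_overlap(elems$length, length, max_rounds)
  elems$end <- elems$start + elems$length
  elems <- dplyr::arrange(elems, .data$start)
  elems <- dplyr::add_count(elems, .data$identity_group, name = "family_size")
  elems <- elems[, c("class", "start", "end", "length", "identity_group",
                     "divergence", "family_size")]

  seq <- if (emit_sequence) genome_sequence_with_repeats(length, elems) else NULL
  new_genome_model(seq, length, elems)
}

#' Construct a genome model from an explicit repeat annotation
#'
#' Lower-level companion to [simulate_genome()] for planting a known repeat
#' landscape (e.g. isolated elements at chosen positions).
#'
#' @param length Genome length in bp.
#' @param repeats Tibble with `class`, `start`, `end` (0-based half-open)
#'   and optionally `identity_group`, `divergence`, `family_size`; missing
#'   columns default to single-copy, zero-divergence elements.
#' @param sequence Optional [Biostrings::DNAString].
#' @return A `genome_model`.
#' @export
genome_model <- function(length, repeats = NULL, sequence = NULL) {
  if (is.null(repeats) || nrow(repeats) == 0) {
    repeats <- tibble::tibble(class = character(), start = numeric(),
                              end = numeric(), length = numeric(),
                              identity_group = integer(),
                              divergence = numeric(), family_size = integer())
  } else {
    assert_cols(repeats, c("class", "start", "end"), "repeats")
    repeats$length <- repeats$end - repeats$start
    if (!"identity_group" %in% names(repeats)) {
      repeats$identity_group <- seq_len(nrow(repeats))
    }
    if (!"divergence" %in% names(repeats)) repeats$divergence <- 0
    if (!"family_size" %in% names(repeats)) {
      repeats <- dplyr::add_count(repeats, .data$identity_group,
                                  name = "family_size")
    }
    stopifnot(all(repeats$length > 0), all(repeats$start >= 0),
              all(repeats$end <= length))
  }
  new_genome_model(sequence, length, repeats)
}

new_genome_model <- function(sequence, length, repeats) {
  structure(list(sequence = sequence, length = length, repeats = repeats,
                 repeat_fraction = sum(repeats$length) / length),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s bp, %d repeat elements (%.1f%% repetitive)%s\n",
              format(x$length, big.mark = ","), nrow(x$repeats),
              100 * x$repeat_fraction,
              if (is.null(x$sequence)) ", annotation only" else ""))
  if (nrow(x$repeats)) {
    tally <- dplyr::summarise(dplyr::group_by(x$repeats, .data$class),
                              n = dplyr::n(), mb = sum(.data$length) / 1e6)
    print(tally)
  }
  invisible(x)
}

# Uniform placement of non-overlapping intervals by batched rejection
# sampling. Elements are processed in descending-length chunks so long
# elements claim contiguous space before short ones fragment it.
# Returns 0-based starts in the input order.
place_without_overlap <- function(lengths, genome_length, max_rounds = 200L) {
  n <- length(lengths)
  start <- rep(NA_real_, n)
  ord <- order(lengths, decreasing = TRUE)
  chunks <- split(ord, ceiling(seq_along(ord) / max(1L, ceiling(n / 20))))
  placed <- IRanges::IRanges()
  for (chunk in chunks) {
    todo <- chunk
    rounds <- 0L
    while (length(todo)) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("could not place all repeat elements without overlap; ",
             "lower the repeat fraction", call. = FALSE)
      }
      prop_start <- floor(stats::runif(length(todo)) *
                            (genome_length - lengths[todo] + 1))
      prop <- IRanges::IRanges(start = prop_start + 1L, width = lengths[todo])
      ok <- which(!IRanges::overlapsAny(prop, placed))
      if (!length(ok)) next
      # resolve intra-batch overlaps greedily along the genome
      ok <- ok[order(prop_start[ok])]
      keep <- logical(length(ok))
      last_end <- -1
      for (i in seq_along(ok)) {
        s <- prop_start[ok[i]]
        if (s > last_end) {
          keep[i] <- TRUE
          last_end <- s + lengths[todo[ok[i]]] - 1
        }
      }
      ok <- ok[keep]
      start[todo[ok]] <- prop_start[ok]
      placed <- c(placed, prop[ok])
      todo <- todo[-ok]
    }
  }
  start
}

random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

genome_sequence_with_repeats <- function(length, elems) {
  base <- random_dna(length)
  if (nrow(elems)) {
    fams <- split(seq_len(nrow(elems)), elems$identity_group)
    for (idx in fams) {
      cons <- random_dna(max(elems$length[idx]))
      for (i in idx) {
        len <- elems$length[i]
        copy <- cons[seq_len(len)]
        nmut <- stats::rbinom(1, len, elems$divergence[i])
        if (nmut > 0) {
          at <- sample.int(len, nmut)
          copy[at] <- random_dna(nmut)
        }
        base[(elems$start[i] + 1):(elems$end[i])] <- copy
      }
    }
  }
  Biostrings::DNAString(paste(base, collapse = ""))
}

#' Write / read genome FASTA and repeat BED6
#'
#' The repeat annotation round-trips through standard BED6: `name` carries
#' the repeat class and `score` the identity group (family id). Coordinates
#' are 0-based half-open on disk, as BED requires.
#'
#' @param genome A `genome_model` with sequence (for FASTA).
#' @param path Output file path.
#' @param chrom Sequence name used in the FASTA/BED records.
#' @return The path, invisibly (writers); a repeats tibble (reader).
#' @export
write_genome_fasta <- function(genome, path, chrom = "chr1") {
  if (is.null(genome$sequence)) {
    stop("genome has no sequence (simulated with emit_sequence = FALSE)",
         call. = FALSE)
  }
  dss <- Biostrings::DNAStringSet(genome$sequence)
  names(dss) <- chrom
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_repeats_bed <- function(genome, path, chrom = "chr1") {
  reps <- if (inherits(genome, "genome_model")) genome$repeats else genome
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = reps$start + 1, end = reps$end),
    name = reps$class, score = reps$identity_group)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  reps <- tibble::tibble(
    class = as.character(gr$name),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    identity_group = as.integer(gr$score))
  reps$length <- reps$end - reps$start
  reps <- dplyr::add_count(reps, .data$identity_group, name = "family_size")
  reps[, c("class", "start", "end", "length", "identity_group", "family_size")]
}
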