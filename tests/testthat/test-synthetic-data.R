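test_that("simulate_genome places the configured repeat landscape", {
  g0 <- simulate_genome(1e6, NULL, seed = 1)
  expect_equal(g0$repeat_fraction, 0)
  expect_equal(nrow(g0$repeats), 0)

  # one LINE class, 100 copies x 5 kb -> half the genome repetitive
  cfg <- repeat_class("LINE", 100L, 5000, 0, 5000, 5000, n_families = 10L)
  g1 <- simulate_genome(1e6, cfg, seed = 2, emit_sequence = FALSE)
  expect_equal(sum(g1$repeats$length), 100 * 5000)
  expect_equal(g1$repeat_fraction, 0.5)
  # annotation accounting is exact and non-overlapping
  ir <- IRanges::IRanges(g1$repeats$start + 1, g1$repeats$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))), 100 * 5000)

  # rat-like landscape: per-class bp tallies within 5 points of the target
  cfg2 <- rat_like_repeats(2e6, repeat_fraction = 0.49)
  g2 <- simulate_genome(2e6, cfg2, seed = 3, emit_sequence = FALSE)
  expect_lt(abs(g2$repeat_fraction - 0.49), 0.05)
  line_bp <- sum(g2$repeats$length[g2$repeats$class == "LINE"])
  expect_lt(abs(line_bp / g2$length - 0.49 * 474.6 / 1240), 0.05)
  expect_lte(max(g2$repeats$length[g2$repeats$class == "LINE"]), 8000)

  # infeasible configuration errors out
  expect_error(
    simulate_genome(1e4, repeat_class("LINE", 100L, 5000, 0, 5000, 5000)),
    "infeasible")
})

test_that("simulate_genome is reproducible and writes byte-identical files", {
  cfg <- rat_like_repeats(5e4, 0.3)
  g1 <- simulate_genome(5e4, cfg, seed = 42)
  g2 <- simulate_genome(5e4, cfg, seed = 42)
  expect_identical(g1$repeats, g2$repeats)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  b1 <- tempfile(fileext = ".bed")
  write_repeats_bed(g1, b1)
  back <- read_repeats_bed(b1)
  expect_equal(back$start, g1$repeats$start)
  expect_equal(back$end, g1$repeats$end)
  expect_equal(back$class, g1$repeats$class)
  expect_equal(back$identity_group, g1$repeats$identity_group)
})

test_that("fragment_into_contigs conserves every base and records truth", {
  g <- simulate_genome(1e6, NULL, seed = 5, emit_sequence = FALSE)
  one <- fragment_into_contigs(g, 1, seed = 6)
  expect_equal(nrow(one), 1)
  expect_equal(one$length, 1e6)
  expect_true(is.na(one$gap_after))

  lay <- fragment_into_contigs(g, 10, gap_model = list(mean_gap = 1000),
                               seed = 7)
  expect_equal(nrow(lay), 10)
  expect_equal(sum(lay$length) + sum(lay$gap_after, na.rm = TRUE), 1e6)
  expect_equal(lay$rank, 1:10)
  # contigs tile the genome in order without overlap
  expect_true(all(lay$start[-1] > lay$end[-10]))

  lay2 <- fragment_into_contigs(g, 10, gap_model = list(mean_gap = 1000),
                                seed = 7)
  expect_identical(lay, lay2)

  expect_error(fragment_into_contigs(1e4, 100, list(mean_gap = 500)),
               "cannot fit")

  # AGP-like table round trip
  f <- tempfile(fileext = ".tsv")
  write_layout_agp(lay, f)
  back <- read_layout_agp(f)
  expect_equal(as.data.frame(back), as.data.frame(lay[, names(back)]),
               ignore_attr = TRUE)
})

test_that("simulate_library plants artifact classes at the requested rates", {
  g <- simulate_genome(1e6, NULL, seed = 8, emit_sequence = FALSE)
  sp0 <- library_spec("clean", 3000, 300, 2000)
  p0 <- simulate_library(g, sp0, seed = 9)
  expect_equal(nrow(p0), 2000)
  expect_true(all(p0$truth_category == "consistent"))
  expect_true(all(p0$fwd_unique & p0$rev_unique))

  sp <- library_spec("dirty", 3000, 300, 2e4, duplicate_fraction = 0.5,
                     remote_fraction = 0.1, inverted_fraction = 0.02,
                     everted_fraction = 0.02)
  p <- simulate_library(g, sp, seed = 10)
  tab <- table(p$truth_category) / nrow(p)
  expect_lt(abs(tab[["duplicate"]] - 0.5), 0.02)
  expect_lt(abs(tab[["remote"]] - 0.1), 0.01)
  # duplicates are exact coordinate clones of a previously emitted pair
  dup <- p[p$truth_category == "duplicate", ]
  src <- p[dup$duplicate_of, ]
  expect_true(all(src$truth_category != "duplicate"))
  expect_equal(dup$fwd_pos, src$fwd_pos)
  expect_equal(dup$rev_pos, src$rev_pos)
  expect_equal(dup$fwd_strand, src$fwd_strand)
  # remote pairs land at least 100 kb away
  rem <- p[p$truth_category == "remote", ]
  expect_true(all(abs(rem$rev_pos - rem$fwd_pos) >= 1e5))
})

test_that("empirical insert distribution matches the configured one", {
  g <- simulate_genome(1e7, NULL, seed = 11, emit_sequence = FALSE)
  sp <- library_spec("20kb", 20000, 2000, 1e5)
  p <- simulate_library(g, sp, seed = 12)
  span <- pmax(p$fwd_pos, p$rev_pos) + p$read_len - pmin(p$fwd_pos, p$rev_pos)
  expect_lt(abs(median(span) - 20000) / 20000, 0.01)

  # KS distance against the configured truncated normal < 0.03
  lo <- 100; hi <- 1e5
  pn <- function(q) {
    (pnorm(q, 20000, 2000) - pnorm(lo, 20000, 2000)) /
      (pnorm(hi, 20000, 2000) - pnorm(lo, 20000, 2000))
  }
  ks <- suppressWarnings(stats::ks.test(span, pn))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("tag uniqueness reflects multi-copy low-divergence repeats", {
  reps <- tibble::tibble(
    class = c("LINE", "LINE", "DNA"),
    start = c(1000, 5000, 9000), end = c(3000, 7000, 11000),
    identity_group = c(1L, 1L, 2L),       # LINE family has 2 copies
    divergence = c(0.01, 0.01, 0.01))
  g <- genome_model(2e5, reps)
  sp <- library_spec("t", 500, 0, 10, read_length = 50L)
  p <- simulate_library(g, sp, seed = 13)
  # override coordinates to probe the rule directly
  probe <- make_pairs(fwd_pos = c(1500, 9500, 950, 2980),
                      rev_pos = c(4000, 12000, 4000, 4000))
  amb <- matescaffold:::ambiguous_ranges(g$repeats, 50L)
  uq <- matescaffold:::tag_is_unique(probe$fwd_pos, 50L, amb)
  # inside 2-copy LINE -> non-unique; inside single-copy DNA -> unique;
  # fully in unique flank -> unique; straddling the repeat edge -> unique
  expect_equal(uq, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("pair sets round-trip through TSV and SAM", {
  g <- simulate_genome(5e5, NULL, seed = 14, emit_sequence = FALSE)
  sp <- library_spec("rt", 5000, 500, 1000, remote_fraction = 0.05,
                     inverted_fraction = 0.05, everted_fraction = 0.05,
                     duplicate_fraction = 0.2)
  p <- simulate_library(g, sp, seed = 15)

  tsv <- tempfile(fileext = ".tsv")
  write_pairset(p, tsv, "tsv")
  expect_equal(as.data.frame(read_pairset(tsv, "tsv")), as.data.frame(p))

  sam <- tempfile(fileext = ".sam")
  write_pairset(p, sam, "sam", chrom_lengths = c(chr1 = g$length))
  back <- read_pairset(sam, "sam")
  expect_equal(as.data.frame(back), as.data.frame(p))

  # SAM flag bits: everted pair has both reads reverse on their own strand
  # convention (0x10 self-reverse / 0x20 mate-reverse mirrored)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  ev_id <- p$pair_id[p$truth_category == "everted"][1]
  recs <- body[startsWith(body, sprintf("rt_%d\t", ev_id))]
  flags <- as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2))
  r1 <- flags[bitwAnd(flags, 0x40) > 0]
  r2 <- flags[bitwAnd(flags, 0x80) > 0]
  ev <- p[p$pair_id == ev_id, ]
  expect_equal(bitwAnd(r1, 0x10) > 0, ev$fwd_strand == "-")
  expect_equal(bitwAnd(r1, 0x20) > 0, ev$rev_strand == "-")
  expect_equal(bitwAnd(r2, 0x10) > 0, ev$rev_strand == "-")

  # empty set: header-only file plus a warning
  empty <- p[0, ]
  f <- tempfile(fileext = ".sam")
  expect_warning(write_pairset(empty, f, "sam",
                               chrom_lengths = c(chr1 = g$length)),
                 "empty")
  expect_true(all(startsWith(readLines(f), "@")))
})
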