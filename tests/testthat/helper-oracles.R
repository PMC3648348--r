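# Independent oracles and small fixture builders used across test files.

# Quick pair-table builder with sensible defaults.
make_pairs <- function(fwd_pos, rev_pos, fwd_strand = "+", rev_strand = "-",
                       fwd_chrom = "chr1", rev_chrom = "chr1",
                       read_len = 50L, fwd_unique = TRUE, rev_unique = TRUE,
                       library = "lib", pair_id = seq_along(fwd_pos)) {
  tibble::tibble(pair_id = pair_id, library = library,
                 fwd_chrom = fwd_chrom, fwd_pos = fwd_pos,
                 fwd_strand = fwd_strand, rev_chrom = rev_chrom,
                 rev_pos = rev_pos, rev_strand = rev_strand,
                 read_len = read_len, truth_category = "consistent",
                 duplicate_of = NA_integer_,
                 fwd_unique = fwd_unique, rev_unique = rev_unique)
}

# Rule-by-rule brute-force re-check of the classification cascade,
# deliberately written as a per-pair loop independent of the vectorized
# implementation.
oracle_classify <- function(pairs, lo, hi) {
  n <- nrow(pairs)
  clonal <- logical(n)
  seen <- character(0)
  for (i in order(pairs$pair_id)) {
    sig <- paste(pairs$fwd_chrom[i], pairs$fwd_pos[i], pairs$fwd_strand[i],
                 pairs$rev_chrom[i], pairs$rev_pos[i], pairs$rev_strand[i])
    if (sig %in% seen) clonal[i] <- TRUE else seen <- c(seen, sig)
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    if (clonal[i]) { cls[i] <- "clonal"; next }
    if (!pairs$fwd_unique[i] || !pairs$rev_unique[i]) {
      cls[i] <- "ambiguous"; next
    }
    if (pairs$fwd_chrom[i] != pairs$rev_chrom[i]) { cls[i] <- "remote"; next }
    if (pairs$fwd_pos[i] <= pairs$rev_pos[i]) {
      sl <- pairs$fwd_strand[i]; sr <- pairs$rev_strand[i]
      span <- pairs$rev_pos[i] + pairs$read_len[i] - pairs$fwd_pos[i]
    } else {
      sl <- pairs$rev_strand[i]; sr <- pairs$fwd_strand[i]
      span <- pairs$fwd_pos[i] + pairs$read_len[i] - pairs$rev_pos[i]
    }
    cls[i] <- if (sl == "+" && sr == "-") {
      if (span >= lo && span <= hi) "consistent" else "remote"
    } else if (sl == "-" && sr == "+") "everted" else "inverted"
  }
  cls
}

# Brute-force N50: try every length as the threshold.
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  }
  min(lengths)
}

# Random uniform DNA string of length n.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# An error-free library simulated on a genome, classified and ready to use.
simulate_classified <- function(genome, name, insert_median, insert_spread,
                                n_pairs, seed, read_length = 50L, ...) {
  sp <- library_spec(name, insert_median, insert_spread, n_pairs,
                     read_length = read_length, ...)
  p <- mark_duplicates(simulate_library(genome, sp, seed = seed))
  st <- estimate_insert_distribution(p)
  b <- insert_bounds(st)
  if (b[1] >= b[2]) b <- b + c(-1, 1)  # degenerate fixed-insert libraries
  list(pairs = classify_pairs(p, b), stats = st)
}

# Exhaustive-search oracle for map alignment: recursively tries every
# monotone sequence of skips and <=max_merge block matches and returns the
# best score under the same scoring as align_maps.
oracle_align_score <- function(av, bv, tol = 0.05, max_merge = 2,
                               gap_penalty = 1) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0) best <- max(best, rec(i - 1, j) - gap_penalty * av[i])
    if (j > 0) best <- max(best, rec(i, j - 1) - gap_penalty * bv[j])
    for (k in seq_len(min(max_merge, i))) {
      for (l in seq_len(min(max_merge, j))) {
        sa <- sum(av[(i - k + 1):i]); sb <- sum(bv[(j - l + 1):j])
        if (abs(sa - sb) <= tol * max(sa, sb)) {
          best <- max(best, rec(i - k, j - l) + (sa + sb) / 2)
        }
      }
    }
    best
  }
  rec(length(av), length(bv))
}
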