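PAIR_COLS <- c("pair_id", "library", "fwd_chrom", "fwd_pos", "fwd_strand",
               "rev_chrom", "rev_pos", "rev_strand", "read_len",
               "truth_category", "duplicate_of", "fwd_unique", "rev_unique")

#' Write and read pair sets (TSV or SAM)
#'
#' The TSV form is the package's canonical 0-based pair table and
#' round-trips losslessly. The SAM form writes two records per pair with
#' standard flag bits (0x1 paired, 0x40/0x80 first/second of pair,
#' 0x10/0x20 self/mate reverse strand), 1-based positions, and carries the
#' simulator's truth annotation in optional tags (`tc:Z` truth category,
#' `df:i` duplicate source, `uf:i`/`ur:i` tag uniqueness) so it also
#' round-trips. Reading SAM goes through Rsamtools.
#'
#' @param pairs A pair tibble (see [simulate_library()]).
#' @param path Output path.
#' @param format `"tsv"` or `"sam"`.
#' @param chrom_lengths Named vector of reference lengths for the SAM
#'   header (required for `format = "sam"`).
#' @return The path (writers) / a pair tibble (readers), invisibly for writers.
#' @export
write_pairset <- function(pairs, path, format = c("tsv", "sam"),
                          chrom_lengths = NULL) {
  format <- match.arg(format)
  if (nrow(pairs) == 0) {
    warning("writing an empty pair set (header only)", call. = FALSE)
  }
  if (format == "tsv") {
    cols <- intersect(PAIR_COLS, names(pairs))
    readr::write_tsv(pairs[, cols], path)
    return(invisible(path))
  }
  if (is.null(chrom_lengths)) {
    stop("chrom_lengths is required for SAM output", call. = FALSE)
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  lines <- character(0)
  if (nrow(pairs) > 0) {
    fwd_rev <- pairs$fwd_strand == "-"
    rev_rev <- pairs$rev_strand == "-"
    flag1 <- 0x1 + 0x40 + 0x10 * fwd_rev + 0x20 * rev_rev
    flag2 <- 0x1 + 0x80 + 0x10 * rev_rev + 0x20 * fwd_rev
    same <- pairs$fwd_chrom == pairs$rev_chrom
    tlen1 <- ifelse(same, ifelse(pairs$fwd_pos <= pairs$rev_pos, 1, -1) *
                      pair_span(pairs), 0)
    cigar <- sprintf("%dM", pairs$read_len)
    dup_of <- col_or(pairs, "duplicate_of", rep(NA_integer_, nrow(pairs)))
    tags1 <- sprintf("tc:Z:%s\tdf:i:%d\tuf:i:%d\tur:i:%d",
                     col_or(pairs, "truth_category", rep("NA", nrow(pairs))),
                     ifelse(is.na(dup_of), -1L, dup_of),
                     as.integer(pairs$fwd_unique),
                     as.integer(pairs$rev_unique))
    qname <- sprintf("%s_%d", pairs$library, pairs$pair_id)
    l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t*\t*\t%s",
                  qname, as.integer(flag1), pairs$fwd_chrom,
                  as.integer(pairs$fwd_pos + 1), cigar,
                  ifelse(same, "=", pairs$rev_chrom),
                  as.integer(pairs$rev_pos + 1), as.integer(tlen1), tags1)
    l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t*\t*",
                  qname, as.integer(flag2), pairs$rev_chrom,
                  as.integer(pairs$rev_pos + 1), cigar,
                  ifelse(same, "=", pairs$fwd_chrom),
                  as.integer(pairs$fwd_pos + 1), as.integer(-tlen1))
    lines <- c(rbind(l1, l2))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_pairset
#' @export
read_pairset <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(readr::read_tsv(path, col_types = readr::cols(
      pair_id = "i", library = "c", fwd_chrom = "c", fwd_pos = "d",
      fwd_strand = "c", rev_chrom = "c", rev_pos = "d", rev_strand = "c",
      read_len = "i", truth_category = "c", duplicate_of = "i",
      fwd_unique = "l", rev_unique = "l", .default = "?")))
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p1 <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("tc", "df", "uf", "ur"))
  b <- Rsamtools::scanBam(bam, param = p1)[[1]]
  first <- bitwAnd(b$flag, 0x40) > 0
  read_len <- as.integer(sub("M$", "", b$cigar[first][1]))
  qn1 <- b$qname[first]
  ord2 <- match(qn1, b$qname[!first])
  tibble::tibble(
    pair_id = as.integer(sub(".*_", "", qn1)),
    library = sub("_[0-9]+$", "", qn1),
    fwd_chrom = as.character(b$rname[first]),
    fwd_pos = b$pos[first] - 1,
    fwd_strand = ifelse(bitwAnd(b$flag[first], 0x10) > 0, "-", "+"),
    rev_chrom = as.character(b$rname[!first])[ord2],
    rev_pos = (b$pos[!first] - 1)[ord2],
    rev_strand = ifelse(bitwAnd(b$flag[first], 0x20) > 0, "-", "+"),
    read_len = read_len,
    truth_category = as.character(b$tag$tc[first]),
    duplicate_of = ifelse(b$tag$df[first] < 0, NA_integer_, b$tag$df[first]),
    fwd_unique = b$tag$uf[first] == 1L,
    rev_unique = b$tag$ur[first] == 1L) |>
    dplyr::arrange(.data$pair_id)
}
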