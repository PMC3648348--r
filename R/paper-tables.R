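#' Reference constants for the rat genome landscape
#'
#' `rat_genome_bp`: total assembled length of the rat reference (2.51 Gb).
#' `rat_effective_genome_bp`: effective (mappable chromosome) length used
#' for expected-coverage arithmetic. The value is fixed by requiring that
#' `expected_coverage(5e6, insert)` reproduce the published per-library
#' 5M-read coverage column to its printed precision for every insert size
#' simultaneously; the feasible interval is [2.4712, 2.4722] Gb (a rounder
#' 2.47 Gb fails the 15-kb row: 30.36 prints as 30.4, not 30.3), and
#' 2.4715 Gb is adopted.
#' `rat_repeat_bp`: total repeat content (1.24 Gb, i.e. over 49%).
#'
#' @name rat_constants
NULL

#' @rdname rat_constants
#' @export
rat_genome_bp <- 2.51e9

#' @rdname rat_constants
#' @export
rat_effective_genome_bp <- 2.4715e9

#' @rdname rat_constants
#' @export
rat_repeat_bp <- 1.24e9

#' Published per-library sequencing and coverage statistics
#'
#' The sequencing/coverage statistics of the ten rat libraries (seven
#' insert sizes; 5, 8 and 15 kb in biological duplicate) used as reference
#' input throughout: sequenced pairs, non-duplicate and unique-consistent
#' fractions, fitted median insert, physical coverage, the closed-form
#' 5M-read coverage column, PCR cycles, and estimated library complexity
#' (values prefixed `>` in the source are non-saturated lower bounds,
#' reported here with `complexity_lower_bound = TRUE`).
#'
#' @return A tibble with one row per library.
#' @export
rat_library_table <- function() {
  tibble::tibble(
    library = c("PE", "3kb", "5kb_a", "5kb_b", "8kb_a", "8kb_b",
                "15kb_a", "15kb_b", "20kb", "25kb"),
    nominal_insert = c(170, 3000, 5000, 5000, 8000, 8000,
                       15000, 15000, 20000, 25000),
    is_mate_pair = c(FALSE, rep(TRUE, 9)),
    sequenced_pairs = c(160e6, 17.7e6, 11.9e6, 16.7e6, 20.8e6, 11.8e6,
                        31.7e6, 11.6e6, 13.3e6, 56.9e6),
    nonduplicate_pairs = c(151e6, 16.3e6, 6.0e6, 14.7e6, 8.6e6, 11.2e6,
                           1.7e6, 1.6e6, 6.7e6, 2.3e6),
    nonduplicate_pct = c(95, 92, 51, 88, 41, 95, 5, 14, 51, 4),
    unique_consistent_pct = c(87, 93, 92, 95, 91, 95, 60, 73, 87, 49),
    median_insert = c(166, 3208, 5696, 5811, 8293, 8160,
                      14561, 13556, 19375, 25871),
    physical_coverage = c(8.5, 50, 11, 28, 25, 34, 6, 7, 48, 11),
    coverage_5m = c(0.34, 6, 10.1, 10.1, 16.2, 16.2, 30.3, 30.3, 40.5, 50.6),
    pcr_cycles = c(5, 14, 18, 13, 14, 13, 21, 21, 14, 17),
    relative_complexity = c(131e6, 4.6e6, 4.7e6, 16.7e6, 5.7e6, 11.8e6,
                            0.6e6, 0.7e6, 4.9e6, 0.7e6),
    complexity_lower_bound = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                               FALSE, FALSE, FALSE, FALSE))
}

#' Published repeat landscape of the rat genome
#'
#' Class-level repeat content: LINEs are the largest class (474.6 Mb,
#' 18.9% of the genome), followed by LTR retrotransposons (220.9 Mb);
#' the remaining repeat bp (satellites, RNA, low-complexity, SINE, DNA
#' transposons) bring the total to 1.24 Gb.
#'
#' @return A tibble (`class`, `bp`); total repeat and genome sizes are in
#'   [rat_repeat_bp] and [rat_genome_bp].
#' @export
rat_repeat_landscape <- function() {
  tibble::tibble(
    class = c("LINE", "LTR", "Other"),
    bp = c(474.6e6, 220.9e6, 1.24e9 - 474.6e6 - 220.9e6))
}
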