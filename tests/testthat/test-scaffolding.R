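test_that("n50 satisfies its definition exactly", {
  expect_equal(n50(c(10, 6, 4, 2)), 6)   # 10+6 = 16 >= 11; 10 alone < 11
  expect_equal(n50(5), 5)
  expect_equal(n50(rep(7, 13)), 7)
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(3, 0)), "positive")
  # equals brute force over all thresholds on random small inputs
  set.seed(70)
  for (i in 1:30) {
    lens <- sample(1:50, sample(1:20, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("build_link_graph aggregates inter-contig pairs into end edges", {
  # two contigs, facing-in pairs near the junction
  lay <- fragment_into_contigs(1e5, 2, list(mean_gap = 100), seed = 71)
  gap <- lay$gap_after[1]
  endA <- lay$end[1]
  n <- 10
  p <- make_pairs(fwd_pos = endA - 500 + seq_len(n),
                  rev_pos = endA + gap + 2400 + seq_len(n),
                  library = "3kb")
  p <- classify_pairs(p, c(500, 20000))
  m <- map_pairs_to_contigs(p, lay)
  g <- build_link_graph(m, lay, c("3kb" = 3000), min_support = 1)
  expect_equal(nrow(g), 1)
  expect_equal(g$support, 10L)
  expect_equal(g$end_a, "R")
  expect_equal(g$end_b, "L")
  # gap estimate from coordinate arithmetic: insert - d_a - d_b, with
  # d_a = endA - fwd_pos = 500 - i and d_b = (rev lpos) + r = 2450 + i,
  # so every supporting pair implies exactly 50 bp
  expect_equal(g$gap_raw, 50)

  # min_support filters weak edges
  g5 <- build_link_graph(m[1:4, ], lay, c("3kb" = 3000), min_support = 5)
  expect_equal(nrow(g5), 0)

  # negative implied gaps are kept but floored in the estimate
  povl <- classify_pairs(make_pairs(fwd_pos = endA - 2900,
                                    rev_pos = endA + gap + 200,
                                    library = "3kb"), c(500, 20000))
  movl <- map_pairs_to_contigs(povl, lay)
  govl <- build_link_graph(movl, lay, c("3kb" = 3000), min_support = 1)
  expect_equal(nrow(govl), 1)
  # d_a = 2900, d_b = 250: implied gap = 3000 - 3150 = -150
  expect_equal(govl$gap_raw, -150)
  expect_equal(govl$gap_estimate, 1)

  # unknown contig errors
  bad <- m; bad$fwd_contig[1] <- "ctg99999"
  expect_error(build_link_graph(bad, lay, c("3kb" = 3000)), "absent")
})

test_that("greedy_scaffold reconstructs an error-free path and is conservative", {
  g <- simulate_genome(1e6, NULL, seed = 72, emit_sequence = FALSE)
  lay <- fragment_into_contigs(g, 10, list(mean_gap = 300), seed = 73)
  sim <- simulate_classified(g, "3kb", 3000, 300, 3e4, seed = 74)
  m <- map_pairs_to_contigs(sim$pairs, lay)
  gr <- build_link_graph(m, lay, c("3kb" = sim$stats$median),
                         min_support = 3)
  sc <- greedy_scaffold(gr)
  acc <- evaluate_against_truth(sc, lay)
  expect_equal(acc$misjoins, 0)
  expect_equal(acc$correct_joins, 9)
  expect_equal(scaffold_metrics(sc)$n_scaffolds, 1)
  # contig conservation
  expect_setequal(sc$contig_id, lay$contig_id)
  expect_equal(nrow(sc), nrow(lay))

  # no edges -> every contig its own scaffold
  sc0 <- greedy_scaffold(build_link_graph(m[0, ], lay,
                                          c("3kb" = 3000)))
  expect_equal(scaffold_metrics(sc0)$n_scaffolds, nrow(lay))
  expect_equal(glance(sc0)$n50, n50(lay$length))
})

test_that("the support-ratio rule skips planted chimeric edges", {
  lens <- c(ctgA = 10000, ctgB = 10000, ctgC = 10000)
  edges <- tibble::tibble(
    contig_a = c("ctgA", "ctgA"), end_a = c("R", "R"),
    contig_b = c("ctgB", "ctgC"), end_b = c("L", "L"),
    library = "5kb", support = c(50L, 2L),
    gap_raw = c(100, 100), gap_estimate = c(100, 100))
  g <- matescaffold:::new_scaffold_graph(edges, lens, c("5kb" = 5000))
  sc <- greedy_scaffold(g, library_order = "5kb", ratio = 0.7)
  joined <- sc |> dplyr::count(scaffold_id)
  # true edge (support 50) used, chimeric edge (2) skipped: ratio 2/50 fine
  # but its end is then occupied
  expect_equal(sort(joined$n, decreasing = TRUE), c(2, 1))
  two <- sc$contig_id[sc$scaffold_id ==
                        joined$scaffold_id[which.max(joined$n)]]
  expect_setequal(two, c("ctgA", "ctgB"))

  # near-tied competing edges make the end ambiguous: nothing joined
  edges2 <- edges
  edges2$support <- c(50L, 45L)
  g2 <- matescaffold:::new_scaffold_graph(edges2, lens, c("5kb" = 5000))
  sc2 <- greedy_scaffold(g2, library_order = "5kb", ratio = 0.7)
  expect_equal(scaffold_metrics(sc2)$n_scaffolds, 3)
})

test_that("error-free links reconstruct random layouts with zero misjoins", {
  # property over 20 random layouts at >= 10x link coverage
  for (i in 1:20) {
    g <- simulate_genome(3e5, NULL, seed = 100 + i, emit_sequence = FALSE)
    n_ctg <- sample(5:12, 1)
    lay <- fragment_into_contigs(g, n_ctg, list(mean_gap = 200),
                                 seed = 200 + i, min_contig = 5000)
    sim <- simulate_classified(g, "8kb", 8000, 800, 12000, seed = 300 + i)
    m <- map_pairs_to_contigs(sim$pairs, lay)
    gr <- build_link_graph(m, lay, c("8kb" = sim$stats$median),
                           min_support = 3)
    sc <- greedy_scaffold(gr)
    acc <- evaluate_against_truth(sc, lay)
    expect_equal(acc$misjoins, 0)
    expect_equal(acc$orientation_errors, 0)
    expect_setequal(sc$contig_id, lay$contig_id)
  }
})

test_that("evaluate_against_truth partitions joins", {
  lay <- fragment_into_contigs(1e5, 4, list(mean_gap = 100), seed = 75)
  perfect <- layout_as_scaffolds(lay)
  acc <- evaluate_against_truth(perfect, lay)
  expect_equal(acc$correct_joins, 3)
  expect_equal(acc$misjoins, 0)
  expect_equal(acc$missed_joins, 0)

  # one flipped contig in an otherwise true path -> orientation errors
  flipped <- perfect
  flipped$orientation[2] <- "-"
  accf <- evaluate_against_truth(flipped, lay)
  expect_equal(accf$orientation_errors, 2)  # both joins touching contig 2
  expect_equal(accf$misjoins, 0)

  # random pairing of contigs: essentially no correct joins
  shuffled <- perfect
  shuffled$contig_id <- perfect$contig_id[c(3, 1, 4, 2)]
  accs <- evaluate_against_truth(shuffled, lay)
  expect_equal(accs$correct_joins, 0)

  # a whole reversed scaffold is still correct
  rev_sc <- perfect
  rev_sc$contig_id <- rev(perfect$contig_id)
  rev_sc$orientation <- "-"
  rev_sc$gap_after <- c(rev(perfect$gap_after[-4]), NA)
  accr <- evaluate_against_truth(rev_sc, lay)
  expect_equal(accr$correct_joins, 3)

  expect_error(evaluate_against_truth(perfect[1:3, ], lay), "different")
})

test_that("combination_sweep ranks combinations and is idempotent", {
  g <- simulate_genome(2e6, NULL, seed = 76, emit_sequence = FALSE)
  lay <- fragment_into_contigs(g, 150, list(mean_gap = 400), seed = 77,
                               min_contig = 2000)
  libs <- list(
    "3kb" = simulate_library(g, library_spec("3kb", 3000, 300, 4e4),
                             seed = 78),
    "15kb" = simulate_library(g, library_spec("15kb", 15000, 1500, 1e4),
                              seed = 79))
  sw <- combination_sweep(libs, lay, 2e6, target_coverage = 8.5,
                          min_support = 3, seed = 80)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$n50, sort(sw$n50, decreasing = TRUE))
  # smallest-first combination stays misjoin-free on error-free links
  expect_equal(sw$misjoins[sw$combination == "3kb+15kb"], 0)
  # a library combined with itself equals the single-library run
  sw2 <- combination_sweep(libs["3kb"], lay, 2e6, target_coverage = 8.5,
                           combinations = list(c("3kb", "3kb"), "3kb"),
                           min_support = 3, seed = 80)
  expect_equal(sw2$n50[1], sw2$n50[2])
  expect_equal(sw2$n_scaffolds[1], sw2$n_scaffolds[2])
})
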