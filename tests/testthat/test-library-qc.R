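test_that("insert distribution is estimated from qualifying pairs only", {
  p <- make_pairs(fwd_pos = seq(0, by = 10, length.out = 150),
                  rev_pos = seq(2950, by = 10, length.out = 150),
                  pair_id = 1:150)
  st <- estimate_insert_distribution(p)
  expect_equal(st$median, 3000)
  expect_equal(st$p1, 3000)
  expect_equal(st$p99, 3000)

  # too few qualifying pairs: error names the count
  expect_error(estimate_insert_distribution(p[1:50, ]), "50 qualifying")

  set.seed(40)
  n <- 1e5
  span <- round(rnorm(n, 20000, 2000))
  big <- make_pairs(fwd_pos = round(runif(n, 0, 1e7)),
                    rev_pos = 0, pair_id = 1:n)
  big$rev_pos <- big$fwd_pos + span - big$read_len
  st2 <- estimate_insert_distribution(big)
  expect_lt(abs(st2$median - 20000) / 20000, 0.01)
  expect_lt(st2$p1, st2$median)
  expect_gt(st2$p99, st2$median)

  # planted remote pairs at 10 Mb span are excluded; median unchanged
  remote <- make_pairs(fwd_pos = round(runif(5000, 0, 1e6)), rev_pos = 0,
                       pair_id = n + 1:5000)
  remote$rev_pos <- remote$fwd_pos + 1e7
  st3 <- estimate_insert_distribution(dplyr::bind_rows(big, remote))
  expect_equal(st3$median, st2$median)
  expect_equal(st3$n, st2$n)
})

test_that("complexity curve saturates at the true molecule count", {
  # all-distinct library: the curve is the identity line
  p <- make_pairs(fwd_pos = seq(0, by = 100, length.out = 1000),
                  rev_pos = seq(5000, by = 100, length.out = 1000))
  cc <- complexity_curve(p, grid = c(100, 500, 1000), replicates = 2,
                         seed = 41)
  expect_equal(cc$unique_nonclonal, c(100, 500, 1000))
  expect_identical(cc, complexity_curve(p, grid = c(100, 500, 1000),
                                        replicates = 2, seed = 41))

  # U = 1e4 distinct molecules sampled with replacement to 1e5:
  # curve follows U(1 - (1 - 1/U)^n)
  set.seed(42)
  U <- 1e4
  mols <- make_pairs(fwd_pos = sample(1e8, U), rev_pos = sample(1e8, U),
                     pair_id = 1:U)
  lib <- mols[sample.int(U, 1e5, replace = TRUE), ]
  lib$pair_id <- seq_len(nrow(lib))
  grid <- round(seq(1e4, 1e5, length.out = 8))
  cc2 <- complexity_curve(lib, grid = grid, replicates = 2, seed = 43)
  closed_form <- U * (1 - (1 - 1 / U)^grid)
  expect_true(all(abs(cc2$unique_nonclonal - closed_form) / closed_form
                  < 0.02))

  # saturation fit recovers U within 10%
  fit <- estimate_max_unique(cc2)
  expect_false(fit$lower_bound)
  expect_lt(abs(fit$estimate - U) / U, 0.10)

  # identity line: no saturation -> lower bound at the observed maximum
  fit0 <- estimate_max_unique(cc)
  expect_true(fit0$lower_bound)
  expect_equal(fit0$estimate, 1000)

  # degenerate two-point grid
  expect_error(estimate_max_unique(cc[1:2, ]), "3 grid points")

  # tidy/glance accessors
  expect_equal(glance(fit)$lower_bound, FALSE)
  expect_equal(tidy(fit)$term, "C")
})

test_that("physical coverage is span bookkeeping over qualifying pairs", {
  p <- classify_pairs(make_pairs(fwd_pos = seq(0, by = 10, length.out = 100),
                                 rev_pos = seq(9950, by = 10,
                                               length.out = 100)),
                      c(500, 20000))
  cov <- physical_coverage(p, 1e6)
  expect_equal(cov$physical_coverage, 1.0)   # 100 x 10 kb on 1 Mb
  expect_equal(cov$pairs_used, 100)

  expect_equal(physical_coverage(p[0, ], 1e6)$physical_coverage, 0)
  expect_error(physical_coverage(p, 0), "genome_length")

  # additivity over disjoint sets
  a <- p[1:40, ]; b <- p[41:100, ]
  expect_equal(physical_coverage(a, 1e6)$physical_coverage +
                 physical_coverage(b, 1e6)$physical_coverage,
               cov$physical_coverage)

  # simulated 20 kb library at expectation 5x
  g <- simulate_genome(1e7, NULL, seed = 44, emit_sequence = FALSE)
  n <- round(5 * 1e7 / 20000)
  sim <- simulate_classified(g, "20kb", 20000, 2000, n, seed = 45)
  cov5 <- physical_coverage(sim$pairs, 1e7, sim$stats)
  expect_lt(abs(cov5$physical_coverage - 5) / 5, 0.02)
})

test_that("expected coverage arithmetic is exact and linear", {
  expect_equal(expected_coverage(5e6, 20000, 2.47e9), 40.48583, tolerance = 1e-6)
  expect_equal(round(expected_coverage(5e6, 170, 2.47e9), 2), 0.34)
  # identity: n = G / insert gives exactly 1x
  expect_equal(expected_coverage(2.47e9 / 20000, 20000, 2.47e9), 1.0)
  # linearity in both n_pairs and insert size
  set.seed(46)
  n <- runif(5, 1e5, 1e7); i <- runif(5, 170, 25000)
  expect_equal(expected_coverage(3 * n, i), 3 * expected_coverage(n, i))
  expect_equal(expected_coverage(n, 2 * i), 2 * expected_coverage(n, i))
})

test_that("normalization hits the target coverage to within one span", {
  g <- simulate_genome(2e6, NULL, seed = 47, emit_sequence = FALSE)
  n <- round(48 * 2e6 / 20000)
  sim <- simulate_classified(g, "20kb", 20000, 2000, n, seed = 48)
  sub <- normalize_to_coverage(sim$pairs, 2e6, 8.5, sim$stats, seed = 49)
  got <- physical_coverage(sub, 2e6, sim$stats)$physical_coverage
  expect_gte(got, 8.5)
  expect_lt(got, 8.5 + 21000 / 2e6)   # within one pair span of the target

  # two seeds: different subsets, same coverage within tolerance
  sub2 <- normalize_to_coverage(sim$pairs, 2e6, 8.5, sim$stats, seed = 50)
  expect_false(identical(sub$pair_id, sub2$pair_id))
  got2 <- physical_coverage(sub2, 2e6, sim$stats)$physical_coverage
  expect_lt(abs(got2 - got), 21000 / 2e6)

  # target equal to the full coverage returns all qualifying pairs
  full <- physical_coverage(sim$pairs, 2e6, sim$stats)
  all_q <- normalize_to_coverage(sim$pairs, 2e6,
                                 full$physical_coverage, sim$stats, seed = 51)
  expect_equal(nrow(all_q), full$pairs_used)

  # unattainable target errors with the attainable maximum
  expect_error(normalize_to_coverage(sim$pairs, 2e6, 100, sim$stats),
               "attainable")
})

test_that("qc_summary and report writer produce a coherent record", {
  g <- simulate_genome(1e6, NULL, seed = 52, emit_sequence = FALSE)
  sim <- simulate_classified(g, "5kb", 5000, 500, 5000, seed = 53,
                             duplicate_fraction = 0.2)
  qs <- qc_summary(sim$pairs, 1e6, sim$stats)
  expect_equal(qs$n_pairs, 5000)
  expect_lt(abs(qs$nonduplicate_fraction - 0.8), 0.02)
  expect_lt(abs(qs$insert_median - 5000) / 5000, 0.02)

  pre <- tempfile()
  cc <- complexity_curve(sim$pairs, replicates = 2, seed = 54)
  write_qc_report(qs, cc, pre)
  expect_true(file.exists(paste0(pre, ".json")))
  j <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(j$library, "5kb")
})
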