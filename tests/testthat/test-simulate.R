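test_that("simulation is deterministic given the config", {
  cfg <- simulation_config(tree = tree6(), family = "branch", n_codons = 60,
                           seed = 77, omega_fg = 0.8, omega_bg = 0.1,
                           codon_freqs = pi_panel)
  s1 <- simulate_codon_alignment(cfg)
  s2 <- simulate_codon_alignment(cfg)
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)
  r1 <- simulate_reads(c(x = strrep("ACGT", 100)), 1, n_reads = 50, seed = 4)
  r2 <- simulate_reads(c(x = strrep("ACGT", 100)), 1, n_reads = 50, seed = 4)
  expect_identical(r1, r2)
})

test_that("purifying limit omega = 0 produces no amino-acid differences", {
  cfg <- simulation_config(tree = tree6(), family = "M0", n_codons = 150,
                           seed = 13, kappa = 2, omega = 0,
                           codon_freqs = pi_panel)
  sim <- simulate_codon_alignment(cfg)
  prots <- vapply(sim$alignment$sequences, galdet::translate_cds, character(1))
  expect_equal(length(unique(prots)), 1L)
  # but synonymous change did occur
  expect_gt(length(unique(sim$alignment$sequences)), 1L)
})

test_that("long-branch simulation converges to the stationary frequencies", {
  pi <- pi_panel
  cfg <- simulation_config(tree = "(a:8,b:8);", family = "M0", n_codons = 4000,
                           seed = 19, kappa = 2, omega = 0.5, codon_freqs = pi)
  sim <- simulate_codon_alignment(cfg)
  emp <- tabulate(sim$alignment$states, nbins = 61) / (2 * 4000)
  # total-variation distance to the input frequencies
  expect_lt(0.5 * sum(abs(emp - pi)), 0.05)
})

test_that("per-branch sampling follows the matrix-exponential transition law", {
  pi <- pi_panel
  n <- 10000
  # joint tip-pair distribution is exactly pi_i P_ij(t_a + t_b) (reversibility)
  cfg <- simulation_config(tree = "(a:0.3,b:0.3);", family = "M0",
                           n_codons = n, seed = 23, kappa = 2, omega = 0.4,
                           codon_freqs = pi)
  sim <- simulate_codon_alignment(cfg)
  st <- sim$alignment$states
  P <- codon_pmatrix(2, 0.4, 0.6, pi)
  expected <- (pi * P) * n
  observed <- matrix(0, 61, 61)
  for (k in seq_len(ncol(st))) {
    observed[st[1, k], st[2, k]] <- observed[st[1, k], st[2, k]] + 1
  }
  # chi-square goodness of fit, small expected cells pooled into one
  big <- expected >= 5
  chi <- sum((observed[big] - expected[big])^2 / expected[big]) +
    (sum(observed[!big]) - sum(expected[!big]))^2 / sum(expected[!big])
  df <- sum(big)  # +1 pooled cell, -1 total constraint
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("paralog pairs hit the identity target and report their differences", {
  pp <- simulate_paralog_pair(n_codons = 440, target_identity = 0.86,
                              stop_codon = 414, seed = 6)
  av <- strsplit(pp$copy_a, "")[[1]]
  bv <- strsplit(pp$copy_b, "")[[1]]
  # diff oracle: engineered positions recovered exactly
  expect_identical(which(av != bv), pp$diff_positions)
  ident <- 100 * mean(av == bv)
  expect_lt(abs(ident - 86), 0.6)
  expect_equal(substr(pp$copy_b, 3 * 413 + 1, 3 * 414), "TAA")
  # no internal stop in copy A
  expect_true(is.na(detect_premature_stop(pp$copy_a)$stop_codon))
  # identical-target limit
  pp100 <- simulate_paralog_pair(n_codons = 100, target_identity = 1, seed = 2)
  expect_identical(pp100$copy_a, pp100$copy_b)
  expect_error(select_baits(pp100$copy_a, pp100$copy_b), "no gap-free")
})

test_that("read simulation respects abundances, exactness and edge cases", {
  tx <- c(long = strrep("ACGTTGCA", 200), short = strrep("TTGACGTA", 150))
  reads <- simulate_reads(tx, c(long = 120, short = 1) / nchar(tx),
                          n_reads = 4000, read_len = 150, seed = 8)
  src <- sub("^read\\d+\\|([^|]+)\\|.*$", "\\1", names(reads))
  n_long <- sum(src == "long")
  n_short <- sum(src == "short")
  expect_lt(abs(n_long / n_short - 120), 2 * 120 * sqrt(1 / max(n_short, 1)))
  # error-free reads are exact substrings of a strand
  rc <- vapply(tx, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  ok <- vapply(seq_along(reads), function(i) {
    s <- src[i]
    grepl(reads[i], tx[s], fixed = TRUE) || grepl(reads[i], rc[s], fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_length(simulate_reads(tx, c(1, 1), n_reads = 0, seed = 1), 0)
  expect_warning(simulate_reads(c(tiny = "ACGT", ok = strrep("ACGT", 100)),
                                c(1, 1), n_reads = 10, seed = 1), "skipped")
})
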