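test_that("a uniquely qualifying bait window is always found", {
  set.seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  other <- base
  # exactly one 50-nt window (101..150) carries 8 engineered diffs
  flip <- c(105, 110, 116, 121, 128, 133, 140, 146)
  for (p in flip) {
    substr(other, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(other, p, p))[1]
  }
  # exhaustive window enumeration oracle: qualifying starts
  av <- strsplit(base, "")[[1]]; bv <- strsplit(other, "")[[1]]
  diffs <- which(av != bv)
  oracle_ok <- vapply(0:(300 - 50), function(s) {
    sum(diffs > s & diffs <= s + 50) >= 7
  }, logical(1))
  for (seed in c(1, 99, 1234)) {
    expect_warning(baits <- select_baits(base, other, n_baits = 5, seed = seed),
                   "only 1 non-overlapping")
    expect_true(all(baits$n_diff >= 7))
    expect_true(all(oracle_ok[baits$start + 1]))
  }
  expect_error(select_baits(base, base), "no gap-free")
})

test_that("selected baits are non-overlapping 50-column windows with enough diffs", {
  pp <- simulate_paralog_pair(n_codons = 440, target_identity = 0.86,
                              stop_codon = 414, seed = 5)
  baits <- select_baits(pp$copy_a, pp$copy_b, seed = 2)
  expect_equal(nrow(baits), 5)
  expect_true(all(baits$end - baits$start == 50))
  expect_true(all(baits$n_diff >= 7))
  st <- sort(baits$start)
  expect_true(all(diff(st) >= 50))
  # segments really come from the two copies
  expect_true(all(substring(pp$copy_a, baits$start_a + 1, baits$start_a + 50) ==
                    baits$seg_a))
  expect_true(all(substring(pp$copy_b, baits$start_b + 1, baits$start_b + 50) ==
                    baits$seg_b))
})

test_that("bait counting equals the naive all-pairs substring oracle", {
  pp <- simulate_paralog_pair(n_codons = 200, target_identity = 0.86, seed = 3)
  baits <- select_baits(pp$copy_a, pp$copy_b, n_baits = 3, seed = 1)
  reads <- simulate_reads(c(a = pp$copy_a, b = pp$copy_b), c(3, 1),
                          n_reads = 150, read_len = 80, error_rate = 0.01,
                          seed = 11)
  got <- count_bait_reads(reads, baits)
  oracle <- naive_bait_counts(reads, baits)
  expect_equal(got$count_a, oracle$count_a)
  expect_equal(got$count_b, oracle$count_b)

  # a single read equal to bait 1 of copy A
  got1 <- count_bait_reads(baits$seg_a[1], baits)
  expect_equal(got1$count_a, c(1L, 0L, 0L))
  expect_equal(got1$count_b, c(0L, 0L, 0L))
  # empty read set
  got0 <- count_bait_reads(character(0), baits)
  expect_true(all(got0$count_a == 0) && all(got0$count_b == 0))
})

test_that("error-free reads never match both copies of the same window", {
  pp <- simulate_paralog_pair(n_codons = 300, target_identity = 0.86, seed = 9)
  baits <- select_baits(pp$copy_a, pp$copy_b, seed = 4)
  reads <- simulate_reads(c(a = pp$copy_a, b = pp$copy_b), c(1, 1),
                          n_reads = 400, read_len = 100, seed = 12)
  for (j in seq_len(nrow(baits))) {
    both <- grepl(baits$seg_a[j], reads, fixed = TRUE) &
      grepl(baits$seg_b[j], reads, fixed = TRUE)
    expect_false(any(both))
  }
})

test_that("relative expression handles ratios, zero denominators and TPM apportioning", {
  counts <- tibble::tibble(bait = 1:5, count_a = c(300, 250, 200, 250, 200),
                           count_b = c(3, 2, 1, 2, 2))
  r <- estimate_relative_expression(counts)
  expect_equal(r$ratio_a_over_b, 120)
  expect_equal(r$status, "ok")
  r2 <- estimate_relative_expression(
    tibble::tibble(bait = 1, count_a = 50, count_b = 0), tpm_combined = 1000)
  expect_equal(r2$ratio_a_over_b, Inf)
  expect_equal(r2$status, "denominator_zero")
  expect_equal(r2$tpm_a, 1000)
  expect_equal(r2$tpm_b, 0)
  r3 <- estimate_relative_expression(tibble::tibble(bait = 1, count_a = 0, count_b = 0))
  expect_equal(r3$status, "undefined")
})

test_that("the ratio estimator is unbiased across replicates", {
  pp <- simulate_paralog_pair(n_codons = 440, target_identity = 0.86, seed = 1)
  baits <- select_baits(pp$copy_a, pp$copy_b, seed = 1)
  n_reads_for <- c(`1` = 2000, `10` = 2000, `120` = 20000)
  for (R in c(1, 10, 120)) {
    ratios <- vapply(1:50, function(i) {
      reads <- simulate_reads(c(a = pp$copy_a, b = pp$copy_b), c(R, 1),
                              n_reads = n_reads_for[[as.character(R)]],
                              read_len = 150, seed = 1000 + i)
      cnt <- count_bait_reads(reads, baits)
      estimate_relative_expression(cnt)$ratio_a_over_b
    }, numeric(1))
    expect_lt(abs(mean(ratios) - R), 0.1 * R)
  }
})
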