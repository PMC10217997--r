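test_that("rate matrix rows sum to zero and respect kappa/omega structure", {
  cs <- codon_states()
  pi <- pi_panel
  Q <- build_rate_matrix(kappa = 3, omega = 0.4, codon_freqs = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)

  # entries zero for codon pairs differing at >1 position
  p <- cs$pairs
  one_step <- matrix(FALSE, 61, 61)
  one_step[p[, c("i", "j")]] <- TRUE
  one_step[p[, c("j", "i")]] <- TRUE
  off <- Q
  diag(off) <- 0
  expect_true(all(off[!one_step] == 0))

  # omega = 0 kills every nonsynonymous entry
  Q0 <- build_rate_matrix(kappa = 2, omega = 0, codon_freqs = pi, scale = FALSE)
  nonsyn <- p[p[, "synonymous"] == 0L, , drop = FALSE]
  expect_true(all(Q0[nonsyn[, c("i", "j")]] == 0))
  expect_true(all(Q0[nonsyn[, c("j", "i")]] == 0))

  # transitions carry kappa relative to transversions (unscaled, equal freqs)
  Qk <- build_rate_matrix(kappa = 5, omega = 1, scale = FALSE)
  ts <- p[p[, "transition"] == 1L, , drop = FALSE][1, ]
  tv <- p[p[, "transition"] == 0L, , drop = FALSE][1, ]
  expect_equal(Qk[ts["i"], ts["j"]] / Qk[tv["i"], tv["j"]], 5)
})

test_that("neutral equal-frequency matrix is symmetric and detailed balance holds", {
  Q <- build_rate_matrix(kappa = 1, omega = 1)
  expect_lt(max(abs(Q - t(Q))), 1e-14)
  pi <- pi_panel
  Q2 <- build_rate_matrix(kappa = 2, omega = 0.5, codon_freqs = pi)
  M <- pi * Q2  # diag(pi) %*% Q: symmetric iff reversible wrt pi
  expect_lt(max(abs(M - t(M))), 1e-14)
})

test_that("stationary distribution equals the input frequencies (null-space oracle)", {
  pi <- pi_panel
  Q <- build_rate_matrix(kappa = 2, omega = 0.5, codon_freqs = pi)
  # generic linear-algebra oracle: left null vector of Q
  ns <- eigen(t(Q))
  k <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, k])
  v <- v / sum(v)
  expect_lt(max(abs(v - pi)), 1e-10)
  expect_lt(max(abs(pi %*% Q)), 1e-10)
})

test_that("invalid frequencies are rejected", {
  bad <- rep(1 / 61, 61)
  bad[1] <- -bad[1]
  expect_error(build_rate_matrix(2, 0.5, bad), "frequencies")
  expect_error(build_rate_matrix(2, 0.5, rep(1, 61)), "frequencies")
  expect_error(build_rate_matrix(-1, 0.5), "kappa")
})

test_that("transition probability matrices are stochastic and converge to pi", {
  pi <- pi_panel
  P <- codon_pmatrix(kappa = 2, omega = 0.3, t = 0.5, codon_freqs = pi)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0))
  Pinf <- codon_pmatrix(kappa = 2, omega = 0.3, t = 200, codon_freqs = pi)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-8)
})
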