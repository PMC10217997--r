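test_that("M0 parameters are recovered from simulated data", {
  cfg <- simulation_config(tree = andrena_tree(), family = "M0",
                           n_codons = 500, seed = 11, kappa = 2, omega = 0.3,
                           codon_freqs = pi_panel)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_codon_model(sim$alignment, sim$tree, "M0", control = quick_control)
  expect_true(fit$converged)
  expect_lt(abs(fit$spec$omega - 0.3), 0.05)
  expect_lt(abs(fit$spec$kappa - 2), 0.5)
})

test_that("branch-model foreground/background dN/dS are recovered", {
  cfg <- simulation_config(tree = andrena_tree(fg_stem = 0.15),
                           family = "branch", n_codons = 413, seed = 21,
                           kappa = 2, omega_fg = 0.68, omega_bg = 0.021,
                           codon_freqs = pi_panel)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_codon_model(sim$alignment, sim$tree, "branch",
                         control = quick_control)
  expect_true(fit$converged)
  expect_lt(abs(fit$spec$omega_fg - 0.68), 0.2)
  expect_lt(abs(fit$spec$omega_bg - 0.021), 0.02)
})

test_that("identical sequences collapse to zero branch lengths and stationary lnL", {
  cs <- codon_states()
  seq <- paste(cs$codons[rep(c(2, 9, 25, 40), 10)], collapse = "")
  aln <- codon_alignment(setNames(rep(seq, 4), c("a", "b", "c", "d")))
  fit <- fit_codon_model(aln, labeled_tree("((a:0.1,b:0.1):0.1,c:0.1,d:0.1);"),
                         "M0", codon_freqs = "equal", control = quick_control)
  expect_lt(sum(fit$branch_lengths), 1e-4)
  expect_equal(fit$lnL, 40 * log(1 / 61), tolerance = 1e-6)
})

test_that("nested fits satisfy the likelihood ordering", {
  cfg <- simulation_config(tree = tree6(), family = "M0", n_codons = 150,
                           seed = 31, kappa = 2, omega = 0.25,
                           codon_freqs = pi_panel)
  sim <- simulate_codon_alignment(cfg)
  f0 <- fit_codon_model(sim$alignment, sim$tree, "M0", control = quick_control)
  fb <- fit_codon_model(sim$alignment, sim$tree, "branch", control = quick_control)
  expect_gte(fb$lnL, f0$lnL - 1e-4)
})

test_that("tidiers summarise fits", {
  cfg <- simulation_config(tree = "(a:0.2,b:0.2);", family = "M0",
                           n_codons = 30, seed = 2, codon_freqs = pi_panel)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_codon_model(sim$alignment, sim$tree, "M0", codon_freqs = "equal",
                         control = quick_control)
  td <- tidy(fit)
  expect_setequal(td$term, c("kappa", "omega"))
  gl <- glance(fit)
  expect_equal(gl$n_codons, 30)
  expect_equal(gl$family, "M0")
  expect_true(is.finite(gl$logLik))
})
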