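test_that("two-taxon likelihood matches the matrix-exponential closed form", {
  pi <- pi_panel
  cfg <- simulation_config(tree = "(a:0.4,b:0.3);", family = "M0",
                           n_codons = 40, seed = 3, kappa = 2.5, omega = 0.4,
                           codon_freqs = pi)
  sim <- simulate_codon_alignment(cfg)
  spec <- codon_model_spec("M0", kappa = 2.5, omega = 0.4, codon_freqs = pi)
  ll <- log_likelihood(sim$alignment, sim$tree, spec)
  # independent oracle: lnL = sum_s log( pi_i P_ij(t_a + t_b) ) via expm
  Q <- build_rate_matrix(2.5, 0.4, pi)
  P <- as.matrix(Matrix::expm(Q * 0.7))
  st <- sim$alignment$states
  ll_oracle <- sum(log(pi[st[1, ]] * P[cbind(st[1, ], st[2, ])]))
  expect_lt(abs(ll - ll_oracle), 1e-8)
})

test_that("single-taxon alignment collapses to the sum of log codon frequencies", {
  pi <- pi_panel
  cs <- codon_states()
  seq <- paste(cs$codons[c(5, 17, 30)], collapse = "")
  aln <- codon_alignment(c(only = seq))
  spec <- codon_model_spec("M0", kappa = 2, omega = 1, codon_freqs = pi)
  expect_equal(log_likelihood(aln, NULL, spec), sum(log(pi[c(5, 17, 30)])))
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  pi <- pi_panel
  cfg <- simulation_config(tree = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.05,e:0.3);",
                           family = "M0", n_codons = 60, seed = 9,
                           kappa = 2, omega = 0.3, codon_freqs = pi)
  sim <- simulate_codon_alignment(cfg)
  spec <- codon_model_spec("M0", kappa = 2, omega = 0.3, codon_freqs = pi)
  ll1 <- log_likelihood(sim$alignment, sim$tree, spec)
  rerooted <- ape::root(sim$tree$phylo, outgroup = "e", resolve.root = TRUE)
  ll2 <- log_likelihood(sim$alignment, labeled_tree(rerooted), spec)
  expect_lt(abs(ll1 - ll2), 1e-6)
})

test_that("missing codons (gaps, ambiguity, stops) contribute no information", {
  pi <- pi_panel
  tr <- labeled_tree("(a:0.2,b:0.2,c:0.2);")
  spec <- codon_model_spec("M0", kappa = 2, omega = 0.5, codon_freqs = pi)
  base <- c(a = "ATGAAA", b = "ATGAGA", c = "ATGAAA")
  ll_base <- log_likelihood(codon_alignment(base), tr, spec)
  # adding an all-missing column (gap / N / stop) leaves lnL unchanged
  with_extra <- c(a = "ATGAAA---", b = "ATGAGAANN", c = "ATGAAATAA")
  ll_extra <- log_likelihood(codon_alignment(with_extra), tr, spec)
  expect_equal(ll_base, ll_extra, tolerance = 1e-10)
})

test_that("taxon mismatches and invalid alignments are rejected", {
  spec <- codon_model_spec("M0")
  expect_error(log_likelihood(codon_alignment(c(a = "ATG", x = "ATG")),
                              labeled_tree("(a:1,b:1);"), spec),
               "match")
  expect_error(codon_alignment(c(a = "ATGA", b = "ATGA")), "divisible")
  expect_error(codon_alignment(c(a = "ATG", b = "ATGAAA")), "equal length")
})

test_that("branch-site mixtures require a foreground and reduce correctly", {
  pi <- pi_panel
  tr_nofg <- labeled_tree("(a:0.2,b:0.2,c:0.2);")
  aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAGA", c = "ATGAAA"))
  spec_a <- codon_model_spec("branch_site_A", codon_freqs = pi)
  expect_error(log_likelihood(aln, tr_nofg, spec_a), "foreground")
  # with omega2 = 1 and omega0 ~ 1 the mixture collapses towards neutral M0
  tr <- labeled_tree("(a#1:0.2,b:0.2,c:0.2);")
  spec_n <- codon_model_spec("branch_site_A1", kappa = 2, omega0 = 0.999,
                             p0 = 0.5, p1 = 0.3, codon_freqs = pi)
  spec_m0 <- codon_model_spec("M0", kappa = 2, omega = 1, codon_freqs = pi)
  ll_mix <- log_likelihood(aln, tr, spec_n)
  ll_m0 <- log_likelihood(aln, tr, spec_m0)
  expect_lt(abs(ll_mix - ll_m0), 0.01)
})
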