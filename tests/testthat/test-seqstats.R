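test_that("variable-site counter agrees with a brute-force column scan", {
  set.seed(5)
  for (rep in 1:5) {
    cols <- replicate(100, {
      base <- sample(c("A", "C", "G", "T"), 1)
      col <- rep(base, 3)
      if (runif(1) < 0.3) col[sample(3, 1)] <- sample(c("A", "C", "G", "T", "N", "-"), 1)
      col
    })
    seqs <- setNames(apply(cols, 1, paste, collapse = ""), c("s1", "s2", "s3"))
    got <- count_variable_sites(seqs)
    expect_equal(got$variable_sites, brute_variable_columns(seqs))
    expect_equal(got$percent_variable,
                 round(100 * got$variable_sites / got$length, 2))
  }
})

test_that("identical sequences have zero variable sites; ambiguity-only variation is not counted", {
  seqs <- c(a = "ATGATG", b = "ATGATG", c = "ATGATG")
  expect_equal(count_variable_sites(seqs)$variable_sites, 0)
  seqs2 <- c(a = "ATGATG", b = "ATGATN", c = "ATG-TG")
  expect_equal(count_variable_sites(seqs2)$variable_sites, 0)
  expect_error(count_variable_sites(seqs, taxa = "a"), "at least 2")
  expect_error(count_variable_sites(seqs, taxa = c("a", "zz")), "not in alignment")
})

test_that("pairwise identity counts matches over non-gap columns and is symmetric", {
  # 10-codon toy pair with 3 engineered mismatches -> 27/30 = 90%
  a <- "ATGAAACCCGGGTTTAAACCCGGGTTTAAA"
  b <- a
  substr(b, 4, 4) <- "G"; substr(b, 16, 16) <- "C"; substr(b, 29, 29) <- "T"
  expect_equal(pairwise_identity(a, b, "nt")$percent_identity, 90)
  expect_equal(pairwise_identity(b, a, "nt")$percent_identity,
               pairwise_identity(a, b, "nt")$percent_identity)
  expect_equal(pairwise_identity(a, a, "nt")$percent_identity, 100)
  # gap columns excluded from the denominator
  expect_equal(pairwise_identity("ATG-AA", "ATGCAA", "nt")$columns, 5)
})

test_that("amino-acid identity translates first and stops end the chain", {
  a <- "ATGAAAAAAAAA"        # M K K K
  b <- "ATGAAATAAAAA"        # M K * .. -> compared over the 2-residue prefix
  r <- pairwise_identity(a, b, "aa")
  expect_equal(r$columns, 2)
  expect_equal(r$percent_identity, 100)
})

test_that("premature stops are located by in-frame scan", {
  expect_true(is.na(detect_premature_stop("ATGAAATAA")$stop_codon))
  r <- detect_premature_stop("ATGTAAAAATAA")
  expect_equal(r$stop_codon, 2L)
  expect_equal(r$coding_length_nt, 3L)
  # exhaustive scan oracle over all codons
  s <- "ATGCCCGGGTGAAAATAGTAA"
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  oracle <- which(codons %in% c("TAA", "TAG", "TGA"))
  oracle <- oracle[oracle < length(codons)][1]
  expect_equal(detect_premature_stop(s)$stop_codon, oracle)
  expect_error(detect_premature_stop("ATGA"), "divisible")
})

test_that("engineered synthetic gene set carries its designed summary statistics", {
  gs <- synthetic_gene_set(seed = 3)
  tab <- variability_table(gs$alignments, taxa = gs$specialists)
  panel <- galactose_gene_panel()
  expect_equal(tab$length, panel$length_nt)
  expect_equal(tab$variable_sites, panel$variable_sites)
  # brute-force cross-check on one gene
  sub <- gs$alignments$galE$sequences[gs$specialists]
  expect_equal(tab$variable_sites[tab$gene == "galE"],
               brute_variable_columns(sub))
  stop_row <- detect_premature_stop(gs$camellia_naga_like_full)
  expect_equal(stop_row$stop_codon, 414L)
  expect_equal(stop_row$coding_length_nt, 1239L)
})
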