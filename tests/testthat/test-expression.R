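test_that("TPM normalises by length and sums to one million per sample", {
  # equal counts, lengths L and 2L -> TPM ratio 2:1
  tpm <- compute_tpm(matrix(c(10, 10), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     lengths = c(100, 200))
  expect_equal(tpm$s1[1] / tpm$s1[2], 2)
  # single gene gets the whole million
  tpm1 <- compute_tpm(matrix(5, 1, 1, dimnames = list("g", "s")), lengths = 500)
  expect_equal(tpm1$s, 1e6)
  # random table: column sums and the direct formula
  set.seed(2)
  counts <- matrix(rpois(20 * 3, 40), 20, 3,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  lens <- sample(200:2000, 20)
  tpm20 <- compute_tpm(counts, lens)
  mat <- as.matrix(tpm20[, paste0("s", 1:3)])
  expect_equal(unname(colSums(mat)), rep(1e6, 3), tolerance = 1e-9)
  oracle <- 1e6 * (counts[, 2] / lens) / sum(counts[, 2] / lens)
  expect_equal(unname(mat[, 2]), unname(oracle))
  expect_error(compute_tpm(matrix(-1, 1, 1), 100), "non-negative")
  expect_warning(compute_tpm(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                             c(100, 100)), "all-zero")
})

test_that("planted differential expression is detected with correct direction", {
  sim <- simulate_expression_table(n_genes = 500, frac_de = 0.1, true_fc = 4,
                                   seed = 10)
  degs <- call_degs(sim$counts, sim$groups, control = "control")
  joined <- dplyr::left_join(degs, sim$truth, by = "gene")
  up_true <- joined$true_fc > 1
  dn_true <- joined$true_fc < 1
  # majority of affected genes flagged in the right direction
  expect_gt(mean(joined$direction[up_true] == "up"), 0.6)
  expect_gt(mean(joined$direction[dn_true] == "down"), 0.6)
  # false flags among null genes stay near the BH-controlled rate
  expect_lt(mean(joined$direction[joined$true_fc == 1] != "ns"), 0.05)
  # BH adjustment is monotone in p
  ord <- order(degs$p_value)
  expect_true(all(diff(degs$padj[ord]) >= -1e-12))
})

test_that("null data yields essentially no DEGs", {
  sim <- simulate_expression_table(n_genes = 400, frac_de = 0, seed = 22)
  degs <- call_degs(sim$counts, sim$groups, control = "control")
  expect_lt(mean(degs$direction != "ns"), 0.02)
})

test_that("zero group means give symbolic infinite fold changes", {
  counts <- rbind(
    silent_in_control = c(0, 0, 0, 0, 900, 1000, 950, 980),
    flat = c(100, 110, 90, 105, 100, 95, 108, 99)
  )
  colnames(counts) <- c(paste0("c", 1:4), paste0("t", 1:4))
  degs <- call_degs(counts, rep(c("ctl", "trt"), each = 4), control = "ctl")
  expect_equal(degs$fc[degs$gene == "silent_in_control"], Inf)
  expect_equal(degs$direction[degs$gene == "silent_in_control"], "up")
  expect_equal(degs$direction[degs$gene == "flat"], "ns")
  expect_error(call_degs(counts[, 1:3], c("a", "a", "b"), control = "a"),
               "at least 2")
})

test_that("the NB moment test broadly agrees with an established DE engine", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_expression_table(n_genes = 300, frac_de = 0.15, true_fc = 5,
                                   seed = 31)
  degs <- call_degs(sim$counts, sim$groups, control = "control")
  mat <- as.matrix(sim$counts[, -1])
  rownames(mat) <- sim$counts$gene
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      mat, S4Vectors::DataFrame(group = factor(sim$groups,
                                               levels = c("control", "treatment"))),
      ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  both <- !is.na(res$padj) & is.finite(degs$log2_fc)
  # fold-change estimates track each other closely
  expect_gt(cor(degs$log2_fc[both], res$log2FoldChange[both]), 0.95)
  # significant sets overlap substantially (Jaccard)
  a <- which(degs$padj < 0.05 & both)
  b <- which(res$padj < 0.05 & both)
  expect_gt(length(intersect(a, b)) / length(union(a, b)), 0.6)
})
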