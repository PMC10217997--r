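# TPM normalisation and fold-change differential-expression filtering.

#' Transcripts per million from counts and effective lengths
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)` per sample; every sample
#' column sums to one million.  An all-zero sample yields all-zero TPM with
#' a warning.
#'
#' @param counts Gene x sample matrix/data frame of non-negative read
#'   counts, or a tibble with a gene id column (see `gene_col`).
#' @param lengths Effective lengths (nt) per gene, `> 0`.
#' @param gene_col Name of the gene id column when `counts` is a tibble
#'   (default `"gene"`; ignored for plain matrices).
#' @return Tibble with `gene`, `length`, and one TPM column per sample.
#' @export
#' @examples
#' compute_tpm(matrix(c(10, 10), 2, dimnames = list(c("g1", "g2"), "s1")),
#'             lengths = c(100, 200))
compute_tpm <- function(counts, lengths, gene_col = "gene") {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[gene_col]])
    mat <- as.matrix(counts[setdiff(names(counts), gene_col)])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(counts)
    genes <- rownames(mat) %||% paste0("gene", seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  if (any(mat < 0)) abort("counts must be non-negative")
  if (length(lengths) != nrow(mat) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("`lengths` must be positive, one per gene")
  }
  rate <- mat / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warn(paste0("all-zero sample(s): ", paste(colnames(mat)[zero], collapse = ", ")))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  out <- as_tibble(tpm)
  dplyr::bind_cols(tibble(gene = genes, length = lengths), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DESeq-style median-of-ratios size factors
size_factors <- function(mat) {
  logg <- rowMeans(log(mat))
  use <- is.finite(logg)
  if (!any(use)) return(setNames(rep(1, ncol(mat)), colnames(mat)))
  apply(mat, 2, function(col) exp(median((log(col) - logg)[use], na.rm = TRUE)))
}

#' Call differentially expressed genes by fold change and adjusted p-value
#'
#' Counts are normalised by median-of-ratios size factors; each gene is
#' tested with a negative-binomial Wald test whose dispersion is
#' moment-estimated from the pooled within-group variability; p-values are
#' Benjamini-Hochberg adjusted.  Fold change is the ratio of normalised
#' group means (treatment over control); a zero control mean with nonzero
#' treatment mean is reported as `Inf` (and `-Inf` ... `0` in the opposite
#' direction), never as an error.  Genes are flagged up if `FC > fc_up` and
#' down if `FC < fc_down`, in both cases requiring `Padj < alpha`.
#'
#' @param counts Gene x sample count matrix (or tibble with a `gene`
#'   column).
#' @param groups Factor/character vector of group labels, one per sample
#'   (exactly two levels, each with at least 2 samples).
#' @param control Label of the control group.
#' @param fc_up,fc_down Fold-change thresholds (defaults 2 and 0.5).
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param gene_col Gene id column name for tibble input.
#' @return A tibble (class `deg_result`): `gene`, `mean_control`,
#'   `mean_treatment` (normalised), `fc`, `log2_fc`, `p_value`, `padj`,
#'   `direction` (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(counts, groups, control, fc_up = 2, fc_down = 0.5,
                      alpha = 0.05, gene_col = "gene") {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[gene_col]])
    mat <- as.matrix(counts[setdiff(names(counts), gene_col)])
  } else {
    mat <- as.matrix(counts)
    genes <- rownames(mat) %||% paste0("gene", seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) abort("`groups` must have one label per sample")
  lv <- unique(groups)
  if (length(lv) != 2L || !control %in% lv) {
    abort("`groups` must have exactly two levels including `control`")
  }
  treat <- setdiff(lv, control)
  if (sum(groups == control) < 2L || sum(groups == treat) < 2L) {
    abort("each group needs at least 2 samples")
  }
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  nc <- norm[, groups == control, drop = FALSE]
  nt <- norm[, groups == treat, drop = FALSE]
  mu_c <- rowMeans(nc)
  mu_t <- rowMeans(nt)
  n_c <- ncol(nc); n_t <- ncol(nt)

  # moment dispersion, pooled within groups: Var = mu + alpha*mu^2
  pooled_var <- (apply(nc, 1, var) * (n_c - 1) + apply(nt, 1, var) * (n_t - 1)) /
    (n_c + n_t - 2)
  mu_bar <- (mu_c * n_c + mu_t * n_t) / (n_c + n_t)
  disp <- pmax(0, (pooled_var - mu_bar) / mu_bar^2)
  disp[!is.finite(disp)] <- 0

  # Wald test on log fold change; pseudo-mean stabilises the SE (not the FC)
  # when a group mean is zero
  eps_c <- pmax(mu_c, 0.5 / n_c)
  eps_t <- pmax(mu_t, 0.5 / n_t)
  se2 <- (1 / eps_t + disp) / n_t + (1 / eps_c + disp) / n_c
  z <- (log(eps_t) - log(eps_c)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  p[mu_c == 0 & mu_t == 0] <- 1
  padj <- p.adjust(p, method = "BH")

  fc <- ifelse(mu_c == 0, ifelse(mu_t == 0, NA_real_, Inf), mu_t / mu_c)
  direction <- dplyr::case_when(
    !is.na(fc) & fc > fc_up & padj < alpha ~ "up",
    !is.na(fc) & fc < fc_down & padj < alpha ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(gene = genes, mean_control = unname(mu_c),
                mean_treatment = unname(mu_t), fc = unname(fc),
                log2_fc = unname(log2(fc)), p_value = unname(p),
                padj = unname(padj), direction = unname(direction))
  class(out) <- c("deg_result", class(out))
  attr(out, "thresholds") <- c(fc_up = fc_up, fc_down = fc_down, alpha = alpha)
  attr(out, "groups") <- c(control = control, treatment = treat)
  out
}
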