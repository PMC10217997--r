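# Codon-state machinery shared by the likelihood engine, the simulators and
# the sequence statistics.  The state space is the 61 sense codons of the
# standard nuclear genetic code; stops, gaps and ambiguous codons are treated
# as missing data.

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon state table for the standard genetic code
#'
#' Enumerates the 61 sense codons (standard nuclear code, stop codons
#' excluded) together with their encoded amino acids, and the list of
#' single-nucleotide codon pairs annotated as transition/transversion and
#' synonymous/nonsynonymous.  This table defines the state order used by all
#' rate matrices and likelihood computations in the package.
#'
#' @return A list with elements `codons` (character vector of 61 codons, the
#'   canonical state order), `aa` (amino acid per codon), and `pairs` (integer
#'   matrix with columns `i`, `j`, `transition`, `synonymous`; `i < j`,
#'   1-based state indices, one row per codon pair differing at exactly one
#'   position).
#' @export
#' @examples
#' cs <- codon_states()
#' length(cs$codons)  # 61
codon_states <- function() {
  if (!is.null(.codon_env$states)) return(.codon_env$states)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  aa <- unname(code[codons])
  bases <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  cod_mat <- do.call(rbind, strsplit(codons, ""))
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  rows <- vector("list", 3L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (b in bases) {
        if (b == cod_mat[i, pos]) next
        mut <- cod_mat[i, ]
        mut[pos] <- b
        j <- idx[paste(mut, collapse = "")]
        if (is.na(j) || j <= i) next  # stop codon or already listed
        k <- k + 1L
        ts <- purine[[b]] == purine[[cod_mat[i, pos]]]
        rows[[k]] <- c(i, j, as.integer(ts), as.integer(aa[i] == aa[j]))
      }
    }
  }
  pairs <- do.call(rbind, rows[seq_len(k)])
  colnames(pairs) <- c("i", "j", "transition", "synonymous")
  .codon_env$states <- list(codons = codons, aa = aa, pairs = pairs)
  .codon_env$states
}

# split an in-frame nucleotide string into codons (uppercase)
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("sequence length must be divisible by 3")
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# map codons to 1..61 state indices; NA for gap/ambiguous/stop codons
codons_to_states <- function(codons) {
  cs <- codon_states()
  match(codons, cs$codons)
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard nuclear genetic code; codons containing gaps or ambiguity codes
#' translate to `X`, stop codons to `*`.
#'
#' @param seq In-frame nucleotide string (length divisible by 3).
#' @param trim_at_stop If `TRUE`, the translation is truncated at the first
#'   stop codon (chain end), mirroring how a premature termination shortens
#'   the protein.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq, trim_at_stop = FALSE) {
  codons <- split_codons(seq)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (trim_at_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are tabulated from the alignment
#' (over non-missing codons) and multiplied across the three codon positions;
#' the product is restricted to the 61 sense codons and renormalised.  A small
#' floor keeps every sense codon representable when a base is absent at some
#' position.
#'
#' @param aln A [codon_alignment].
#' @param floor Minimum per-codon frequency before renormalisation.
#' @return Numeric vector of 61 codon frequencies (order of [codon_states]).
#' @export
codon_freqs_f3x4 <- function(aln, floor = 1e-6) {
  aln <- as_codon_alignment(aln)
  cs <- codon_states()
  pos_freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in aln$sequences) {
    cods <- split_codons(s)
    cods <- cods[!is.na(codons_to_states(cods))]
    if (!length(cods)) next
    m <- do.call(rbind, strsplit(cods, ""))
    for (p in 1:3) {
      tab <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
      pos_freq[p, ] <- pos_freq[p, ] + as.numeric(tab)
    }
  }
  if (sum(pos_freq) == 0) return(rep(1 / 61, 61))
  pos_freq <- pos_freq / rowSums(pos_freq)
  cod_mat <- do.call(rbind, strsplit(cs$codons, ""))
  pi <- pos_freq[1, cod_mat[, 1]] * pos_freq[2, cod_mat[, 2]] * pos_freq[3, cod_mat[, 3]]
  pi <- pmax(pi, floor)
  pi / sum(pi)
}

#' Equal codon frequencies
#' @return Numeric vector of 61 values `1/61`.
#' @export
codon_freqs_equal <- function() rep(1 / 61, 61)

check_codon_freqs <- function(pi) {
  if (length(pi) != 61 || any(!is.finite(pi)) || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8) {
    abort("codon frequencies must be 61 non-negative values summing to 1")
  }
  invisible(pi)
}
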