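# In-frame codon alignment container.

#' Construct a codon alignment
#'
#' An in-frame, gap-aware multiple alignment of protein-coding nucleotide
#' sequences.  All sequences must be the same length, divisible by 3.  Codons
#' that are stops, or contain gaps or ambiguity codes, are flagged as missing
#' and contribute no information to likelihood computations.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (or a `Biostrings::DNAStringSet`).
#' @return An object of class `codon_alignment`: a list with `taxa`,
#'   `sequences` (named character), `n_codons`, and `states` (taxa x codons
#'   integer matrix of 1-61 codon states, `NA` = missing).
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG"))
#' aln$n_codons
codon_alignment <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences) || is.null(names(sequences)) ||
      anyDuplicated(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be a named character vector with unique names")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) abort("all sequences must have equal length")
  if (lens[1L] %% 3L != 0L) abort("alignment length must be divisible by 3")
  n_codons <- unname(lens[1L]) %/% 3L
  states <- t(vapply(sequences, function(s) codons_to_states(split_codons(s)),
                     integer(n_codons)))
  if (n_codons == 1L) states <- matrix(states, ncol = 1L,
                                       dimnames = list(names(sequences), NULL))
  structure(
    list(taxa = names(sequences), sequences = sequences,
         n_codons = n_codons, states = states),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$n_codons,
      " codons (", 3L * x$n_codons, " nt); ",
      sum(is.na(x$states)), " missing codons\n", sep = "")
  invisible(x)
}

as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  codon_alignment(x)
}

#' Read an aligned, in-frame FASTA file as a codon alignment
#'
#' @param file Path to an aligned FASTA file.
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(file) {
  codon_alignment(Biostrings::readDNAStringSet(file))
}

#' Write a codon alignment (or named sequences) to FASTA
#'
#' @param x A [codon_alignment] or named character vector of sequences.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file) {
  seqs <- if (inherits(x, "codon_alignment")) x$sequences else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

# compress alignment columns into unique site patterns
# returns list(states = taxa x n_pattern matrix with -1 for missing (0-based
# codon states for the C++ engine), weights)
compress_patterns <- function(aln, taxa_order) {
  st <- aln$states[taxa_order, , drop = FALSE]
  key <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  pat <- st[, first, drop = FALSE]
  pat0 <- pat - 1L
  pat0[is.na(pat0)] <- -1L
  storage.mode(pat0) <- "integer"
  list(states = pat0, weights = weights,
       pattern_index = match(key, key[first]))
}
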