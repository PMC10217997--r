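# Descriptive sequence statistics: variable sites, pairwise identity,
# premature-stop detection.

#' Count variable nucleotide sites in an alignment subset
#'
#' A column is variable iff at least two distinct unambiguous nucleotides
#' (A/C/G/T) occur among the chosen taxa; columns whose only variation
#' involves gaps or ambiguity codes are not counted (the conservative
#' convention of standard polymorphism tools).
#'
#' @param aln A [codon_alignment] or named character vector of aligned
#'   sequences (equal lengths; length need not be a multiple of 3 for plain
#'   vectors).
#' @param taxa Subset of taxon labels to survey (default: all; at least 2).
#' @param gene Optional gene name carried into the report.
#' @return One-row tibble: `gene`, `length` (nt), `variable_sites`,
#'   `percent_variable` (rounded to 2 decimals).
#' @export
#' @examples
#' count_variable_sites(c(a = "ATGAAA", b = "ATGAAT", c = "ATGAAA"))
count_variable_sites <- function(aln, taxa = NULL, gene = NA_character_) {
  seqs <- if (inherits(aln, "codon_alignment")) aln$sequences else toupper(aln)
  if (!is.character(seqs) || is.null(names(seqs))) {
    abort("`aln` must be a codon_alignment or named character vector")
  }
  if (length(unique(nchar(seqs))) != 1L) abort("sequences must have equal length")
  if (is.null(taxa)) taxa <- names(seqs)
  if (length(taxa) == 0L) abort("`taxa` must name at least one sequence")
  missing_taxa <- setdiff(taxa, names(seqs))
  if (length(missing_taxa)) {
    abort(paste0("taxa not in alignment: ", paste(missing_taxa, collapse = ", ")))
  }
  if (length(taxa) < 2L) abort("need at least 2 taxa to survey variation")
  m <- do.call(rbind, strsplit(seqs[taxa], ""))
  is_var <- apply(m, 2, function(col) {
    nt <- unique(col[col %in% c("A", "C", "G", "T")])
    length(nt) >= 2L
  })
  len <- ncol(m)
  v <- sum(is_var)
  tibble(gene = gene, length = len, variable_sites = v,
         percent_variable = round(100 * v / len, 2))
}

#' Variability report for several gene alignments
#'
#' @param alignments Named list of alignments (see [count_variable_sites()]).
#' @param taxa Taxon subset applied to every gene.
#' @return Tibble with one row per gene.
#' @export
variability_table <- function(alignments, taxa = NULL) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  bind_rows(purrr::imap(alignments, function(a, nm) {
    count_variable_sites(a, taxa = taxa, gene = nm)
  }))
}

#' Pairwise percent identity between two sequences
#'
#' Identity is `100 * matches / aligned columns where neither sequence has a
#' gap`.  At the amino-acid level, in-frame nucleotide inputs are translated
#' with the standard code first; a stop codon ends the chain, and columns
#' beyond either chain end are excluded from the denominator.  Unaligned
#' inputs of different length are globally aligned first
#' (`Biostrings::pairwiseAlignment`).
#'
#' @param seq_a,seq_b Nucleotide sequences (aligned: equal length; or
#'   alignable).
#' @param level `"nt"` or `"aa"`.
#' @param label_a,label_b Sequence labels for the report.
#' @return One-row tibble: `label_a`, `label_b`, `level`, `matches`,
#'   `columns`, `percent_identity`.
#' @export
#' @examples
#' pairwise_identity("ATGAAA", "ATGAAT")$percent_identity  # 83.33
pairwise_identity <- function(seq_a, seq_b, level = c("nt", "aa"),
                              label_a = "seq_a", label_b = "seq_b") {
  level <- match.arg(level)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  pre_aligned <- nchar(seq_a) == nchar(seq_b)
  if (level == "aa") {
    if (nchar(seq_a) %% 3L || nchar(seq_b) %% 3L) {
      abort("amino-acid identity needs in-frame nucleotide sequences")
    }
    seq_a <- translate_cds(seq_a, trim_at_stop = TRUE)
    seq_b <- translate_cds(seq_b, trim_at_stop = TRUE)
    if (pre_aligned) {
      # chain ends from premature stops: compare over the shared prefix
      n <- min(nchar(seq_a), nchar(seq_b))
      seq_a <- substr(seq_a, 1L, n); seq_b <- substr(seq_b, 1L, n)
    }
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    if (!pre_aligned) {
      al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global")
      seq_a <- as.character(Biostrings::alignedPattern(al))
      seq_b <- as.character(Biostrings::alignedSubject(al))
    } else {
      abort("pre-aligned sequences must have equal length")
    }
  }
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  keep <- a != "-" & b != "-"
  cols <- sum(keep)
  matches <- sum(a[keep] == b[keep])
  tibble(label_a = label_a, label_b = label_b, level = level,
         matches = matches, columns = cols,
         percent_identity = 100 * matches / cols)
}

#' Detect a premature stop codon in an in-frame CDS
#'
#' Scans in-frame codons and reports the first stop strictly before the
#' final codon; a terminal stop alone is not premature.
#'
#' @param cds In-frame nucleotide sequence (length divisible by 3; gaps are
#'   ignored codon-wise, i.e. a codon containing a gap cannot be a stop).
#' @param label Sequence label for the report.
#' @return One-row tibble: `label`, `n_codons`, `stop_codon` (1-based codon
#'   index or `NA` if none), `premature` (logical), `coding_length_nt`
#'   (nucleotides before the first premature stop, or the full length).
#' @export
#' @examples
#' detect_premature_stop("ATGTAAAAATAA")$stop_codon  # 2
detect_premature_stop <- function(cds, label = NA_character_) {
  codons <- split_codons(cds)
  n <- length(codons)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  premature <- stops[stops < n]
  stop_at <- if (length(premature)) premature[1L] else NA_integer_
  tibble(label = label, n_codons = n, stop_codon = stop_at,
         premature = !is.na(stop_at),
         coding_length_nt = if (is.na(stop_at)) 3L * n else 3L * (stop_at - 1L))
}
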