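# Shared fixtures: small trees and quick optimizer settings.

pi_panel <- galdet::panel_codon_freqs()

# six-taxon tree with a two-tip foreground clade (stem + 2 branches)
tree6 <- function(fg_stem = 0.08) {
  galdet::labeled_tree(sprintf(
    "((a:0.05,b:0.05)#1:%g,(c:0.06,d:0.06):0.03,(e:0.08,f:0.08):0.02);",
    fg_stem))
}

quick_control <- galdet::fit_control(n_restarts = 1)

# independent brute-force variable-column scan (oracle for seqstats)
brute_variable_columns <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n_var <- 0L
  for (j in seq_len(ncol(m))) {
    seen <- character(0)
    for (i in seq_len(nrow(m))) {
      if (m[i, j] %in% c("A", "C", "G", "T")) seen <- union(seen, m[i, j])
    }
    if (length(seen) >= 2L) n_var <- n_var + 1L
  }
  n_var
}

# naive all-pairs substring scan (oracle for bait counting), via Biostrings
naive_bait_counts <- function(reads, baits) {
  hit_one <- function(seg) {
    sum(vapply(reads, function(r) {
      x <- Biostrings::DNAString(r)
      Biostrings::countPattern(seg, x) > 0 ||
        Biostrings::countPattern(as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seg))), x) > 0
    }, logical(1)))
  }
  data.frame(
    bait = baits$bait,
    count_a = vapply(baits$seg_a, hit_one, numeric(1), USE.NAMES = FALSE),
    count_b = vapply(baits$seg_b, hit_one, numeric(1), USE.NAMES = FALSE)
  )
}
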