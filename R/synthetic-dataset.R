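# Synthetic study-like dataset: a six-gene galactose-derivative metabolism
# panel across 12 Andrena-like taxa, with a five-species oil-tea-specialist
# foreground clade.  Two generators are provided:
#
#  * `synthetic_gene_set()` engineers alignments whose summary statistics
#    (gene lengths, within-clade variable-site counts, paralog identity,
#    premature stop) exactly match the panel's reference values -- used to
#    exercise the descriptive-statistics and paralog tools;
#  * `simulate_panel_alignments()` evolves alignments under the two-ratio
#    branch model with the panel's dN/dS values as generating truth -- used
#    to exercise the model-fitting pipeline with known answers.
#
# All outputs are synthetic stand-ins, not real sequences.

#' Reference panel of galactose-derivative metabolism genes
#'
#' Per-gene study conditions used by the synthetic generators: coding length,
#' the number of variable sites among the five specialist species, the
#' generating foreground/background dN/dS of the two-ratio branch model, and
#' the foreground stem branch length (substitutions per codon).  NAGA_like is
#' a young duplicate of NAGA confined to the specialist clade; its stem
#' carries the paralog divergence (~14% nucleotide), while the single-copy
#' genes have shallow within-clade divergence, and its premature stop
#' shortens the coding region from 1320 to 1239 nt.
#'
#' @return A tibble with columns `gene`, `length_nt`, `variable_sites`,
#'   `omega_fg`, `omega_bg`, `fg_stem`, `positively_selected`.
#' @export
galactose_gene_panel <- function() {
  tibble(
    gene = c("NAGA", "NAGA_like", "galM", "galK", "galT", "galE"),
    length_nt = c(1320L, 1239L, 1077L, 1182L, 1152L, 1098L),
    variable_sites = c(16L, 33L, 29L, 24L, 15L, 8L),
    omega_fg = c(0.049, 0.680, 0.251, 0.864, 0.387, 0.129),
    omega_bg = c(0.023, 0.021, 0.360, 0.161, 0.088, 0.063),
    fg_stem = c(0.012, 0.15, 0.012, 0.012, 0.012, 0.012),
    positively_selected = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}

#' Twelve-taxon species tree with the specialist clade as foreground
#'
#' Five oil-tea-specialist species form a monophyletic foreground clade
#' (stem branch plus all branches within); the seven non-specialists are
#' background.  Within-clade branch lengths are short (~0.5% per branch,
#' matching the panel's 1-3% within-clade variability) and genus-level
#' branches moderate.
#'
#' @param fg_stem Stem branch length of the foreground clade.
#' @return A [labeled_tree].
#' @export
andrena_tree <- function(fg_stem = 0.012) {
  fg <- paste0(
    "((A_camellia:0.006,A_hunanensis:0.006):0.004,",
    "(A_striata:0.006,(A_sp1:0.006,A_sp2:0.006):0.004):0.004)#1:", fg_stem)
  nwk <- paste0(
    "((", fg, ",(A_chekiangensis:0.05,A_haemorrhoa:0.05):0.03):0.03,",
    "(A_minutula:0.06,A_dorsata:0.06):0.03,",
    "(A_fulva:0.07,(A_hattorfiana:0.06,A_bucephala:0.06):0.03):0.02);")
  labeled_tree(nwk)
}

#' Specialist (foreground) taxon labels of [andrena_tree()]
#' @return Character vector of 5 labels.
#' @export
specialist_taxa <- function() {
  c("A_camellia", "A_hunanensis", "A_striata", "A_sp1", "A_sp2")
}

# F3x4 codon frequencies from position-specific base frequencies
f3x4_from_base_freqs <- function(pos_freq) {
  cs <- codon_states()
  cod_mat <- do.call(rbind, strsplit(cs$codons, ""))
  pi <- pos_freq[1, cod_mat[, 1]] * pos_freq[2, cod_mat[, 2]] *
    pos_freq[3, cod_mat[, 3]]
  pi / sum(pi)
}

#' Default codon frequencies of the synthetic panel
#'
#' F3x4 frequencies from mildly AT-rich, position-specific base
#' compositions typical of hymenopteran coding sequence.
#' @return Numeric 61-vector.
#' @export
panel_codon_freqs <- function() {
  pos <- rbind(c(A = 0.28, C = 0.21, G = 0.30, T = 0.21),
               c(A = 0.31, C = 0.22, G = 0.17, T = 0.30),
               c(A = 0.29, C = 0.23, G = 0.17, T = 0.31))
  f3x4_from_base_freqs(pos)
}

# mutate the nucleotide at alignment column `col` of sequence `codons`
# (character vector of codons) to a different base keeping the codon sense;
# returns the new codon or NA if impossible
mutate_column_sense <- function(codons, col) {
  ci <- (col - 1L) %/% 3L + 1L
  pos <- (col - 1L) %% 3L + 1L
  old <- codons[ci]
  v <- strsplit(old, "")[[1L]]
  for (b in sample(setdiff(c("A", "C", "G", "T"), v[pos]))) {
    w <- v; w[pos] <- b
    cand <- paste(w, collapse = "")
    if (!is.na(codons_to_states(cand))) return(list(codon_index = ci, codon = cand))
  }
  NULL
}

# sprinkle exactly `n_cols` variable columns over sequences `targets` of an
# alignment stored as a list of codon vectors; one random target per column
engineer_variable_columns <- function(seq_list, targets, n_cols, nt_range) {
  done <- integer(0)
  guard <- 0L
  while (length(done) < n_cols) {
    guard <- guard + 1L
    if (guard > 50L * n_cols) abort("failed to place variable columns")
    col <- sample(nt_range, 1L)
    if (col %in% done) next
    sp <- sample(targets, 1L)
    m <- mutate_column_sense(seq_list[[sp]], col)
    if (is.null(m)) next
    seq_list[[sp]][m$codon_index] <- m$codon
    done <- c(done, col)
  }
  seq_list
}

# random sense-preserving divergence: mutate ~rate of codons by one nt
diverge_codons <- function(codons, rate) {
  n <- length(codons)
  k <- rbinom(1L, n - 1L, rate)
  if (k == 0L) return(codons)
  for (ci in sample(2:n, k)) {
    col <- (ci - 1L) * 3L + sample.int(3L, 1L)
    m <- mutate_column_sense(codons, col)
    if (!is.null(m)) codons[m$codon_index] <- m$codon
  }
  codons
}

#' Engineered synthetic gene set with the panel's exact summary statistics
#'
#' Builds 12-taxon alignments for the six panel genes such that, by
#' construction: each gene has its panel coding length; the variable-site
#' count among the five specialist taxa equals the panel value exactly; the
#' camellia NAGA/NAGA_like coding regions differ at 173 of 1239 nt (86%
#' nucleotide identity) of which 91 change the amino acid (78% amino-acid
#' identity); and the full-length camellia NAGA_like carries a premature TAA
#' at codon 414 of 440 (coding length 1239 nt).  Non-specialist taxa carry
#' the NAGA sequence in the NAGA_like alignment (the standard substitution
#' when a lineage lacks the duplicate), plus background divergence.
#'
#' @param seed Integer seed.
#' @param bg_rate Per-codon background divergence rate for the seven
#'   non-specialist taxa (default 0.05).
#' @return List: `alignments` (named list of six [codon_alignment]s; the
#'   NAGA_like alignment covers its 1239-nt coding region),
#'   `camellia_naga`, `camellia_naga_like_full` (full 1320-nt CDS with the
#'   premature stop), `tree` (a [labeled_tree]), `specialists`, and `panel`.
#' @export
synthetic_gene_set <- function(seed = 1L, bg_rate = 0.05) {
  panel <- galactose_gene_panel()
  tree <- andrena_tree()
  taxa <- tree$phylo$tip.label
  fg <- specialist_taxa()
  bg <- setdiff(taxa, fg)
  cs <- codon_states()
  sense_no_stop <- setdiff(cs$codons, c("TAA", "TAG", "TGA"))

  with_seed(seed, {
    alignments <- list()
    camellia_naga <- NULL
    camellia_naga_like_full <- NULL

    for (r in seq_len(nrow(panel))) {
      g <- panel$gene[r]
      if (g == "NAGA_like") next  # built together with NAGA below
      n_cod <- panel$length_nt[r] %/% 3L
      anc <- c("ATG", sample(sense_no_stop, n_cod - 1L, replace = TRUE))
      seqs <- setNames(rep(list(anc), length(taxa)), taxa)
      for (sp in bg) seqs[[sp]] <- diverge_codons(seqs[[sp]], bg_rate)
      seqs <- engineer_variable_columns(seqs, setdiff(fg, "A_camellia"),
                                        panel$variable_sites[r],
                                        4:(3L * n_cod))
      alignments[[g]] <- codon_alignment(
        vapply(seqs, paste, character(1), collapse = ""))
      if (g == "NAGA") {
        camellia_naga <- paste(seqs$A_camellia, collapse = "")

        # --- NAGA_like: duplicate of camellia NAGA ---------------------
        n_coding <- 413L  # premature stop at codon 414 of 440
        nl <- seqs$A_camellia
        # 91 nonsynonymous + 82 synonymous single-nt differences in the
        # coding region -> 173/1239 nt (86%), 91/413 aa (78%)
        avail <- 2:n_coding
        n_nonsyn <- 91L; n_syn <- 82L
        placed_nonsyn <- 0L; placed_syn <- 0L
        guard <- 0L
        while ((placed_nonsyn < n_nonsyn || placed_syn < n_syn) &&
               (guard <- guard + 1L) < 1e5) {
          ci <- avail[sample.int(length(avail), 1L)]
          avail <- setdiff(avail, ci)
          if (!length(avail)) abort("ran out of codons while engineering the paralog")
          v <- codon_variants(nl[ci])
          one_nt <- function(pool) {
            pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
            pool[vapply(pool, function(x) {
              sum(strsplit(x, "")[[1L]] != strsplit(nl[ci], "")[[1L]]) == 1L
            }, logical(1))]
          }
          if (placed_nonsyn < n_nonsyn) {
            cand <- one_nt(v$nonsyn)
            if (length(cand)) {
              nl[ci] <- sample(cand, 1L)
              placed_nonsyn <- placed_nonsyn + 1L
              next
            }
          }
          if (placed_syn < n_syn) {
            cand <- one_nt(v$syn)
            if (length(cand)) {
              nl[ci] <- sample(cand, 1L)
              placed_syn <- placed_syn + 1L
            }
          }
        }
        if (placed_nonsyn < n_nonsyn || placed_syn < n_syn) {
          abort("failed to engineer the paralog difference pattern")
        }
        nl[414L] <- "TAA"
        camellia_naga_like_full <- paste(nl, collapse = "")

        # coding-region alignment: specialists carry NAGA_like, the seven
        # non-specialists their NAGA sequence
        nl_coding <- nl[seq_len(n_coding)]
        nseqs <- setNames(vector("list", length(taxa)), taxa)
        for (sp in fg) nseqs[[sp]] <- nl_coding
        for (sp in bg) nseqs[[sp]] <- seqs[[sp]][seq_len(n_coding)]
        nseqs <- engineer_variable_columns(nseqs, setdiff(fg, "A_camellia"),
                                           panel$variable_sites[panel$gene == "NAGA_like"],
                                           4:(3L * n_coding))
        alignments[["NAGA_like"]] <- codon_alignment(
          vapply(nseqs, paste, character(1), collapse = ""))
      }
    }
    alignments <- alignments[panel$gene]
    list(alignments = alignments,
         camellia_naga = camellia_naga,
         camellia_naga_like_full = camellia_naga_like_full,
         tree = tree, specialists = fg, panel = panel)
  })
}

#' Simulate the six-gene panel under the two-ratio branch model
#'
#' Each gene is evolved on [andrena_tree()] (foreground stem per gene) under
#' the branch model with the panel's `omega_fg`/`omega_bg` as generating
#' truth, its panel coding length, and shared `kappa`/codon frequencies.
#'
#' @param seed Integer seed.
#' @param kappa Generating transition/transversion ratio (default 2).
#' @param codon_freqs Generating codon frequencies (default
#'   [panel_codon_freqs()]).
#' @param genes Subset of panel genes (default all six).
#' @return Named list of simulation results (see
#'   [simulate_codon_alignment()]), one per gene.
#' @export
simulate_panel_alignments <- function(seed = 1L, kappa = 2,
                                      codon_freqs = panel_codon_freqs(),
                                      genes = NULL) {
  panel <- galactose_gene_panel()
  if (!is.null(genes)) panel <- panel[panel$gene %in% genes, , drop = FALSE]
  out <- purrr::map(seq_len(nrow(panel)), function(r) {
    cfg <- simulation_config(
      tree = andrena_tree(fg_stem = panel$fg_stem[r]),
      family = "branch", n_codons = panel$length_nt[r] %/% 3L,
      seed = seed + r, kappa = kappa,
      omega_fg = panel$omega_fg[r], omega_bg = panel$omega_bg[r],
      codon_freqs = codon_freqs)
    simulate_codon_alignment(cfg)
  })
  setNames(out, panel$gene)
}
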