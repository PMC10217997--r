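# Seeded generators: codon alignments evolved along a labeled tree,
# duplicated gene pairs at a controlled identity, and short reads at
# controlled abundance ratios.

#' Configuration for codon-alignment simulation
#'
#' @param tree A [labeled_tree] (or Newick with `#1` foreground marks).
#'   Branch lengths are expected substitutions per codon.
#' @param family Generating model family (see [codon_model_spec()]).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed; identical configs give identical output.
#' @param kappa,omega,omega_fg,omega_bg,omega0,omega2,p0,p1,codon_freqs
#'   Model parameters, as in [codon_model_spec()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(tree, family = "M0", n_codons = 400, seed = 1L,
                              kappa = 2, omega = 0.2, omega_fg = 0.2,
                              omega_bg = 0.2, omega0 = 0.1, omega2 = 2,
                              p0 = 0.7, p1 = 0.2,
                              codon_freqs = codon_freqs_equal()) {
  tree <- as_labeled_tree(tree)
  spec <- codon_model_spec(family, kappa = kappa, omega = omega,
                           omega_fg = omega_fg, omega_bg = omega_bg,
                           omega0 = omega0, omega2 = omega2, p0 = p0, p1 = p1,
                           codon_freqs = codon_freqs)
  structure(list(tree = tree, spec = spec, n_codons = as.integer(n_codons),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Simulate a codon alignment along a labeled tree
#'
#' Root codons are drawn from the model's equilibrium frequencies and
#' evolved along each branch with transition probabilities from the model's
#' rate matrix.  Branch-site families draw a site class per codon and switch
#' to the foreground omega on foreground-flagged branches; the true class of
#' every site is returned for validating site-posterior methods.
#'
#' @param config A [simulation_config()].
#' @return List: `alignment` (a [codon_alignment]), `tree`, `site_class`
#'   (integer per site: 1-based class index; for branch-site families
#'   classes 3/4 are the positively selected 2a/2b classes), `positive_site`
#'   (logical; `TRUE` where the site evolves under `omega2` on the
#'   foreground), and `config`.
#' @export
simulate_codon_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$spec
  classes <- spec_classes(spec)
  n_class <- nrow(classes$omega)
  ld <- tree_engine_data(config$tree, config$tree$phylo$tip.label)
  pi <- spec$codon_freqs
  n_site <- config$n_codons

  # mixture models share one rate scale (mixture-averaged background rate),
  # matching the likelihood engine's convention
  rate_scale <- if (n_class > 1L) {
    sum(classes$prob * vapply(classes$omega[, 1], function(w) {
      codon_mean_rate(spec$kappa, w, pi)
    }, numeric(1)))
  } else NULL

  with_seed(config$seed, {
    site_class <- if (n_class > 1L) {
      sample.int(n_class, n_site, replace = TRUE, prob = classes$prob)
    } else rep(1L, n_site)
    node_states <- matrix(NA_integer_, ld$n_node, n_site)
    node_states[ld$root0 + 1L, ] <- sample.int(61, n_site, replace = TRUE, prob = pi)

    n_edge <- nrow(ld$edges0)
    for (e in rev(seq_len(n_edge))) {  # reverse postorder = preorder
      parent <- ld$edges0[e, 1] + 1L
      child <- ld$edges0[e, 2] + 1L
      fg <- ld$edge_fg[e] == 1L
      for (c in unique(site_class)) {
        idx <- which(site_class == c)
        omega_e <- classes$omega[c, if (fg) 2L else 1L]
        P <- codon_pmatrix(spec$kappa, omega_e, ld$edge_len[e], pi,
                           rate_scale = rate_scale)
        ps <- node_states[parent, idx]
        for (s in unique(ps)) {
          sel <- idx[ps == s]
          node_states[child, sel] <- sample.int(61, length(sel),
                                                replace = TRUE, prob = P[s, ])
        }
      }
    }
    cs <- codon_states()
    seqs <- vapply(seq_len(ld$ntip), function(i) {
      paste(cs$codons[node_states[i, ]], collapse = "")
    }, character(1))
    names(seqs) <- ld$tip_order
    positive <- if (spec$family == "branch_site_A") site_class >= 3L else
      rep(FALSE, n_site)
    list(alignment = codon_alignment(seqs), tree = config$tree,
         site_class = site_class, positive_site = positive, config = config)
  })
}

# single-nucleotide codon variants of `codon` (sense codons only), split by
# synonymous/nonsynonymous
codon_variants <- function(codon) {
  cs <- codon_states()
  i <- match(codon, cs$codons)
  p <- cs$pairs
  rows <- p[p[, "i"] == i | p[, "j"] == i, , drop = FALSE]
  other <- ifelse(rows[, "i"] == i, rows[, "j"], rows[, "i"])
  list(syn = cs$codons[other[rows[, "synonymous"] == 1L]],
       nonsyn = cs$codons[other[rows[, "synonymous"] == 0L]])
}

#' Simulate a duplicated gene pair at a controlled identity
#'
#' Generates an ancestral CDS (ATG start, sense codons, no internal stop),
#' duplicates it, and applies single-nucleotide substitutions to copy B
#' until the nucleotide identity reaches the target.  Substitutions prefer
#' synonymous third-position changes with probability `syn_bias`, so the
#' translated identity drops below the nucleotide identity, as in real
#' young paralog pairs.  Optionally a premature stop codon (TAA) is written
#' at a stated codon of copy B.
#'
#' @param n_codons CDS length in codons (default 440).
#' @param target_identity Target nucleotide identity in `(2/3, 1]`.
#' @param stop_codon 1-based codon index of the engineered premature stop in
#'   copy B, or `NULL` for none.
#' @param syn_bias Probability that a substitution is synonymous when
#'   possible (default 0.5).
#' @param seed Integer seed.
#' @return List: `copy_a`, `copy_b` (CDS strings, equal length),
#'   `diff_positions` (1-based nt positions differing), `stop_codon`,
#'   `n_codons`.
#' @export
simulate_paralog_pair <- function(n_codons = 440, target_identity = 0.86,
                                  stop_codon = NULL, syn_bias = 0.5,
                                  seed = 1L) {
  if (target_identity > 1 || target_identity < 0) {
    abort("`target_identity` must be in [0, 1]")
  }
  n_nt <- 3L * n_codons
  n_diff <- round((1 - target_identity) * n_nt)
  if (n_diff > n_codons - 1L) {
    abort("target identity incompatible with length: would need more than one substitution per codon")
  }
  cs <- codon_states()
  sense_no_stop <- setdiff(cs$codons, c("TAA", "TAG", "TGA"))
  with_seed(seed, {
    anc <- c("ATG", sample(sense_no_stop, n_codons - 1L, replace = TRUE))
    copy_b <- anc
    mutable <- setdiff(seq_len(n_codons), c(1L, stop_codon))
    targets <- sample(mutable, n_diff)
    for (k in targets) {
      v <- codon_variants(copy_b[k])
      pick_syn <- length(v$syn) && (runif(1) < syn_bias || !length(v$nonsyn))
      pool <- if (pick_syn) v$syn else v$nonsyn
      pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
      if (!length(pool)) pool <- v$syn
      # keep exactly one nt difference per mutated codon
      cand <- pool[vapply(pool, function(x) {
        sum(strsplit(x, "")[[1L]] != strsplit(copy_b[k], "")[[1L]]) == 1L
      }, logical(1))]
      if (!length(cand)) next
      copy_b[k] <- sample(cand, 1L)
    }
    if (!is.null(stop_codon)) {
      if (stop_codon > n_codons) abort("`stop_codon` exceeds the CDS length")
      copy_b[stop_codon] <- "TAA"
    }
    a <- paste(anc, collapse = "")
    b <- paste(copy_b, collapse = "")
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    list(copy_a = a, copy_b = b, diff_positions = which(av != bv),
         stop_codon = stop_codon, n_codons = n_codons)
  })
}

#' Simulate short single-end reads from transcripts
#'
#' A read's source transcript is chosen proportionally to `abundance x
#' effective length` (effective length = transcript length − read length
#' + 1); the start is uniform over valid positions and the strand uniform.
#' Per-base substitution errors occur at `error_rate`.  Truth tags (source,
#' strand, start) are embedded in the read names.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param abundances Relative molar abundances, one per transcript.
#' @param n_reads Number of reads.
#' @param read_len Read length (default 150).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @return Named character vector of read sequences; names are
#'   `read<i>|<transcript>|<strand>|<start>`.
#' @export
simulate_reads <- function(transcripts, abundances, n_reads, read_len = 150,
                           error_rate = 0, seed = 1L) {
  stopifnot(is.character(transcripts), !is.null(names(transcripts)),
            length(abundances) == length(transcripts))
  lens <- nchar(transcripts)
  eff <- pmax(lens - read_len + 1L, 0L)
  if (any(eff == 0L)) {
    warn(paste0("transcript(s) shorter than the read length skipped: ",
                paste(names(transcripts)[eff == 0L], collapse = ", ")))
  }
  wt <- abundances * eff
  if (n_reads == 0L || sum(wt) == 0) return(setNames(character(0), character(0)))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    src <- sample.int(length(transcripts), n_reads, replace = TRUE,
                      prob = wt / sum(wt))
    start <- vapply(src, function(i) sample.int(eff[i], 1L), integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- substring(transcripts[src], start, start + read_len - 1L)
    flip <- strand == "-"
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        v <- strsplit(r, "")[[1L]]
        hit <- runif(length(v)) < error_rate
        if (any(hit)) {
          v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L),
                           character(1))
        }
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    names(reads) <- sprintf("read%06d|%s|%s|%d", seq_len(n_reads),
                            names(transcripts)[src], strand, start)
    reads
  })
}

#' Write reads to a FASTQ file
#'
#' @param reads Named character vector of read sequences.
#' @param file Output path.
#' @param quality_char Constant base-quality character (default `"I"`).
#' @return `file`, invisibly.
#' @export
write_fastq <- function(reads, file, quality_char = "I") {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads) %||% paste0("read", seq_along(reads))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(quality_char, n)
  }, character(1)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = qual)
  invisible(file)
}
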