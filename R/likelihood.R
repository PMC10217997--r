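# Phylogenetic log-likelihood of a codon alignment under a model spec.

# assemble the data bundle shared by likelihood evaluation and fitting
likelihood_data <- function(aln, tree) {
  aln <- as_codon_alignment(aln)
  tree <- as_labeled_tree(tree)
  td <- tree_engine_data(tree, aln$taxa)
  pat <- compress_patterns(aln, td$tip_order)
  c(td, pat, list(pairs = codon_states()$pairs))
}

engine_eval <- function(ld, edge_len, kappa, classes, pi,
                        want_grad = FALSE, want_class_sitelik = FALSE) {
  codon_loglik_engine(
    states = ld$states, weights = ld$weights,
    edges0 = ld$edges0, edge_len = edge_len, edge_fg = ld$edge_fg,
    n_node = ld$n_node, root0 = ld$root0,
    pi = pi, kappa = kappa,
    class_omega = classes$omega, class_prob = as.numeric(classes$prob),
    pairs = ld$pairs,
    common_scale = nrow(classes$omega) > 1L,
    want_grad = want_grad, want_class_sitelik = want_class_sitelik
  )
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Felsenstein pruning over compressed site patterns; missing codons (gaps,
#' ambiguities, stops) contribute all-ones partial likelihoods.  For
#' branch-site families the site likelihood is a mixture over site classes,
#' with the foreground omega applied on foreground-flagged branches.  The
#' tree's branch lengths are used as given (expected substitutions per
#' codon).
#'
#' @param aln A [codon_alignment] (or named character vector of aligned
#'   sequences).
#' @param tree A [labeled_tree] whose tip labels match the alignment taxa.
#'   A single-taxon alignment needs no tree (`tree = NULL`): the
#'   log-likelihood collapses to the sum of log codon frequencies.
#' @param spec A [codon_model_spec].
#' @return The log-likelihood (scalar).  Degenerate parameter/data
#'   combinations (a site pattern with probability zero) return `-Inf`
#'   rather than an error.
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAGA"))
#' tr <- labeled_tree("(a:0.2,b:0.2);")
#' log_likelihood(aln, tr, codon_model_spec("M0", kappa = 2, omega = 0.5))
log_likelihood <- function(aln, tree, spec) {
  aln <- as_codon_alignment(aln)
  stopifnot(inherits(spec, "codon_model_spec"))
  if (length(aln$taxa) == 1L) {
    st <- aln$states[1L, ]
    return(sum(log(spec$codon_freqs[st[!is.na(st)]])))
  }
  if (is.null(tree)) abort("a tree is required for alignments with >1 taxon")
  tree <- as_labeled_tree(tree)
  if (spec$family != "M0" && length(tree$fg_nodes) == 0L) {
    abort("branch and branch-site models require a non-empty foreground")
  }
  ld <- likelihood_data(aln, tree)
  res <- engine_eval(ld, ld$edge_len, spec$kappa, spec_classes(spec),
                     spec$codon_freqs)
  res$loglik
}
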