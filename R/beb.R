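# Bayes empirical Bayes site posteriors for branch-site model A.

#' BEB posterior probabilities of positive selection per codon site
#'
#' For a fitted branch-site model A, computes per-site posterior
#' probabilities that the site belongs to the positively selected class
#' (classes 2a/2b, foreground omega2), integrating out the site-class
#' proportions and `omega0` over a uniform grid prior (Bayes empirical
#' Bayes).  `kappa`, `omega2` and branch lengths are held at their MLEs.
#' The proportion grid uses the transform `p0 = t1`, `p1 = (1 - t1) t2`
#' with `t1`, `t2` and `omega0` each on `grid_size` midpoints of (0, 1).
#'
#' @param fit A [codon_fit] of family `"branch_site_A"`.
#' @param grid_size Grid points per dimension (default 10).
#' @param threshold Posterior cutoff for flagging sites (default 0.95).
#' @param ref_taxon Taxon whose amino acid is reported per site (default the
#'   first alignment taxon).
#' @return A tibble (class `beb_posteriors`) with one row per codon site:
#'   `site`, `ref_aa`, class posteriors `p_class0`, `p_class1`, `p_class2a`,
#'   `p_class2b`, `posterior` (positive class, `p_class2a + p_class2b`), and
#'   `flagged` (`posterior > threshold`).
#' @export
beb_site_posteriors <- function(fit, grid_size = 10, threshold = 0.95,
                                ref_taxon = NULL) {
  stopifnot(inherits(fit, "codon_fit"))
  if (fit$family != "branch_site_A") {
    abort("BEB posteriors require a branch-site model A fit")
  }
  aln <- fit$alignment
  ld <- likelihood_data(aln, fit$tree)
  ld$edge_len <- fit$branch_lengths
  npat <- length(ld$weights)
  mid <- (seq_len(grid_size) - 0.5) / grid_size

  # per-omega0 class site log-likelihoods (4 x npat each)
  class_ll <- lapply(mid, function(w0) {
    spec_g <- fit$spec
    spec_g$omega0 <- w0
    res <- engine_eval(ld, ld$edge_len, fit$spec$kappa, spec_classes(spec_g),
                       fit$codon_freqs, want_class_sitelik = TRUE)
    if (!is.finite(res$loglik)) {
      abort("degenerate likelihood during BEB grid evaluation")
    }
    res$class_site_loglik
  })

  grid <- expand.grid(i_w0 = seq_len(grid_size), t1 = mid, t2 = mid)
  G <- nrow(grid)
  log_weight <- numeric(G)
  post_num <- matrix(0, 4, npat)     # accumulated p(class, site | theta) * w(theta)
  log_joint <- numeric(G)
  site_post_g <- vector("list", G)

  for (g in seq_len(G)) {
    p0 <- grid$t1[g]
    p1 <- (1 - grid$t1[g]) * grid$t2[g]
    p2 <- 1 - p0 - p1
    w <- p0 / (p0 + p1)
    prob <- c(p0, p1, p2 * w, p2 * (1 - w))
    cll <- class_ll[[grid$i_w0[g]]]
    m <- apply(cll, 2, max)
    f_rel <- exp(sweep(cll, 2, m))               # 4 x npat, scaled per pattern
    f_tot <- colSums(prob * f_rel)
    log_joint[g] <- sum(ld$weights * (log(f_tot) + m))
    site_post_g[[g]] <- sweep(prob * f_rel, 2, f_tot, "/")  # class | site, theta
  }
  lw <- log_joint - max(log_joint)
  wts <- exp(lw) / sum(exp(lw))
  for (g in seq_len(G)) post_num <- post_num + wts[g] * site_post_g[[g]]

  idx <- ld$pattern_index
  post <- t(post_num)[idx, , drop = FALSE]
  colnames(post) <- c("p_class0", "p_class1", "p_class2a", "p_class2b")

  if (is.null(ref_taxon)) ref_taxon <- aln$taxa[1L]
  if (!ref_taxon %in% aln$taxa) abort("`ref_taxon` not in alignment")
  ref_aa <- strsplit(translate_cds(aln$sequences[[ref_taxon]]), "")[[1L]]

  out <- as_tibble(post)
  out <- mutate(out,
    site = seq_len(aln$n_codons),
    ref_aa = ref_aa,
    posterior = .data$p_class2a + .data$p_class2b,
    flagged = .data$posterior > threshold
  )
  out <- select(out, "site", "ref_aa", dplyr::starts_with("p_class"),
                "posterior", "flagged")
  class(out) <- c("beb_posteriors", class(out))
  attr(out, "threshold") <- threshold
  out
}
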