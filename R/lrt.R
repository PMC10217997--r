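# Likelihood ratio tests between nested codon model fits.

.nested_pairs <- list(
  c("M0", "branch"),
  c("branch_site_A1", "branch_site_A")
)

#' Likelihood ratio test between nested codon model fits
#'
#' Computes `2 * (lnL_alt - lnL_null)` (clamped at zero) and the upper-tail
#' chi-square probability.  The supported nestings are M0 within the branch
#' model, and branch-site model A1 within model A; both add one free
#' parameter, so `df = 1` by default.
#'
#' @param fit_null,fit_alt [codon_fit] objects fitted to the same alignment
#'   and tree, with `fit_null`'s family nested in `fit_alt`'s.
#' @param df Degrees of freedom for the chi-square reference (default: the
#'   difference in free parameter counts).
#' @return A one-row tibble (class `codon_lrt`) with `null_family`,
#'   `alt_family`, `lnL_null`, `lnL_alt`, `stat_2dlnl`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt, df = NULL) {
  stopifnot(inherits(fit_null, "codon_fit"), inherits(fit_alt, "codon_fit"))
  ok <- any(vapply(.nested_pairs, function(p) {
    identical(p, c(fit_null$family, fit_alt$family))
  }, logical(1)))
  if (!ok) {
    abort(paste0("families are not nested (null first): ",
                 fit_null$family, " vs ", fit_alt$family))
  }
  if (fit_null$alignment$n_codons != fit_alt$alignment$n_codons ||
      !identical(fit_null$alignment$taxa, fit_alt$alignment$taxa)) {
    abort("fits must come from the same alignment")
  }
  if (is.null(df)) df <- 1L
  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  out <- tibble(
    null_family = fit_null$family, alt_family = fit_alt$family,
    lnL_null = fit_null$lnL, lnL_alt = fit_alt$lnL,
    stat_2dlnl = stat, df = as.integer(df),
    p_value = pchisq(stat, df = df, lower.tail = FALSE)
  )
  class(out) <- c("codon_lrt", class(out))
  out
}

#' Chi-square upper tail for a printed 2dlnL statistic
#'
#' Convenience wrapper for checking reported likelihood-ratio statistics.
#'
#' @param stat_2dlnl Likelihood-ratio statistic(s).
#' @param df Degrees of freedom.
#' @return Upper-tail probabilities.
#' @export
#' @examples
#' lrt_pvalue(24.279)  # ~8.34e-7
lrt_pvalue <- function(stat_2dlnl, df = 1) {
  pchisq(stat_2dlnl, df = df, lower.tail = FALSE)
}
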