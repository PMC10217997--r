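# broom-style tidiers for fitted objects.

#' Tidy a fitted codon model
#'
#' @param x A [codon_fit].
#' @param ... Unused.
#' @return Tibble with one row per global parameter: `term`, `estimate`.
#' @export
tidy.codon_fit <- function(x, ...) {
  pars <- spec_parameters(x$spec)
  tibble(term = names(pars), estimate = unname(unlist(pars)))
}

#' One-row summary of a fitted codon model
#'
#' @param x A [codon_fit].
#' @param ... Unused.
#' @return Tibble: `family`, `logLik`, `n_free_params`, `n_codons`,
#'   `n_taxa`, `converged`, `tree_length`.
#' @export
glance.codon_fit <- function(x, ...) {
  tibble(
    family = x$family, logLik = x$lnL, n_free_params = x$n_free_params,
    n_codons = x$alignment$n_codons, n_taxa = length(x$alignment$taxa),
    converged = x$converged, tree_length = sum(x$branch_lengths)
  )
}

#' @export
tidy.codon_lrt <- function(x, ...) {
  tibble(term = c("stat_2dlnl", "df", "p_value"),
         estimate = c(x$stat_2dlnl, x$df, x$p_value))
}
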