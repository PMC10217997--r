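# Goldman-Yang style codon rate matrix (61 sense codons).

#' Build a codon instantaneous rate matrix
#'
#' Muse/Goldman-Yang style parameterisation on the 61 sense codons: the rate
#' from codon `i` to codon `j` is zero unless the codons differ at exactly
#' one position, and otherwise proportional to the target codon's equilibrium
#' frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes.  Rows sum to zero; by default the matrix is scaled
#' so the mean substitution rate at stationarity is 1 (branch lengths are
#' then expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS, `>= 0`.
#' @param codon_freqs 61 equilibrium codon frequencies (defaults to equal).
#' @param scale Scale to unit mean rate at stationarity?
#' @return A 61 x 61 rate matrix with codon row/column names.
#' @export
#' @examples
#' Q <- build_rate_matrix(kappa = 2, omega = 0.5)
#' max(abs(rowSums(Q)))  # ~0
build_rate_matrix <- function(kappa, omega, codon_freqs = codon_freqs_equal(),
                              scale = TRUE) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    abort("`kappa` must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega < 0) {
    abort("`omega` must be a single non-negative number")
  }
  check_codon_freqs(codon_freqs)
  cs <- codon_states()
  p <- cs$pairs
  Q <- matrix(0, 61, 61, dimnames = list(cs$codons, cs$codons))
  rate <- ifelse(p[, "transition"] == 1L, kappa, 1) *
    ifelse(p[, "synonymous"] == 1L, 1, omega)
  Q[cbind(p[, "i"], p[, "j"])] <- rate * codon_freqs[p[, "j"]]
  Q[cbind(p[, "j"], p[, "i"])] <- rate * codon_freqs[p[, "i"]]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(codon_freqs * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# mean rate (expected substitutions per codon per unit time) of an unscaled Q
codon_mean_rate <- function(kappa, omega, codon_freqs) {
  Q <- build_rate_matrix(kappa, omega, codon_freqs, scale = FALSE)
  -sum(codon_freqs * diag(Q))
}

#' Codon transition probability matrix
#'
#' `expm(Q t)` computed by symmetric eigendecomposition of the reversible
#' rate matrix.
#'
#' @inheritParams build_rate_matrix
#' @param t Branch length (expected substitutions per codon when `rate_scale`
#'   is the matrix's own mean rate).
#' @param rate_scale Divisor applied to the unscaled matrix before
#'   exponentiation; `NULL` (default) scales to unit mean rate.
#' @return A 61 x 61 stochastic matrix.
#' @export
codon_pmatrix <- function(kappa, omega, t, codon_freqs = codon_freqs_equal(),
                          rate_scale = NULL) {
  Q <- build_rate_matrix(kappa, omega, codon_freqs, scale = is.null(rate_scale))
  if (!is.null(rate_scale)) Q <- Q / rate_scale
  d <- sqrt(codon_freqs)
  B <- sweep(Q * d, 2, d, "/")  # diag(d) %*% Q %*% diag(1/d), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- (e$vectors %*% (t(e$vectors) * exp(e$values * t)))
  P <- P * outer(1 / d, d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}
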