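# Codon model specifications: M0, two-ratio branch model, and branch-site
# models A / A1.

model_families <- c("M0", "branch", "branch_site_A", "branch_site_A1")

#' Specify a codon substitution model
#'
#' @param family One of `"M0"` (single dN/dS for the whole tree), `"branch"`
#'   (separate foreground and background dN/dS), `"branch_site_A"` (site
#'   classes: purifying `omega0`, neutral 1, and a foreground-only class
#'   `omega2 >= 1`), or `"branch_site_A1"` (model A with `omega2 = 1` fixed,
#'   the null of the branch-site test).
#' @param kappa Transition/transversion ratio, `> 0`.
#' @param omega dN/dS for `"M0"`.
#' @param omega_fg,omega_bg Foreground/background dN/dS for `"branch"`.
#' @param omega0 Purifying-class dN/dS in `(0, 1)` for branch-site models.
#' @param omega2 Positive-selection-class dN/dS `>= 1` for
#'   `"branch_site_A"` (fixed at 1 for `"branch_site_A1"`).
#' @param p0,p1 Site-class proportions for branch-site models; the remaining
#'   mass `1 - p0 - p1` is split between classes 2a/2b proportionally to
#'   `p0 : p1`.
#' @param codon_freqs 61 equilibrium codon frequencies.
#' @return An object of class `codon_model_spec`.
#' @export
#' @examples
#' codon_model_spec("branch", kappa = 2, omega_fg = 0.68, omega_bg = 0.021)
codon_model_spec <- function(family, kappa = 2,
                             omega = 0.2, omega_fg = 0.2, omega_bg = 0.2,
                             omega0 = 0.1, omega2 = 2, p0 = 0.7, p1 = 0.2,
                             codon_freqs = codon_freqs_equal()) {
  family <- match.arg(family, model_families)
  if (!is.finite(kappa) || kappa <= 0) abort("`kappa` must be positive")
  check_codon_freqs(codon_freqs)
  spec <- list(family = family, kappa = kappa, codon_freqs = codon_freqs)
  chk_w <- function(w, nm) {
    if (!is.finite(w) || w < 0) abort(paste0("`", nm, "` must be non-negative"))
  }
  if (family == "M0") {
    chk_w(omega, "omega")
    spec$omega <- omega
  } else if (family == "branch") {
    chk_w(omega_fg, "omega_fg"); chk_w(omega_bg, "omega_bg")
    spec$omega_fg <- omega_fg
    spec$omega_bg <- omega_bg
  } else {
    if (!is.finite(omega0) || omega0 <= 0 || omega0 >= 1) {
      abort("`omega0` must lie in (0, 1)")
    }
    if (family == "branch_site_A1") omega2 <- 1
    if (!is.finite(omega2) || omega2 < 1) abort("`omega2` must be >= 1")
    if (any(!is.finite(c(p0, p1))) || p0 < 0 || p1 < 0 || p0 + p1 > 1) {
      abort("`p0`, `p1` must be non-negative with p0 + p1 <= 1")
    }
    if (p0 + p1 <= 0) abort("p0 + p1 must be positive")
    spec$omega0 <- omega0
    spec$omega2 <- omega2
    spec$p0 <- p0
    spec$p1 <- p1
  }
  structure(spec, class = "codon_model_spec")
}

#' @export
print.codon_model_spec <- function(x, ...) {
  pars <- spec_parameters(x)
  cat("<codon_model_spec> ", x$family, ": ",
      paste(names(pars), signif(unlist(pars), 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

spec_parameters <- function(spec) {
  spec[setdiff(names(spec), c("family", "codon_freqs"))]
}

# site classes: matrix of (background, foreground) omega + class proportions
spec_classes <- function(spec) {
  switch(spec$family,
    M0 = list(omega = matrix(spec$omega, 1, 2), prob = 1),
    branch = list(omega = matrix(c(spec$omega_bg, spec$omega_fg), 1, 2), prob = 1),
    {
      p2 <- 1 - spec$p0 - spec$p1
      w <- spec$p0 / (spec$p0 + spec$p1)
      list(
        omega = rbind(
          c(spec$omega0, spec$omega0),
          c(1, 1),
          c(spec$omega0, spec$omega2),
          c(1, spec$omega2)
        ),
        prob = c(spec$p0, spec$p1, p2 * w, p2 * (1 - w))
      )
    }
  )
}

n_free_parameters <- function(family, n_edge) {
  n_edge + switch(family,
    M0 = 2,              # kappa, omega
    branch = 3,          # kappa, omega_fg, omega_bg
    branch_site_A = 5,   # kappa, omega0, omega2, p0, p1
    branch_site_A1 = 4   # kappa, omega0, p0, p1
  )
}
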