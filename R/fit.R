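# Maximum-likelihood fitting of codon models on a fixed topology.

#' Optimizer settings for [fit_codon_model()]
#'
#' @param n_restarts Number of seeded random restarts of the global
#'   parameters (branch lengths are warm-started from the best fit so far).
#' @param seed Integer seed for the restart draws.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance factor (see [stats::optim()]).
#' @param pgtol L-BFGS-B projected-gradient tolerance; the default accepts a
#'   solution once the log-likelihood gradient is numerically flat.
#' @return A list of control settings.
#' @export
fit_control <- function(n_restarts = 3, seed = 1L, maxit = 1000, factr = 1e7,
                        pgtol = 1e-4) {
  list(n_restarts = n_restarts, seed = as.integer(seed),
       maxit = maxit, factr = factr, pgtol = pgtol)
}

# bounds shared by all families
.bounds <- list(
  t = c(1e-8, 20), kappa = c(0.1, 20), omega = c(1e-4, 50),
  omega0 = c(1e-4, 0.999), omega2 = c(1, 50), x = c(-12, 12)
)

# free-parameter layout per family: names + bounds for the non-branch block
family_layout <- function(family) {
  switch(family,
    M0 = list(names = c("kappa", "omega"),
              lo = c(.bounds$kappa[1], .bounds$omega[1]),
              hi = c(.bounds$kappa[2], .bounds$omega[2])),
    branch = list(names = c("kappa", "omega_bg", "omega_fg"),
                  lo = c(.bounds$kappa[1], rep(.bounds$omega[1], 2)),
                  hi = c(.bounds$kappa[2], rep(.bounds$omega[2], 2))),
    branch_site_A = list(
      names = c("kappa", "omega0", "omega2", "x1", "x2"),
      lo = c(.bounds$kappa[1], .bounds$omega0[1], .bounds$omega2[1], rep(.bounds$x[1], 2)),
      hi = c(.bounds$kappa[2], .bounds$omega0[2], .bounds$omega2[2], rep(.bounds$x[2], 2))),
    branch_site_A1 = list(
      names = c("kappa", "omega0", "x1", "x2"),
      lo = c(.bounds$kappa[1], .bounds$omega0[1], rep(.bounds$x[1], 2)),
      hi = c(.bounds$kappa[2], .bounds$omega0[2], rep(.bounds$x[2], 2)))
  )
}

# softmax over (x1, x2, 0) -> (p0, p1, p2)
props_from_x <- function(x1, x2) {
  z <- exp(c(x1, x2, 0) - max(x1, x2, 0))
  z / sum(z)
}

params_to_spec <- function(family, extras, codon_freqs) {
  e <- as.list(extras)
  switch(family,
    M0 = codon_model_spec("M0", kappa = e$kappa, omega = e$omega,
                          codon_freqs = codon_freqs),
    branch = codon_model_spec("branch", kappa = e$kappa,
                              omega_fg = e$omega_fg, omega_bg = e$omega_bg,
                              codon_freqs = codon_freqs),
    {
      p <- props_from_x(e$x1, e$x2)
      codon_model_spec(family, kappa = e$kappa, omega0 = e$omega0,
                       omega2 = if (family == "branch_site_A") e$omega2 else 1,
                       p0 = p[1], p1 = p[2], codon_freqs = codon_freqs)
    }
  )
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Jointly maximises branch lengths and the family's global parameters
#' (kappa, dN/dS ratios, site-class proportions) with bounded quasi-Newton
#' (L-BFGS-B).  Branch-length partial derivatives are analytic (two-pass
#' pruning); the few global parameters use central finite differences.
#' Seeded random restarts of the global parameters guard against local
#' optima.
#'
#' @inheritParams log_likelihood
#' @param family Model family: `"M0"`, `"branch"`, `"branch_site_A"`, or
#'   `"branch_site_A1"`.
#' @param codon_freqs `"F3x4"` (position-specific nucleotide frequencies
#'   estimated from the alignment, the default), `"equal"`, or a numeric
#'   61-vector.
#' @param fix_branch_lengths Keep the tree's branch lengths fixed (faster;
#'   default re-optimises them, standard practice for these models).
#' @param control Optimizer settings from [fit_control()].
#' @return An object of class `codon_fit` with elements `spec` (MLE
#'   parameter values), `lnL`, `tree` (the [labeled_tree] with re-estimated
#'   branch lengths), `converged`, `n_free_params`, `family`, and the input
#'   alignment.  [tidy()] and [glance()] methods are available.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_codon_alignment(simulation_config(
#'   tree = "((a:0.3,b:0.3):0.1,(c:0.3,d:0.3):0.1);",
#'   family = "M0", omega = 0.3, n_codons = 120, seed = 1))
#' fit <- fit_codon_model(sim$alignment, sim$tree, "M0",
#'                        control = fit_control(n_restarts = 1))
#' glance(fit)
#' }
fit_codon_model <- function(aln, tree, family = "M0", codon_freqs = "F3x4",
                            fix_branch_lengths = FALSE,
                            control = fit_control()) {
  aln <- as_codon_alignment(aln)
  tree <- as_labeled_tree(tree)
  family <- match.arg(family, model_families)
  if (family != "M0" && length(tree$fg_nodes) == 0L) {
    abort("branch and branch-site models require foreground branches on the tree")
  }
  pi <- if (is.numeric(codon_freqs)) {
    check_codon_freqs(codon_freqs)
  } else if (identical(codon_freqs, "F3x4")) {
    codon_freqs_f3x4(aln)
  } else if (identical(codon_freqs, "equal")) {
    codon_freqs_equal()
  } else {
    abort("`codon_freqs` must be \"F3x4\", \"equal\", or a numeric 61-vector")
  }

  ld <- likelihood_data(aln, tree)
  n_edge <- nrow(ld$edges0)
  lay <- family_layout(family)
  n_extra <- length(lay$names)
  free_t <- !fix_branch_lengths
  nt <- if (free_t) n_edge else 0L

  t_init <- pmin(pmax(ld$edge_len, 0.01), 5)
  extras_init <- c(kappa = 2,
                   switch(family,
                     M0 = c(omega = 0.2),
                     branch = c(omega_bg = 0.2, omega_fg = 0.2),
                     branch_site_A = c(omega0 = 0.2, omega2 = 2, x1 = log(7), x2 = log(2)),
                     branch_site_A1 = c(omega0 = 0.2, x1 = log(7), x2 = log(2))))

  split_par <- function(par) {
    list(t = if (free_t) par[seq_len(nt)] else ld$edge_len,
         extras = setNames(par[nt + seq_len(n_extra)], lay$names))
  }
  eval_par <- function(par, want_grad = FALSE) {
    p <- split_par(par)
    spec <- params_to_spec(family, p$extras, pi)
    engine_eval(ld, p$t, spec$kappa, spec_classes(spec), pi,
                want_grad = want_grad)
  }
  fn <- function(par) {
    ll <- eval_par(par)$loglik
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  lo <- c(if (free_t) rep(.bounds$t[1], n_edge), lay$lo)
  hi <- c(if (free_t) rep(.bounds$t[2], n_edge), lay$hi)
  gr <- function(par) {
    res <- eval_par(par, want_grad = TRUE)
    if (!is.finite(res$loglik)) return(rep(0, length(par)))
    g_extra <- vapply(seq_len(n_extra), function(k) {
      i <- nt + k
      h <- max(1e-5, 1e-4 * abs(par[i]))
      up <- min(par[i] + h, hi[i]); dn <- max(par[i] - h, lo[i])
      if (up <= dn) return(0)
      pu <- par; pu[i] <- up
      pd <- par; pd[i] <- dn
      (eval_par(pu)$loglik - eval_par(pd)$loglik) / (up - dn)
    }, numeric(1))
    g <- c(if (free_t) as.numeric(res$grad_t), g_extra)
    g[!is.finite(g)] <- 0
    -g
  }

  run_optim <- function(par0) {
    stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = control$maxit, factr = control$factr,
                                pgtol = control$pgtol %||% 1e-4))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(control$seed)

  best <- run_optim(c(if (free_t) t_init, extras_init))
  n_rs <- max(0L, control$n_restarts - 1L)
  for (r in seq_len(n_rs)) {
    ex <- extras_init
    ex["kappa"] <- runif(1, 0.5, 8)
    for (nm in intersect(names(ex), c("omega", "omega_bg", "omega_fg"))) {
      ex[nm] <- exp(runif(1, log(0.02), log(3)))
    }
    if ("omega0" %in% names(ex)) ex["omega0"] <- runif(1, 0.02, 0.9)
    if ("omega2" %in% names(ex)) ex["omega2"] <- exp(runif(1, 0, log(10)))
    if ("x1" %in% names(ex)) { ex["x1"] <- rnorm(1, 1, 1); ex["x2"] <- rnorm(1, 0, 1) }
    t_warm <- if (free_t) pmin(pmax(best$par[seq_len(nt)], 1e-6), 20) else NULL
    cand <- run_optim(c(t_warm, ex))
    if (cand$value < best$value) best <- cand
  }

  p <- split_par(best$par)
  spec <- params_to_spec(family, p$extras, pi)
  fitted_phylo <- ld$phylo
  fitted_phylo$edge.length <- as.numeric(p$t)
  fitted_tree <- tree
  fitted_tree$phylo <- fitted_phylo
  converged <- best$convergence == 0
  if (!converged) {
    warn(paste0("codon model fit (", family, ") did not converge: ",
                best$message))
  }
  structure(
    list(spec = spec, lnL = -best$value, tree = fitted_tree,
         branch_lengths = as.numeric(p$t), family = family,
         converged = converged,
         n_free_params = n_free_parameters(family, if (free_t) n_edge else 0L),
         codon_freqs = pi, alignment = aln, optim = best[c("convergence", "counts")]),
    class = "codon_fit"
  )
}

#' @export
print.codon_fit <- function(x, ...) {
  pars <- spec_parameters(x$spec)
  cat("<codon_fit> ", x$family, "  lnL = ", format(x$lnL, digits = 10),
      if (!x$converged) "  (NOT converged)", "\n  ",
      paste(names(pars), signif(unlist(pars), 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
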