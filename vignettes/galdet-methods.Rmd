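---
title: "Models and methods behind galdet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind galdet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Oil-tea (*Camellia oleifera*) nectar contains galactose derivatives
(raffinose, manninotriose, stachyose) that are toxic to most bees, yet a
small clade of *Andrena* mining bees lives almost exclusively on it.  The
molecular question is whether the genes that metabolise these sugars — the
α-N-acetylgalactosaminidase gene *NAGA*, a specialist-clade duplicate
*NAGA-like*, and the Leloir-pathway genes *galM*, *galK*, *galT*, *galE* —
show lineage-specific adaptation in the specialist clade.  galdet
implements the analysis machinery such a study needs:

* maximum-likelihood codon substitution models on a fixed species tree,
  with likelihood-ratio tests (LRTs) for a foreground/background shift in
  dN/dS and Bayes empirical Bayes (BEB) site posteriors;
* descriptive alignment statistics (variable sites, pairwise identity,
  premature-stop detection);
* a bait-based scheme to apportion RNA-seq reads between two paralogs too
  similar for ordinary read mapping;
* TPM normalisation and fold-change/adjusted-significance DEG filtering;
* seeded simulators so that every stage runs, and is validated, on
  synthetic data with known truth.

## Codon substitution models

The state space is the 61 sense codons of the standard nuclear code.  The
instantaneous rate from codon $i$ to codon $j$ is the Goldman–Yang style

$$
q_{ij} \;=\;
\begin{cases}
0 & \text{more than one position differs},\\
\pi_j & \text{synonymous transversion},\\
\kappa\,\pi_j & \text{synonymous transition},\\
\omega\,\pi_j & \text{nonsynonymous transversion},\\
\kappa\,\omega\,\pi_j & \text{nonsynonymous transition},
\end{cases}
$$

with equilibrium codon frequencies $\pi$ (F3x4 estimated from the
alignment by default; an equal-frequency option is exposed — the frequency
model of the original runs such tables come from is typically unstated, so
exact log-likelihood reproduction to decimals is not guaranteed and not
claimed).  The matrix is reversible, so likelihoods are invariant to root
placement; exponentiation uses the symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$.

Four families are implemented:

* **M0** — one $\omega$ for the whole tree;
* **branch** — $\omega_{fg}$ on foreground branches, $\omega_{bg}$
  elsewhere (the foreground is the stem branch of the specialist clade
  plus every branch within it, marked with `#1` labels in Newick or with
  the `foreground` argument);
* **branch-site model A** — four site classes: purifying
  $(\omega_0,\omega_0)$ with weight $p_0$, neutral $(1,1)$ with $p_1$, and
  foreground-only positive classes $(\omega_0,\omega_2)$ and
  $(1,\omega_2)$ sharing the remaining mass proportionally to $p_0:p_1$,
  with $\omega_2 \ge 1$;
* **model A1** — model A with $\omega_2 = 1$ fixed, the null of the
  branch-site test.

**Scaling convention.**  For single-class families each generator is
scaled to unit mean rate at stationarity, so branch lengths are expected
substitutions per codon (with free branch lengths any per-matrix constant
is absorbed, so this is pure convention).  For the branch-site mixtures
the *relative* rates of the classes on a shared branch matter, so all
class matrices share one scale factor, the mixture-averaged background
mean rate.  The simulator uses the identical convention, and the two
routes (R eigendecomposition for simulation, C++ engine for inference)
are cross-checked against `Matrix::expm` in the tests.

**Missing data.**  Codons that are stops or contain gaps/ambiguities are
treated as missing (all-ones partial likelihoods).  This keeps the
61-state space valid when one sequence carries a premature stop — exactly
the *NAGA-like* situation — without truncating the other taxa.

## Fitting and testing

Branch lengths and global parameters are maximised jointly with bounded
L-BFGS-B ($\omega \in [10^{-4}, 50]$, $\kappa \in [0.1, 20]$, class
proportions through a softmax transform).  Branch-length partials are
analytic (a post-order/pre-order two-pass over the pruning recursions);
the handful of global parameters use central finite differences.  Three
seeded restarts of the global parameters (branch lengths warm-started)
guard against local optima; convergence is declared on a projected
gradient below `1e-4` or a relative function tolerance of about `1e-9`.
Site patterns are compressed before evaluation (no numerical effect).

The LRTs compare nested pairs — M0 within branch, A1 within A.  Each
nesting adds exactly one free parameter, so $2\Delta\ell$ is referred to
$\chi^2_1$; the package defaults to `df = 1` accordingly.  (Published
branch-model tables of this kind sometimes describe the test as `df = 2`
in their methods while printing `p (df = 1)` columns whose values
reproduce under `df = 1`; the one-parameter counting is what the
implementation follows.)  The statistic is clamped at zero.

**BEB.**  After fitting model A, per-site posteriors of the positive
class integrate over a uniform grid prior on the nuisance parameters:
$t_1, t_2, \omega_0$ each on 10 midpoints of $(0,1)$, with
$p_0 = t_1,\; p_1 = (1-t_1)t_2$, and $\kappa$, $\omega_2$ and branch
lengths held at their MLEs.  Sites with posterior $> 0.95$ are flagged.
On simulations with 10% of sites at $\omega_2 = 4$, flagged sites are
strongly enriched for true positives (the recovery rate is reported by
the acceptance script); on $\omega_2 = 1$ null simulations essentially
nothing is flagged.

## Descriptive statistics

A column is *variable* iff at least two distinct unambiguous nucleotides
occur in the surveyed taxa; columns whose only variation involves gaps or
`N` are not counted (the conservative convention of standard polymorphism
tools).  Pairwise identity is matches over aligned columns where neither
sequence is gapped; at the amino-acid level sequences are translated
first and a stop ends the chain, so a premature stop restricts the
comparison to the shared coding prefix.  These two denominator choices
are what reproduce the reference panel's 86% nucleotide / 78% amino-acid
paralog identity, and they are deliberate, documented decisions.
Premature stops are located by an in-frame scan for the first stop
strictly before the terminal codon.

## Bait-based paralog quantification

Two paralogs at ~86% identity defeat ordinary mapping-based
quantification.  Instead, 50-column gap-free windows of their pairwise
alignment with at least 7 mismatches are enumerated, and 5 mutually
non-overlapping windows are sampled uniformly (seeded).  A read counts
for copy X at window j iff it contains copy X's segment — or its reverse
complement — as an exact substring.  Two completions of the obvious
procedure are deliberate: reverse-complement matching (reads are
unstranded; forward-only matching would silently halve the counts) and
the non-overlap constraint (overlapping windows would double-count
reads).  With at least 7 differences per window an error-free read can
never match both copies at the same window.  Matching is exact, as in
`seqkit grep`-style counting; the read simulator can inject errors to
quantify the sensitivity loss.  The expression ratio is the ratio of
total counts; a zero denominator is reported symbolically as infinite
(the situation of a duplicate absent from a lineage), and a supplied
merged-locus TPM is apportioned by the count ratio.

## Expression filtering

TPM is $10^6 (c_i/l_i)/\sum_j (c_j/l_j)$ per sample.  The DEG caller
normalises counts with median-of-ratios size factors, moment-estimates a
per-gene NB dispersion from pooled within-group variability, and applies
a Wald test on the log fold change with Benjamini–Hochberg adjustment.
Genes pass with $FC > 2$ or $FC < 0.5$ and adjusted $p < 0.05$ (all three
thresholds are arguments).  The thresholds, not any particular DE engine,
are the reproducible content here; the caller is validated against
planted-effect simulations and cross-checked against DESeq2 in the test
suite (fold-change correlation and significant-set overlap), but no
attempt is made to reproduce another engine's exact adjusted p-values.  A
zero control mean yields $FC = +\infty$ symbolically, never an error.

## The synthetic study conditions

The generators' defaults *are* the study conditions the package is
validated under, chosen once:

* **Gene panel** (`galactose_gene_panel()`): six genes with coding
  lengths 1320/1239/1077/1182/1152/1098 nt, within-specialist-clade
  variable sites 16/33/29/24/15/8, branch-model truth
  $(\omega_{fg}, \omega_{bg})$ = (0.049, 0.023), (0.680, 0.021),
  (0.251, 0.360), (0.864, 0.161), (0.387, 0.088), (0.129, 0.063), with
  *NAGA-like*, *galK* and *galT* the positively selected members.
* **Tree** (`andrena_tree()`): 12 taxa; a five-species specialist clade
  with short internal branches (~0.4–0.6% per branch, matching the
  panel's 1–3% within-clade variability), moderate genus-level branches
  (3–8%), and a foreground stem of 1.2% — except for *NAGA-like*, whose
  stem (15%) carries the paralog divergence, because in the combined
  alignment the seven duplicate-lacking taxa are represented by their
  *NAGA* sequence (the standard substitution) so the stem absorbs the
  ~14% paralog split.
* **Frequencies** (`panel_codon_freqs()`): F3x4 from mildly AT-rich
  position-specific base compositions typical of hymenopteran CDS;
  $\kappa = 2$.
* **Paralog pair**: 86% nucleotide identity over the 1239-nt coding
  region with a synonymous-biased substitution spectrum so amino-acid
  identity (78%) falls below nucleotide identity, and a premature TAA at
  codon 414 of 440; **reads**: 150 bp, unstranded, uniform starts,
  abundance ratios {1, 10, 120}.

`synthetic_gene_set()` *engineers* alignments so the descriptive
statistics equal the panel values exactly — appropriate for validating
counting code, but those alignments are not draws from a substitution
model.  `simulate_panel_alignments()` *evolves* alignments under the
branch model with the panel truth — appropriate for validating inference,
but a single realisation carries sampling noise: for the weak-effect
genes (noncentrality near 1) a spurious significant LRT has a
non-trivial per-realisation probability, which is why the validation
asserts the full significance pattern for the strong genes and a
majority pattern for the conserved ones, and why single-realisation
$2\Delta\ell$ values are reported rather than asserted.  Neither
generator produces indels, rate variation beyond the site classes,
selection on synonymous codons, or assembly/alignment artefacts — so
passing tests demonstrate correctness of the estimators under the
modelled conditions, not robustness to everything real data can do.

## Validation scale

The test suite and acceptance script size their simulations to run on a
single CPU in minutes while keeping assertions statistically meaningful:
parameter recovery on 500-codon, 12-taxon alignments (M0 $\hat\omega$
within ±0.05, about one standard error at that information content;
branch-model recovery asserted on 3-replicate means); LRT null
calibration on 200 replicates of 6-taxon, 150-codon alignments (type-I
error within binomial 99% bounds of 0.05); BEB recovery at 400 codons;
read-ratio recovery at 20,000 reads within 2 Poisson standard errors.

## Known limitations

* No tree search — the topology is an input; no codon models beyond the
  four families; no among-site rate variation beyond the class structure.
* Exact-substring bait counting loses sensitivity roughly linearly in the
  per-base error rate times the window length; the simulator quantifies
  this but the counter does not correct for it.
* The NB moment test is slightly conservative at very low counts compared
  with full GLM-based engines.
* BEB here fixes $\kappa$, $\omega_2$ and branch lengths at their MLEs;
  posterior uncertainty in those is not propagated.
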