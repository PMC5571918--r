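---
title: "Polarized quartet scoring: model, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarized quartet scoring: model, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyquart)
```

## The problem

For four taxa there are exactly three unrooted binary trees, q1 = AB|CD,
q2 = AC|BD and q3 = AD|BC, distinguished by their single internal branch.
Conventional maximum-likelihood (ML) model selection among the three can fail
under *long-branch attraction* (LBA): when two non-adjacent terminal branches
are much longer than the internal branch, convergent chance similarity
between the two fast lineages accumulates faster than genuine shared
innovation across the short internal branch, and even a nearly correctly
specified model can prefer the tree that joins the two long branches.

This package scores the three topologies by an explicitly Hennigian route:
it asks how many alignment columns *look like shared derived states*
(putative synapomorphies) for each tree under each possible direction of
character change along the internal branch, and then subtracts an ML-based
estimate of how many such columns would be expected by convergence alone if
one of the *other* two trees were true.

## Site-pattern classification

A column restricted to four taxa induces a set partition of the roles
(A,B,C,D) by shared state. The 256 ordered nucleotide 4-tuples fall into 15
structural classes: constant (4 tuples), four singleton classes, one per
deviating role (12 tuples each), three symmetric XXYY classes, one per
topology (12 each), six asymmetric XXYZ classes, one per topology and
sharing pair (24 each), and all-distinct (24). Symmetric and asymmetric
patterns of a topology are its split support; their total for topology $x$
is $\tau_x$.

A *polarized* quartet tree is a topology plus a choice of derived split
half. If CD is the derived half of q1, a column in which C and D share a
state not seen elsewhere (the symmetric class or the CD-sharing asymmetric
class) is a putative synapomorphy and counts towards the observed apomorphic
support $S^{obs}$; an AB-sharing asymmetric column is then plesiomorphic
(count $\rho$) — the sharing is on the ancestral side, so it carries no
grouping information for this polarity. By construction
$S^{obs} + \rho = \tau$. Each topology is evaluated under both polarities
(six polarized trees per quartet); no outgroup or prior root knowledge is
needed.

## The convergence correction

Observed apomorphy-like support can be convergent. The expected amount is
estimated by ML: all three topologies are fitted to the quartet's pattern
spectrum under GTR+$\Gamma$+I (each fit is reused as the "competing"
hypothesis for the other two topologies, so exactly three optimizations are
performed per quartet). For a polarized tree $z$ of topology $x$, the
convergence expectation is

$$\kappa_z = \tfrac12 \sum_{y \ne x} \big( \hat\xi_x^{(y)} + \hat\mu_z^{(y)} \big),$$

where $\hat\xi_x^{(y)}$ and $\hat\mu_z^{(y)}$ are the expected counts (fitted
probability times alignment length) of $x$'s symmetric class and of $z$'s
derived-side asymmetric class under the fit of competing topology $y$. The
mean over the two competitors is a deliberate simplification: at most one of
them can be true, so $\kappa$ is a compromise estimate rather than the
actual convergence count.

## The singleton correction $\omega$

Singleton site-patterns (one taxon deviating) are a proxy for terminal
branch lengths. With $\phi$ the smallest and $N$ the total of the four
singleton counts, the asymmetry factor is $\omega = 1 - 4\phi/N$: zero for
perfectly balanced terminal branches, approaching one under extreme
asymmetry. $\omega^{obs}$ comes from the observed tally and is a common
factor for all six polarized trees (it cannot change their ranking by
itself); $\omega^{exp}_x$ is the mean of the factors computed from the
expected singleton counts of the two competing fits, and does differ between
topologies. If $N = 0$ (no singletons at all, essentially only possible in
degenerate alignments) the factor is undefined and the correction is
disabled by setting it to 0.

Two algebraic forms of the final score circulate for this method family,
and they are **not** equivalent:

* `concept_complement` (package default):
  $\theta_z = S^{obs}_z (1 - \omega^{obs}) - \kappa_z (1 - \omega^{exp}_x)$
* `eq8_direct`:
  $\theta_z = S^{obs}_z\, \omega^{obs} - \kappa_z\, \omega^{exp}_x$

The package implements both and exposes the choice everywhere
(`evaluate_quartet(convention=)`, `grid_spec(convention=)`, the CLI and the
report). The default was fixed by an empirical discrimination experiment
built into this package's own simulations: in the Felsenstein zone (internal
branch 0.01, two non-adjacent terminals at 1.5, 250 kbp, $\alpha = 1$,
$I = 0.3$) the complement form recovers the generating topology in the
large majority of replicates while the direct form does not (and ML fails
almost always). Intuitively, under strong asymmetry $\omega \to 1$: the
complement form then *damps* both observed and expected support towards the
balanced-branch expectation, whereas the direct form amplifies exactly the
noisy components. Under balanced branches ($\omega \to 0$) the complement
form reduces to the uncorrected difference $S^{obs} - \kappa$, which is the
sensible limit.

Scores may be negative and are deliberately not floored: the final weights

$$\delta_x = \max(\theta_{x\to}, \theta_{x\leftarrow}), \qquad
  \lambda_x = \frac{\delta_x - \delta_{min}}{\sum_j (\delta_j - \delta_{min})}$$

only use differences. $\lambda$ is a point on the 2-simplex; the minimizing
topology always gets 0. If all three $\delta$ are numerically equal
(e.g. an all-constant alignment) no topology is preferred and the uniform
weights $(\tfrac13,\tfrac13,\tfrac13)$ are returned; grid scoring counts
that as a failure, mirroring the tie rule for ML.

## Likelihood machinery

* GTR generator $Q_{ij} = s_{ij}\pi_j$, normalized to one expected
  substitution per unit time at stationarity over variable sites; base
  frequencies are always the empirical composition of the quartet data, not
  free parameters.
* Among-site rate variation: discrete gamma with equal-probability
  categories represented by their exact conditional means (mean 1), default
  4 categories; plus a free (or fixed) proportion of invariant sites.
  Branch lengths are per *variable* site; rates are not rescaled for the
  invariant fraction. The simulator uses the same convention, so the only
  model misspecification in the built-in experiments is continuous versus
  discretized gamma.
* Pattern probabilities are exact sums over the two internal node states,
  computed for all 256 tuples at once from the spectral decomposition of
  the reversible generator; the likelihood is multinomial on the compressed
  spectrum, so its cost is independent of alignment length.
* Optimization: L-BFGS-B on log branch lengths (bounds $[10^{-8}, 20]$),
  log exchangeabilities (GT fixed at 1), log $\alpha$ (bounds
  $[0.01, 100]$) and $p_{inv} \in [0, 0.99]$; convergence at a relative
  function tolerance of order $10^{-8}$, with up to three jittered restarts
  on non-convergence (flagged, best-found optimum kept). Starting branch
  lengths come from Jukes–Cantor pairwise distances via the four-point
  decomposition, which is what keeps a 12-parameter fit at a few hundred
  milliseconds even for pathological branch-length ratios.
* Probabilities are floored at $10^{-300}$ before logging; an exact
  structural zero (possible only with hard zero branch lengths) under an
  observed pattern yields $-\infty$ with an `impossible` flag.
* The internal fits of the scoring pipeline estimate *all* parameters
  including $p_{inv}$ ("all free"); the ML baseline defaults to fixing
  $\alpha$ and $I$ at their generating values, the most favourable setting
  for ML in the built-in experiments.

## The simulator and what it does (not) emulate

`simulate_quartet()` draws i.i.d. sites under GTR with a continuous gamma
(the generating condition of the study design; discrete optionally) and a
fixed invariant proportion. The built-in designs elongate terminal branches
relative to a short internal branch BL1 $\in \{0.01, 0.02\}$:
two adjacent long branches ("farris"), two non-adjacent ("felsenstein"),
one long ("one_long") and three long ("three_long"), with the elongated
length BL2 stepped up to 1.5, secondary length BL3 and all remaining
terminals at 0.1. Defaults follow the study conditions: the fixed GTR
exchangeabilities and frequencies of `study_gtr_model()`, $I = 0.3$,
250 kbp. For `one_long` the elongated and the BL3 branch are placed on
opposite split halves — the arrangement in which chance similarity could
attract them — as the design prose does not pin the placement down.

The simulator emulates none of the complications of real data: no indels or
missing data (site exclusion is nevertheless implemented and tested on
hand-built alignments), no compositional heterogeneity, no among-branch
model variation, no alignment error. Passing the built-in experiments
therefore demonstrates behaviour under near-ideal model conditions — the
point of the study design, which isolates branch-length asymmetry as the
sole failure source — and does not certify performance on real alignments.

## Problem sizes used in the built-in checks

The package's own test suite runs the experiments at desk scale, chosen to
keep the full suite within a coffee break while leaving the binomial noise
well below the asserted margins: 20 replicates for the Felsenstein/Farris
head-to-head at 250 kbp, 5 replicates per gamma shape
($\alpha \in \{0.1, 0.3, 0.5, 0.7, 1.0, 2.0\}$) for the three-long-branch
sweep, and 10 replicates for smoke-level consistency checks at 20 kbp. The
acceptance script uses 10 replicates per shape (60 in total). The original
study scale (100 replicates per cell, full BL2 grids) is available through
`grid_spec()`/`run_grid()` by raising `replicates` and widening the
parameter lists.

## Known limitations

* Quartets only; no supertree assembly, rogue-taxon analysis or root
  placement, although the per-polarity scores would be the natural input
  for such extensions.
* Nucleotides only; ambiguity codes and gaps are excluded, not modelled.
* $\kappa$'s mean-over-competitors is a known simplification (see above),
  and the singleton-based $\omega$ assumes singleton counts track terminal
  branch lengths approximately linearly, which saturates for very long
  branches.
* The score is meaningful for long alignments (tens of kbp and up); for
  single-gene lengths the stochastic error of the pattern spectrum
  dominates the short-internal-branch signal the method targets.
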