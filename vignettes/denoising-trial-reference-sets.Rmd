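---
title: "Denoising trial-derived adverse-event effects and probing observational methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising trial-derived adverse-event effects and probing observational methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialref)
```

## The problem

Registry result reports for active-comparator trials (one drug compared
directly against another) record, per arm, how many participants experienced
each adverse event. Pooled into 2×2 tables, these are experimentally
randomized estimates of relative adverse-event risk — thousands of them. They
are, however, noisy: most comparisons have few events, and naive sample odds
ratios are wildly dispersed. This vignette describes how `trialref` turns
these tables into a denoised reference set and how the reference set scores
an observational method's output.

## Model

For comparison $i$ with table $Z_i = (X_{A,i}, Y_{A,i}, X_{B,i}, Y_{B,i})$,
conditioning on both margins removes the nuisance baseline rate and leaves
the Fisher noncentral hypergeometric law for the free cell, indexed by the
log odds ratio $\omega_i$:

$$L_i(\omega) = \frac{\binom{n_A}{X_A}\binom{n_B}{X_B} e^{\omega X_A}}
{\sum_t \binom{n_A}{t}\binom{n_B}{m-t} e^{\omega t}},$$

with $n_A = X_A + Y_A$, $n_B = X_B + Y_B$, $m = X_A + X_B$. This is the same
conditioning that underlies Fisher's exact test; it is exact for any cell
counts, including zeros, which matters because many strong adverse-event
effects have a zero cell.

The ensemble is modelled hierarchically: $\omega_i \sim G$ i.i.d., with $G$
**symmetric about 0**. Symmetry is not a convenience — in an active-comparator
design there is no distinguished baseline arm, so the population of effects
must be invariant to relabelling the two drugs. $G$ is estimated by the
Kiefer–Wolfowitz nonparametric maximum likelihood estimator (NPMLE),
maximizing $\sum_i \log \int L_i(\omega)\,dG(\omega)$ over symmetric
distributions on a discrete grid, and each effect is reported as the
posterior mean $\hat\omega_i = E_{\hat G}[\omega_i \mid Z_i]$. Comparisons
with little information are shrunk almost entirely to 0; comparisons with
many events retain large effects. Subsets
$S_t = \{i : \exp(\hat\omega_i) \ge t\}$ (inclusive, hence nested in $t$)
grade the reference set by evidence strength.

## Tunable parameters

* **Grid** (`effect_grid`): atoms at $0, \pm k\Delta$ with step
  $\Delta = 0.05$ on the log-OR scale up to $\log 1000$ (279 atoms). The
  ceiling leaves ample headroom above the largest denoised effects seen in
  practice (odds ratios in the tens); the step is fine enough that grid
  discretization moves posterior means by $< \Delta/2$. Both are user-visible
  arguments.
* **EM convergence** (`fit_symmetric_npmle`): relative objective improvement
  below `tol = 1e-9` or `max_iter = 10000` iterations. Weights below `1e-12`
  are pruned and the rest renormalized afterwards: NPMLE mixing weights are
  sparse and can be non-unique, but the objective and the posterior means —
  the quantities consumed downstream — are stable.
* **Ingest filters** (`ingest_trials`): minimum arm enrolment
  `min_arm_size = 100` (an arm of 99 is dropped); token-overlap acceptance at
  $\ge 0.5$; `apply_quality_filter` toggles the
  randomized-with-participant-blinding requirement for ablation runs.
* **Continuity correction** (0.5 per cell) is used *only* for ordering
  (orientation) and display of sample odds ratios; every likelihood
  computation uses raw counts, since the conditional likelihood is exact and
  needs no correction.
* **Significance** is always the inclusive `p <= alpha`, default 0.05, and
  threshold sweeps default to $t \in \{1.00, 1.05, \dots, 4.00\}$.

## Design choices in the ingest pipeline

Registry exports leave several details open; the package fixes them as
follows.

* The token-overlap denominator is the *arm label's* token set:
  `|label ∩ name| / |label|`, inclusive at 0.5. A two-token label matching a
  one-token lexicon name ("Sitagliptin phosphate" vs "sitagliptin") is
  accepted; a five-token dosing description ("Nicotine patch 21 mg daily")
  is not. This is the conservative reading of "at least half the tokens
  match": verbose labels must carry real lexical evidence.
* The minimum-size filter uses arm *enrolment*, not per-event at-risk
  counts, and runs before any outcome handling; contingency denominators
  then use the event's at-risk count where reported (at-risk subsets are
  common in registry adverse-event tables), falling back to enrolment via
  the adapter schema.
* When two reported terms in one arm map to the same ICD10 code, affected
  counts are summed but the at-risk denominator is the maximum of the
  entries, with the sum capped there (and a warning when the cap binds).
  The entries describe overlapping subsets of a single arm; summing
  denominators would double-count participants. Distinct *dose arms*, by
  contrast, are disjoint, so dose merging sums both numerators and
  denominators.
* Masking vocabulary: the quality filter requires the literal role
  `"participant"` in `masking_roles`. Adapters translating registry masking
  descriptions ("double blind", "quadruple masking") are expected to expand
  them to role lists.
* Unmapped drugs and adverse-event terms are dropped from results but
  tallied in the ingest drop log, so a run is auditable without being
  interrupted.
* Pooling across trials happens before orientation, and orientation is
  applied last; ties (sample OR exactly 1) orient the lexicographically
  smaller ingredient code as drug A, making the pipeline deterministic.

## Numerical choices

All likelihood work is in log space: log-binomial coefficients via
`lchoose`, a log-sum-exp denominator over the exact support, and a
per-table shift by the value at $\omega = 0$ (both the NPMLE objective and
posterior means are invariant to per-table constants; the shift keeps rows
well-scaled and makes the point mass $\delta_0$ score exactly 0, a useful
feasibility baseline).

Two implementation details buy exact symmetry rather than
symmetry-to-rounding:

* The (table, $\omega$) pair is canonicalized inside the likelihood, so a
  table and its column-swapped twin evaluate on the identical floating-point
  path with $\omega$ negated. Swapping drug columns therefore mirrors the
  likelihood curve bit for bit.
* The symmetry constraint on $G$ is imposed structurally: likelihoods are
  folded into half-grid kernels $[L_i(+g) + L_i(-g)]/2$, the standard
  unconstrained-simplex NPMLE is solved there by monotone EM fixed-point
  iterations from uniform weights, and weights are reflected back. Posterior
  means are likewise folded over the half grid. Together these make fitted
  weights exactly symmetric and swapped-table posterior means exact
  negations — a property the test suite asserts with `identical()`.

Degenerate tables (no events, or events in every subject) have single-point
support, a flat likelihood, and posterior mean exactly 0 under any symmetric
prior; all-flat datasets leave the EM at its uniform initialization (uniform
over half-grid foldings), a documented convention rather than an error.

## What the synthetic-data generator emulates

`simulation_spec()` defaults encode the validation conditions used
throughout the package: $M = 5000$ comparisons, effects from the
spike-and-slab prior $0.8\,\delta_0 + 0.1\,\delta_{+\log 4} +
0.1\,\delta_{-\log 4}$ (most drug pairs have identical adverse-event
profiles; a minority differ fourfold in odds), arm sizes uniform on
200–2000, baseline event rates uniform on 0.01–0.3. Tables are drawn as two
independent binomials, under which the conditional law given the margins is
*exactly* the noncentral hypergeometric likelihood being fitted — so
parameter recovery is a faithful end-to-end test of the estimation
machinery, not an approximation study. `simulate_method_results()` emulates
an observational method as an independent two-binomial study with `power_n`
patients per arm and an additive log-OR confounding bias, reporting a Wald
p-value and a sign direction.

What the generator does **not** emulate: real registry label noise beyond
the fixture cases, correlated comparisons sharing a trial arm, between-trial
heterogeneity in the true effect (the pipeline pools by summation, as the
reference-set construction does), outcome underreporting, and the
population mismatch between trials and claims data. Passing tests therefore
demonstrate the statistical machinery is correct under its own model, not
that any particular observational data source is concordant with trials.

A second, fully enumerable fixture set (`generate_fixture_trials()`)
exercises every ingest rule with hand-counted outcomes: 4 pooled comparisons
survive with the quality filter, 6 without it.

## Validation scales

The shipped tests and the reproduction script use desk-scale problem sizes
chosen to exercise every property at comfortable precision: normalization
of the pmf over 200 random tables × 5 effect sizes (deviation below
$10^{-10}$); EM-vs-exhaustive-simplex-search agreement within $10^{-6}$ on 5
tables × 3 half-grid atoms; and parameter recovery at $M = 5000$ on the full
279-atom grid, where the fitted prior places mass $0.20 \pm 0.05$ outside
$|\omega| < \log 2$ and posterior means beat continuity-corrected sample log
odds ratios in mean squared error by roughly a factor of five. A full run of
suite plus script takes about a minute on one CPU.

## Known limitations

* The NPMLE's mixing weights are not unique in general; only
  objective-level and posterior-mean-level quantities should be compared
  across implementations, and printed denoised odds ratios can differ in
  the last digit under a different grid.
* Posterior intervals and local false-sign rates are not provided — the
  reference set consumes point estimates only.
* A single prior is shared by all comparisons; drug classes with
  systematically stronger side effects (e.g. cytotoxics) are shrunk toward
  the global ensemble. Stratified or covariate-modulated priors are a
  natural extension, out of scope here.
* The evaluation is deliberately direction-only (concordant sign rate):
  effect magnitudes are not compared between the reference set and the
  method under evaluation, because estimands (odds ratio vs hazard ratio)
  and populations differ.
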