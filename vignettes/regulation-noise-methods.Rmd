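---
title: "Models and methods: expression noise floors, sorting selection, and the evolution of regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnoise)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, and the design choices made where more than one reasonable
implementation existed. All quantities are on the natural-log scale;
log-fluorescence may optionally be shifted to GFP-molecule units by the
constant `log(2.88)` (about 1.06), off by default.

## The noise floor and excess noise

In a constant-rate model of expression the protein copy number per cell is
negative-binomial, `var(n) = (b + 1) <n>` with burst size `b`. Cell-to-cell
fluctuations in transcription, translation and decay rates add a term
proportional to the squared mean, giving
`var(n) = beta <n> + sigma_ab^2 <n>^2` with a renormalized burst size `beta`
and the relative variance `sigma_ab^2` of the product of the rates across
cells. With a background fluorescence `n_bg`, and assuming fluctuations
small relative to the mean, the variance of log measured fluorescence is
bounded below by

    var(log n_meas) = sigma_ab^2 (1 - n_bg/<n>)^2 + (beta/<n>) (1 - n_bg/<n>).

The curve decays from the burst-dominated regime at low expression to the
extrinsic asymptote `sigma_ab^2` at high expression. A promoter's **excess
noise** is its measured variance of log-fluorescence minus this floor at its
mean. Negative excess (slightly below the fitted floor) is retained by
default — it carries information about fit error — with a `clip` flag where
non-negativity is needed.

**Fitting the floor.** The floor is a lower envelope, so `fit_noise_floor()`
bins promoters by mean log-expression into equal-count bins (default 20),
takes the record at a low quantile of the variance in each bin (default the
5th percentile) *with its own mean* — so data generated exactly on the
floor yield envelope points exactly on the curve — and least-squares fits
the closed form to those points. For fixed `n_bg` the form is linear in
`(sigma_ab^2, beta)`, so the fit is a non-negativity-constrained linear
regression (with two parameters the active-set solution is one of four
candidates); when `n_bg` is co-fitted, a 1-D search over the background
profiles out the linear part. The fit refuses fewer than 20 promoters or
less than ~0.8 decades of dynamic range, since two shape parameters cannot
be constrained from a narrow mean range. On the envelope quantile: with
noise-free per-promoter records the choice barely matters; with records
estimated from finite cell samples the low quantile preferentially selects
downward estimation errors, biasing the fitted floor low by a few tens of
percent at 500 cells/promoter — a known property of envelope estimators
that matters when interpreting small excess values near zero.

**Robust per-promoter statistics.** Flow data contain a small fraction of
gross outliers (debris, doublets). `estimate_log_stats()` models the sample
as a Gaussian signal plus a broad uniform outlier component over the data
range, fits the mixture by EM, discards points whose outlier posterior
exceeds 1/2, and computes plain moments on the rest. On clean Gaussian
samples essentially nothing is discarded (the uniform density is far below
the Gaussian's except in the extreme tails), so the estimator is unbiased
to within sampling error; 1% contamination at 10–15 SD changes the variance
by well under 5%. A trimmed fallback (symmetric tail trim with a Gaussian
consistency correction for the trim-induced shrinkage) is available; it is
cruder under asymmetric contamination because the correction assumes
symmetric trimming of a symmetric distribution.

## FACS selection and sort-and-mutate evolution

The probability that a cell at log-expression `x` survives a sort round is
modelled as a Gaussian gate `exp(-(x - mu*)^2 / (2 tau^2))`; defaults used
throughout the examples are the medium-expression sort values `mu* = 8.1`,
`tau = 0.03`. For a genotype whose expression is Gaussian with mean `mu`
and variance `sigma^2`, integrating the gate gives the closed-form fitness

    f(mu, sigma | mu*, tau) = sqrt(tau^2/(tau^2 + sigma^2))
                              * exp(-(mu - mu*)^2 / (2 (tau^2 + sigma^2))),

which `genotype_fitness()` evaluates and the tests verify against numerical
quadrature. Fitness depends strongly on the mean and only through the
square-root prefactor on the variance: per e-fold, the sensitivity to the
mean at a typical deviation is several times the sensitivity to the noise,
which is why mean-targeted sorting leaves noise essentially unselected —
though the prefactor does make noise *weakly* deleterious at the target,
and the simulator exposes this dependence rather than hiding it.

`evolve_population()` samples cells from genotype distributions in
proportion to abundance, accepts each with the gate probability (default;
a rank mode keeping the nearest `cells_selected` cells is available — the
two coincide in the regime where the Gaussian-gate estimate was made),
founds the next round's lineages from the accepted cells, and mutates.

**Mutation kernel.** Mutagenesis is represented at the phenotype level:
with probability `p_mutate` per lineage per round, the mean receives a
Gaussian perturbation of SD `rate_mu` (default 0.2 log units) and the
log-variance one of SD `rate_sigma` (default 0.05). `p_mutate` defaults to
`1 - exp(-2)`, the chance that a Poisson process with two effective events
per round hits a lineage at all, so most lineages carry between zero and a
few mutations. The asymmetry between `rate_mu` and `rate_sigma` is
deliberate: point mutations in a promoter chiefly retune its mean
expression — mutant libraries span the full expression range while
individual genotypes remain near the noise floor — so per-mutation variance
effects are set several-fold smaller than mean effects. With the rates set
equal instead, the simulation leaves the regime it is meant to represent:
noise becomes as mutable as the mean and the weak prefactor selection
produces a measurable downward drift in excess noise over a few rounds.

**Floor tracking.** A genotype's floor-level variance is burst noise set by
its current expression level, not an independently heritable trait. When
floor parameters are supplied, a mutation that moves the mean carries the
genotype's *excess* over and re-anchors the floor component at the new mean
(`track_floor = TRUE`, the default in that case). Without tracking, a
genotype inherits its absolute variance across mean changes, and floor
differences between the old and new mean are mislabelled as excess noise —
a parameterization artifact that produces a spurious excess trend under
mean-targeted selection. The non-tracking behaviour is kept behind the flag
for studying exactly that effect.

## The regulation-evolution theory

Selection across environments is Gaussian around a desired level `mu_e`
with a width `tau` common to all environments (a simplification the closed
forms require; per-environment widths can be explored through the
constructive numeric path). Log-fitness is the weighted average of
per-environment log fitness. Four dimensionless parameters govern the value
of a new regulatory interaction:

* `Y` — expression mismatch, `Y^2 = var(mu_e) / (sigma^2 + tau^2)`;
* `X` — coupling strength, `X^2 = c^2 sigma_r^2 / (sigma^2 + tau^2)`;
* `R` — correlation between the regulator's mean activities and the
  desired levels;
* `S` — the regulator's signal-to-noise, `S^2 = var(r_e) / sigma_r^2`.

With the basal mean optimized, the gain from coupling is

    d log f = 1/2 [ (X^2 + R^2) Y^2 - (S X - R Y)^2 ] / (1 + X^2)
              - 1/2 log(1 + X^2),

which the tests verify to machine precision against the explicit
environment-averaged difference for randomly constructed ensembles. The
closed-form optima `S* = R Y / X` and `X*^2 = max(0, (1 - R^2) Y^2 - 1)`
are cross-checked by nested numeric maximization that never touches the
closed forms. An unregulated promoter's optimal noise is the bet-hedging
value `max(0, var(mu_e) - tau^2)`; with an optimally coupled regulator the
total variance `sigma^2 + c^2 sigma_r^2` stays basal when
`(1 - R^2) Y^2 <= 1` and otherwise equals `(1 - R^2) var(mu_e) - tau^2`,
the mismatch left untracked by the condition response — the two regimes
meeting continuously at the phase boundary, where `S*` diverges.

Conventions and edge cases: `X` is non-negative, with the sign of a
repressive coupling absorbed into the effective correlation (the gain
depends on `c` only through `X^2` and `S X - R Y`); consequently the
closed-form optima are stated for `R >= 0` — for a negatively correlated
regulator, flip the coupling sign. Degenerate limits (`X -> 0` with
`S -> infinity` jointly at the phase boundary) are handled by evaluating
the constructive log-fitness rather than the reduced form. For composite
regulators, the effective activity is the coupling-weighted mean and the
effective noise follows
`sigma_r^2 = sum_i c_i^2 sigma_i^2 + sum_{i != j} R_ij sigma_i sigma_j`;
the cross term is implemented exactly in this form, with a
`cross_weighted` flag providing the `c_i c_j`-weighted variant (the
variance of the literal linear combination, scaled by `1/c^2`) — the two
differ whenever couplings are unequal, and the unweighted form is the
documented default.

`fitness_landscape()` takes explicit `R` and `S` grids (no window is
hard-coded) and maximizes the gain over `X >= 0` per cell by 1-D
optimization, also emitting the ridge `S*(R)`; `phase_diagram()` tabulates
the optimal total noise over `(Y, R)`.

## Attributing excess noise to regulators

The linear noise-propagation model writes each promoter's excess noise as
the sum of the propagation strengths of the regulators targeting it,
`E_p = intercept + sum_r R_pr V_r + noise`, with a binary incidence matrix
and a Gaussian prior `exp(-lambda V_r^2 / 2)` on the strengths. Design
choices:

* the intercept is included and unpenalized — promoters with no annotated
  inputs get an all-zero row, and their excess is near zero but not
  exactly zero;
* `lambda` is selected by repeated random 80/20 splits (default 50
  repeats), maximizing the average held-out fraction of variance
  explained, then the model is refit on all promoters;
* the residual variance is a plug-in estimate from training residuals at
  the selected `lambda` (using effective degrees of freedom), and
  per-regulator uncertainties come from the curvature of the penalized
  objective — the standard ridge sandwich
  `s^2 A^{-1} X'X A^{-1}` with `A = X'X + lambda I` (intercept
  unpenalized);
* strengths are unconstrained by default (noise propagation is physically
  non-negative; a `nonneg` active-set option is provided);
* `rank_significant()` filters to `V_r > sigma(V_r)` and sorts by
  `V_r / sigma(V_r)`, ties broken by regulator id.

On the standard synthetic network (1000 promoters, 20 regulators, edge
probability 0.1, residual noise at twice the signal SD) the fitted
strengths correlate with the planted ones above 0.9 and the variance
explained tracks the generating signal fraction; permuting the response
drives held-out variance explained to zero or below.

## Association analyses

Running means over excess-noise cutoffs use the sorted unique excess values
by default (a grand-mean anchor below the minimum is prepended), the SE
convention is sample SD over the square root of n, and empty cutoffs are
omitted with a note. Expression plasticity is the mean squared log
fold-change over conditions (nominally 240), on whatever log base the input
uses; missing conditions are excluded with the count reported. Regulatory
inputs per promoter are operon-averaged distinct-TF counts, with duplicate
interaction rows collapsed and unmapped promoters excluded with a note.
Threshold enrichment between two groups uses a one-sided hypergeometric
tail (enrichment of above-threshold promoters in the second group), which
the tests verify against brute-force combinatorial enumeration on small
tables.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure the analyses assume:
log-normal per-genotype expression with variance on the floor plus planted
excess (exponential with mean 0.05 by default, a fixture choice matching
the long-tailed look of native excess distributions); mean log-expression
uniform on [6.5, 9.5], somewhat more than a decade around the medium sort
target 8.1; environment/regulator ensembles hitting target `(R, S)`
exactly by orthogonal construction; Bernoulli incidence networks with
exponential planted strengths; and condition fold-changes whose variance
is linearly coupled to excess. They do **not** emulate instrument effects
(gating, autofluorescence spectra, day effects), sequence-level mutation
(evolution is simulated on phenotypes), correlated TF activity
fluctuations, or the discreteness of real regulon structure — so passing
tests demonstrate correctness of the machinery under the model's own
assumptions, not that real measurement tables would yield the same
parameter values. Every generator is deterministic given its seed and
returns ground truth alongside the data.

## Numerical choices and problem sizes

Closed forms are preferred wherever they exist; numeric optimization
(golden-section via `optimize()`, nested for joint problems) is used only
as an independent cross-check of those forms and for landscape/phase
tabulation, with interval tolerances of 1e-9 to 1e-13 and explicit
comparison against the `X = 0` boundary, which interior search cannot
return. The test and example problem sizes — 600 promoters at 500 cells,
five sort rounds at 2e5 cells, a 20 x 20 optimum grid, 100-draw identity
checks, and a 1000 x 20 regression fixture — were chosen so each check has
clear statistical power while the whole suite runs in seconds.

## Known limitations

* The floor fit on *estimated* (rather than exact) records is biased low
  by the envelope-selection effect discussed above; debiasing would
  require modelling the per-promoter variance sampling distribution.
* The outlier model is a pragmatic mixture, not a full Bayesian treatment;
  it satisfies the stated robustness contract but makes no optimality
  claim.
* The theory evaluates fitness; it does not simulate fixation dynamics of
  regulatory alleles, nor multi-gene co-evolution.
* The incidence matrix is taken as given; the regression attributes
  variance, it does not discover edges, and it assumes independent TF
  fluctuations.
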