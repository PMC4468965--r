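# regnoise

Gene expression is noisy: genetically identical cells in one condition
spread around their mean expression level, and for bacterial promoters
that spread has a hard lower bound — a *noise floor* set by bursty
transcription at low expression and by global rate fluctuations at high
expression. `regnoise` is a toolkit for asking how selection treats the
noise a promoter has *above* that floor, and when propagating a
regulator's fluctuations into a target is not a defect but a rudimentary,
selectable form of gene regulation. It is written for quantitative/systems
biologists working with flow-cytometry promoter measurements, sort-and-
mutate selection experiments, and regulatory-network annotations.

Four pieces of machinery, each independently usable:

* **Noise floor and excess noise.** The minimal variance of
  log-fluorescence as a function of mean expression,

      var(log n) = σ²_ab (1 − n_bg/⟨n⟩)² + (β/⟨n⟩)(1 − n_bg/⟨n⟩),

  fitted as a lower envelope over a promoter population
  (`fit_noise_floor`), with per-promoter excess noise
  `E_p = var(log n) − floor(mean)` (`excess_noise`) and an outlier-robust
  mean/variance estimator for raw per-cell samples (`estimate_log_stats`).

* **FACS selection and sort-and-mutate evolution.** A Gaussian selection
  gate `f(x) = exp(−(x−μ*)²/2τ²)` integrates against a genotype's
  expression distribution to the closed-form fitness
  `f(μ,σ) = √(τ²/(τ²+σ²)) · exp(−(μ−μ*)²/2(τ²+σ²))`
  (`genotype_fitness`), and `evolve_population` simulates rounds of
  sorting and phenotype-level mutagenesis.

* **The regulation-evolution theory.** In a fluctuating environment with
  desired levels μ_e, the log-fitness gain from coupling a promoter to a
  regulator depends on four dimensionless numbers — coupling strength X,
  expression mismatch Y, regulator correlation R and signal-to-noise S:

      d log f = ½ [(X²+R²)Y² − (SX−RY)²]/(1+X²) − ½ log(1+X²),

  with closed-form optima S* = RY/X and X*² = max(0, (1−R²)Y² − 1), the
  bet-hedging optimum max(0, var(μ_e) − τ²) for unregulated noise, and a
  phase boundary (1−R²)Y² = 1 between a basal-noise and an
  environment-driven-noise regime (`dlogf`, `optimal_coupling`,
  `predicted_total_noise`, `fitness_landscape`, `phase_diagram`).

* **Noise-propagation attribution.** A ridge regression of promoter
  excess noise on a binary regulator-target incidence matrix,
  `E_p = Σ_r R_pr V_r + noise`, with cross-validated prior strength,
  curvature-based uncertainties and significance ranking
  (`fit_propagation`, `rank_significant`), plus the descriptive
  association analyses (running means over excess cutoffs, plasticity,
  operon-averaged input counts, hypergeometric enrichment).

A synthetic-data module (`gen_flow_populations`, `gen_network`,
`gen_environment_and_regulator`, `gen_plasticity`) generates every input
with ground truth, so the whole pipeline runs and is tested without any
external data.

## Worked example

Five rounds of simulated sorting toward a medium expression target
(μ* = 8.1, τ = 0.03), starting from a 200-genotype library spanning ±2 log
units with floor-level noise (this is `analysis/02_sort_and_mutate.R`):

```r
library(regnoise)
fp   <- noise_floor_params(0.025, 450, 0)
gate <- selection_gate(8.1, 0.03)
set.seed(20260927)
mu0  <- runif(200, 8.1 - 2, 8.1 + 2)
pop  <- promoter_population(mu0, minimal_variance(exp(mu0), fp))
res  <- evolve_population(pop, rep(list(gate), 5), mutation_kernel(),
                          cells_sampled = 2e5, cells_selected = 2e5,
                          seed = 20260928, floor_params = fp)
print(res$summary, digits = 3)
#>   round mean_mu var_mu mean_abs_dev mean_sigma2 mean_excess selected_fraction
#> 1     0    7.97 1.4590        1.069       0.312    0.00e+00                NA
#> 2     1    7.88 0.3860        0.486       0.238    6.19e-05            0.0187
#> 3     2    8.04 0.1692        0.313       0.186    4.55e-04            0.0447
#> 4     3    8.08 0.1164        0.266       0.173    3.90e-04            0.0553
#> 5     4    8.09 0.1003        0.251       0.170   -9.20e-05            0.0571
#> 6     5    8.11 0.0946        0.244       0.167   -5.69e-04            0.0595
```

The mean distance to the gate centre collapses from 1.07 to 0.24 log units
while mean excess noise stays within ±6×10⁻⁴ of zero with no trend —
sorting on the mean leaves noise at its default, floor-level value. The
realized selected fractions match the abundance-weighted closed-form
fitness within binomial error.

On the theory side, for a promoter with expression mismatch Y = 4,
coupling to an *uncorrelated but noisy* regulator (R = 0, S = 0.5) yields
a log-fitness gain of 6.00, beating a moderately correlated one
(R = 0.64, S = 4; gain 4.80) whose signal-to-noise is far above its
ridge-optimal value S* = 0.88 — noise propagation doing the work of
regulation (`analysis/03_regulation_theory.R`).

The numbered scripts under `analysis/` run the full workflow — library
simulation and floor fitting, sort-and-mutate evolution, theory
landscapes, propagation regression, association curves — and write tidy
TSVs under `results/`.

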