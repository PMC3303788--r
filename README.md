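# promcm

Markov-chain models of gene induction by competing transcription factors.

## The problem

A doxycycline (dox)-controlled synthetic transcription unit can be driven
by an activator alone (A), a repressor alone (R), or both at once (A+R),
with the two factors binding the same regulatory site in a mutually
exclusive way.  Measured dose-response curves of the single-factor lines
are shallow sigmoids (Hill coefficients around 1.6 and 1.8), yet the
combined line responds much more steeply and its single-cell expression
is all-or-none rather than graded.  Kinetic simulation of such a system
normally needs a dozen rate constants nobody has measured.  `promcm`
implements the alternative: a discrete-time Markov-chain model (MCM) of
the promoter state whose switching probabilities are Hill functions of
the inducer concentration, estimated *only* from the single-factor
dose-response curves, and a stochastic telegraph + birth–death solver
that turns the promoter-state chain into single-cell and population
expression levels.

The package is for quantitative biologists who want to fit and simulate
promoter-state chains from ordinary population dose-response data: no
single-molecule rates, no mass-action network.

## The model

**Promoter chain.**  The 3-state chain has states
{repressor-bound, unbound, activator-bound} with per-cycle switching
probabilities P<sub>A1</sub> (unbound → activator-bound),
P<sub>A2</sub> (back), P<sub>R1</sub>, P<sub>R2</sub> (repressor side),
and no direct jump between the two bound states.  Binding contingency —
the two factors cannot occupy the site simultaneously — imposes
P<sub>A1</sub> + P<sub>R1</sub> &lt; 1.  Single-factor lines are 2-state
telegraph chains (p<sub>1</sub>: OFF → ON, p<sub>2</sub>: ON → OFF) with
stationary law P<sub>ON</sub> = p<sub>1</sub>/(p<sub>1</sub>+p<sub>2</sub>).

**Dose dependence.**  Every switching probability is a two-parameter
Hill function of dox, p(d) = d<sup>H</sup>/(K<sup>H</sup> + d<sup>H</sup>).
The four (two) Hill functions are estimated by minimizing the squared
deviation of the factor binding equilibria
P<sub>Act</sub> = P<sub>A1</sub>/(P<sub>A1</sub>+P<sub>A2</sub>) and
P<sub>Rep</sub> = P<sub>R1</sub>/(P<sub>R1</sub>+P<sub>R2</sub>) from the
observed activator-only and repressor-only occupancy curves
(reference Hill coefficients 1.6 and 1.8), plus a penalty of 10,000
whenever the binding contingency fails anywhere on the dose grid.  The
search is a seeded differential evolution over
K ∈ [10⁻³, 10²], H ∈ [0.1, 10] per Hill function.

**Expression.**  Each cell updates its promoter state once per cycle
(by default with the two-jump composite move through the unbound state)
and then its mRNA level by
X′ = max(0, X + (α·f + BL − γ·δ·X)·Δt), with transcription rate α = 2,
degradation γ = 0.2, Δt = 1, promoter activity f ∈ {0, 1, 10} for the
repressor-bound/unbound/activator-bound states, degradation noise
δ ~ N(1, 0.5²), and basal leakage BL = γ·10<sup>z</sup>, z ~ N(0, 0.5²).
Populations are 10,000 cells recorded at cycle 200.

**Headline prediction.**  Simulated population means over a 34-dose grid
are min–max normalized and refit with a Hill curve; the emergent
combined-system Hill coefficient exceeds both single-factor coefficients
because activation requires repressor release *and* activator capture —
the occupancy of the activator-bound state behaves as
u<sup>1.6</sup>/(1 + u<sup>1.6</sup> + u<sup>−1.8</sup>) with u = d/K,
whose low-dose slope is 1.6 + 1.8.

## Worked example

```r
library(promcm)

## estimate the four switching-probability Hill functions of the
## competing activator+repressor chain from the reference curves
fit <- mcm(chain = "three_state", seed = 1, budget = 20000)
summary(fit)
#> Markov-chain gene-induction model (three_state chain)
#>           K      H
#> A1  15.8061 8.8907
#> A2  32.4035 7.2908
#> R1 100.0000 2.8515
#> R2  13.8060 4.6519
#> objective = 2.65604e-06; max |occupancy residual|: P_Act 0.0002, P_Rep 0.0014
#> contingency satisfied; seed 1; 20047 evaluations

## simulate a dose-response table and refit a Hill curve
cfg <- sim_config(n_cells = 2000)
tab <- run_dose_response("three_state", fit, dose_grid(17), cfg, seed = 100)
predict_hill(tab)
#> Hill fit (n = 17): K = 0.780858 (SE 0.0078), H = 2.23571 (SE 0.044)
#>   residual sum of squares: 0.00121186

## all-or-none single-cell heterogeneity at an inducing dose
pop <- simulate_population("three_state", fit, 2.5, cfg, seed = 7)
pop
#> Population sample (three_state chain) at dox = 2.5: n = 2000, mean = 93.94, sd = 31.76
mode_count(pop$values)
#> [1] 3
```

The fitted binding curves reproduce the observed single-factor
occupancies to within ~10⁻³ (the raw K/H values are reported up to the
scale non-identifiability discussed in the vignette; the fitted curves,
not the raw parameters, are the meaningful output).  The refit Hill
coefficient of the combined chain (≈ 2.2–2.3 at full scale) is steeper
than either single factor alone; the population at 2.5 µg/ml splits into
distinct low/basal/high expression modes — the all-or-none phenotype —
while single-factor chains respond gradually.

A thin command-line wrapper over the same functions is installed at
`inst/cli/promcm.R` with subcommands `estimate`, `simulate`,
`dose-response`, `predict` and `report`, driven by a YAML run
configuration (`run_config()` / `write_run_config()`).

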