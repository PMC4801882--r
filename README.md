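# bcelldyn

Compartmental dynamics of B-cell development in the mouse bone marrow and
spleen, under continuous BrdU labeling.

`bcelldyn` is for quantitative immunologists who want to turn BrdU
labeled-fraction time courses into rate estimates for B lymphopoiesis, and
to ask whether bone-marrow B-cell production is under homeostatic feedback
from the peripheral mature pool. It implements:

* a five-compartment ODE model — pro-/pre-B (`B_oe`), immature (`B_i`),
  bone-marrow mature recirculating (`B_Mrec`), splenic transitional
  (`B_t`) and splenic mature (`B_Mspl`) cells — in which the pro-/pre-B
  division rate is throttled logistically by joint niche occupancy:

  `dB_oe/dt = S + γ·B_oe·(1 − (B_oe + B_Mrec)/K) − δ_oe·B_oe + δ_r·B_i`

  with first-order differentiation, death, and marrow↔spleen exchange
  flows downstream (all rates per 6-h unit);
* the ten-compartment labeled/unlabeled extension for continuous BrdU
  labeling (an unlabeled cell that divides yields two labeled daughters;
  the source is never labeled; death rates are label-blind);
* the study protocols: control (steady state → 7 days labeling) and
  depleted (steady state → anti-CD20 depletion → 34 days recovery →
  labeling);
* inference in the original study's style: Latin-hypercube candidate
  sampling, a steady-state totals filter, Gaussian maximum likelihood on
  per-mouse labeled fractions, and profile-likelihood 95% confidence
  intervals (cutoff `G² ≤ 3.84`, the χ²(1) 95th percentile);
* global sensitivity analysis of subset totals (stepwise linear
  regression and partial rank correlation coefficients);
* a synthetic-cohort generator reproducing the study design (2 groups ×
  days 2/4/7 × 8 mice × 4 subsets, Gaussian noise sd 0.03).

The right-hand sides are compiled C used through `deSolve`, so a full
steady-state-plus-labeling simulation runs in about a millisecond and
10,000-candidate fits take seconds.

## Worked example

```r
library(bcelldyn)

# Published control best-fit rates, completed by calibrating the source S
# and capacity K so the steady state anchors the splenic mature pool at
# 2e7 cells with logistic occupancy 0.5:
p <- default_params("control")
p
#> <kinetic_params> (rates per 6 h, S in cells/6 h, K in cells)
#>          S      gamma          K   delta_oe    delta_r       mu_i  delta_i_t
#>  2.106e+05  3.000e-01  2.604e+06  5.000e-01  0.000e+00  1.000e-01  6.000e-01
#> delta_i_re      mu_re     phi_BM       mu_t    delta_t      phi_s    eps_spl
#>  1.900e-01  8.000e-03  9.400e-01  3.000e-02  3.000e-02  3.000e-02  8.000e-03

# Simulate 7 days of continuous BrdU labeling from steady state and read
# the labeled fractions at the harvest days:
traj <- simulate_experiment(p, experiment_design("control"))
labeled_fraction_table(traj)
#>    day               subset labeled_fraction
#> 1    2             immature      0.453107641
#> 2    2 mature_recirculating      0.048149105
#> 3    2         transitional      0.125045207
#> 4    2       splenic_mature      0.008038057
#> 5    4             immature      0.461487223
#> 6    4 mature_recirculating      0.065705283
#> 7    4         transitional      0.252778348
#> 8    4       splenic_mature      0.025901969
#> 9    7             immature      0.461538467
#> 10   7 mature_recirculating      0.093943730
#> 11   7         transitional      0.359921472
#> 12   7       splenic_mature      0.057475249
```

The immature pool saturates within two days at ~46% — the fraction of
pro-/pre-B output that is labeled, capped below 1 by the unlabeled source
— while the mature compartments label slowly because they exchange mostly
with each other and turn over through external input at under 1% per 6 h.

```r
# Fit a synthetic cohort (8 mice/day/group, Gaussian sd 0.03) by filtered
# Latin-hypercube maximum likelihood:
data <- generate_cohort(cohort_spec(seed = 42))
fit <- fit_mle(data, default_ranges("control"), N = 500, seed = 7,
               design = experiment_design("control"),
               total_ranges = generate_totals_ranges(p, 0.5))
fit
#> <bcell_fit> control group: lnL = 189.428 (12/500 candidates passed, seed 7)
#>          S      gamma          K   delta_oe    delta_r       mu_i  delta_i_t
#>   2.11e+05   3.61e-01   2.60e+06   5.83e-01   5.54e-02   2.62e-01   7.01e-01
#> delta_i_re      mu_re     phi_BM       mu_t    delta_t      phi_s    eps_spl
#>   2.47e-01   5.41e-02   3.59e-01   2.11e-02   4.60e-02   1.60e-02   7.69e-03

# 95% profile-likelihood interval for the immature death rate:
ci <- profile_likelihood_ci(fit, "mu_i", data, grid_size = 11,
                            n_draws = 100, rounds = 2)
c(ci$lower, ci$upper)
```

`residence_time(default_params("depleted"), "immature")` gives 1.13
six-hour units — depleted and control immature cells dwell equally long,
because in depleted mice increased death substitutes for decreased
differentiation, one of the study's central results.

A thin command-line wrapper is installed under `inst/cli/bcelldyn.R`:

```sh
Rscript inst/cli/bcelldyn.R synth --config cohort.yaml --seed 1 --out-dir out/
Rscript inst/cli/bcelldyn.R fit   --config fit.yaml   --seed 2 --out-dir out/
```

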