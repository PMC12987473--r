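---
title: "From quality tables to a recommended cultivation configuration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From quality tables to a recommended cultivation configuration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melonopt)
```

## The problem

A two-factor field trial varies plant spacing (55, 65, 75 cm) and
pruning-fruit retention (single vine one fruit, double vine two fruits,
three vines three fruits, three vines two fruits) in netted melon
(*Cucumis melo* var. *reticulatus*) grown in an arid region. Each of the
ten treatments yields phenology stage dates, a yield, and nine fruit
quality indicators. Three production goals compete: early maturity
(short total growth period), high yield, and high comprehensive fruit
quality. `melonopt` implements the full decision chain that turns those
tables into a single recommended configuration:

1. **Phenology arithmetic** — stage durations from calendar dates;
2. **Entropy-weight TOPSIS** — a comprehensive quality score $C_i$ per
   treatment from the nine indicators;
3. **Neural surrogate** — a small feed-forward network mapping
   (spacing, pruning) to (duration, yield, $C_i$);
4. **NSGA-II** — the Pareto front of the three objectives over the
   feasible design grid;
5. **Weighted-sum selection** — one configuration from the front.

A synthetic-trial generator with planted optima closes the loop: it lets
the whole chain be tested for whether it recovers a known truth.

## Phenology durations

Durations are inclusive day counts: both endpoints are counted, so
`stage_duration(d, d)` is 1 day. This is the unique convention that
reproduces every printed duration in the bundled growth-period table
(20/20 integers) from its stage dates, and it satisfies the additivity
law `dur(a,b) + dur(b,c) = dur(a,c) + 1`.

```{r}
dur <- compute_phenology_durations(builtin_fixture("phenology_table3"))
head(dur, 3)
```

## Entropy-weight TOPSIS

With $a$ treatments and $b$ indicators (here $10 \times 9$), the
positive matrix $X = (X_{ij})$ is column-normalized by its root sum of
squares, $Y_{ij} = X_{ij} / \sqrt{\sum_i X_{ij}^2}$. Column proportions
$P_{ij} = Y_{ij} / \sum_i Y_{ij}$ give the information entropy
$H_j = -\frac{1}{\ln a} \sum_i P_{ij} \ln P_{ij}$ and the entropy
weights $\omega_j = (1 - H_j) / (b - \sum_j H_j)$: indicators that
discriminate more between treatments (lower entropy) weigh more, with
no subjective weighting. The weighted matrix $Z_{ij} = \omega_j Y_{ij}$
defines the positive/negative ideal solutions (columnwise max/min — all
nine indicators are treated as benefit-type, since the source tables
designate no cost-type indicator), Euclidean separations $D_i^\pm$, and
the closeness
$C_i = D_i^- / (D_i^+ + D_i^-) \in [0, 1]$, ranked descending.

```{r}
res <- run_topsis(builtin_fixture("quality_table4"))
round(res$weights$weights, 3)
as.data.frame(res)[order(res$ranks), ][1:3, ]
```

Two numerical conventions deserve note:

* **Separation scale.** $C_i$ is invariant to any common rescaling of
  $Z$, but the printed separations $D_i^\pm$ are not. The denominator of
  the normalization can be read as the column's root *sum* of squares
  (unit-norm columns) or its root *mean* square (RMS); the two differ by
  the constant $\sqrt{a}$, which cancels in $C_i$. The published
  separations for these tables follow the RMS scale, so
  `run_topsis(..., separation_scale = "rms")` (the default) reports
  $D_i^\pm$ on it; `"unit"` gives raw unit-norm-space distances. A small
  residual (≲2%) against the published $D_i^-$ values remains and is
  consistent with the published values having been computed from
  replicate-level data that the main-text tables do not carry.
* **Degenerate guards.** $0 \ln 0 := 0$ in the entropy (unreachable
  under the positivity precondition, guarded anyway); an all-constant
  table has undefined weights and errors; tied closeness values are
  ranked by input order and flagged.

The goodness of fit `goodness_of_fit()` is the product-moment
correlation computed from its definition; it is cross-checked against
`stats::cor` in the tests.

## The neural surrogate

The surrogate is a 2–12–8–3 feed-forward network: inputs are the design
coordinates, outputs the three objectives. Fixed choices, with their
reasons:

* **Encoding.** Spacing is min–max scaled from [30, 80] cm to [−1, 1];
  the pruning method enters as its ordinal code 1–4 scaled the same way
  (a one-hot encoding is available behind `encoding = "onehot"` but is
  not the default, because the four methods are deliberately ordered by
  vine/fruit load). Outputs are min–max scaled to [−1, 1]; MSE is
  reported on that scale, and `descale(scale(y)) = y` holds to 1e−12.
* **Activations.** tanh on both hidden layers, identity output — the
  conventional pairing for small Levenberg–Marquardt-trained regression
  networks.
* **Trainer.** Full-batch Levenberg–Marquardt: the residual Jacobian is
  computed by batch backpropagation (verified against finite
  differences), and the damped normal equations
  $(J^\top J + \lambda I)\,\delta = -J^\top r$ are solved each epoch,
  with $\lambda$ divided by 10 after an accepted step and multiplied by
  10 after a rejected one. The configured learning rate (0.05) is the
  initial damping; `max_epochs` 2000 and `mse_target` 1e−8 are stopping
  rules, alongside a relative-improvement floor. A plain
  gradient-descent trainer sits behind the same interface
  (`method = "gd"`). On a linear problem the trainer reaches the
  closed-form least-squares optimum to 1e−10 (tested against both
  `lm.fit` and `minpack.lm::nls.lm`).
* **Restarts and splits.** Training restarts from `restarts` (default
  10) seeded initializations and keeps the restart with the lowest
  validation MSE. The random split default is 70/15/15; with only 10
  treatments that is 8/1/1, so a leave-one-out mode (`"loo"`, rotating
  the held-out sample across restarts) and a `"none"` mode (fit all
  rows; appropriate when the design covers the whole grid and the net is
  used as an interpolator) are provided. The published source does not
  state its split, so figure-level fit statistics are treated as
  qualitative.
* **Determinism.** (data, config, seed) fully determine the weights;
  the RNG state of the caller is left untouched.

With 167 parameters against at most 132 residuals the network is an
interpolator by design — exactly how the original analysis used it. The
cost is extrapolation: fitted on designs spanning 55–75 cm, predictions
at 30–50 or 80 cm are unconstrained by data (the published-table run in
`analysis/04_optimize_select.R` predicts $C_i$ at its clamp of 1 beyond
75 cm). Predicted $C_i$ is therefore clamped to [0, 1] with a flag, and
conclusions from the bundled-data run should be read as method
demonstration, not as new agronomy.

## NSGA-II over the design grid

The feasible space is discrete and small: spacing an integer multiple of
5 in [30, 80] cm (11 levels) × 4 pruning codes = 44 designs. The
optimizer minimizes (duration, −yield, −$C_i$) with standard elitist
NSGA-II: fast non-dominated sorting, crowding distance with infinite
distance at objective extremes, binary tournament on (rank, crowding),
uniform per-gene crossover (p = 0.8), per-gene random-reset mutation
(p = 0.1), and (μ+λ) truncation with population 100 for 100 generations.
Choices specific to this package:

* **Feasibility by construction.** Genomes are (spacing index, pruning
  code) pairs; every decodable genome is feasible, so no penalty
  handling exists.
* **Grid-seeded initialization.** With population ≥ 44 the initial
  population contains one copy of every feasible design plus random
  fill. Elitist truncation never discards a first-front member when the
  front fits in the population, so the returned front provably equals
  the exhaustive non-dominated set — the genetic machinery is kept (and
  is exercised with smaller populations), but the reported front does
  not depend on search luck.
* **Oracle.** `brute_force_pareto()` evaluates all 44 designs and takes
  the exact non-dominated set by pairwise comparison; the tests require
  the evolved front to equal it, and the sorting/crowding components to
  match independent brute-force implementations on random populations.
* **Duplicates** are allowed during evolution (44 genomes, population
  100 — forbidding them would be a different algorithm); the reported
  front is genotypically deduplicated.

## Selecting one configuration

The front is collapsed by a weighted sum with equal weights (1, 1, 1).
Raw units would make this meaningless — yield (tens of t/hm²) would
drown $C_i$ (≤1) — so each objective is first min–max normalized over
the front to [0, 1], oriented so 1 is best (duration inverted; an
objective with zero range maps to 1). Equal weights then weigh the three
goals equally *relative to the spread the front offers*. Raw-unit
scoring remains available (`normalize = FALSE`) for sensitivity
analysis. Score ties break toward shorter duration, then higher yield,
then higher $C_i$ — the stated priority of early maturity, high yield,
and quality. The chosen design is always a member of the front.

## The synthetic-trial generator

`trial_scenario()` fixes response surfaces and a noise model:

* duration `d0 + dv·(vines−1) + df·(fruits−1) + ds·(spacing−55)`
  (defaults 101, 8, 1, −0.1 — calibrated to the published growth-period
  table: single-vine control 101 days, double-vine ≈ 109–110, triple
  vine ≈ 117–119, spacing nearly irrelevant);
* yield `y0 + ys·(s−55) + ys2·(s−55)² + ycode[code]` (defaults 51,
  −0.4, 0, (−22, 0, −1, +3)) — strictly decreasing in spacing, the
  three-vine two-fruit method on top, and anchored near the two
  published yields (53.97 t/hm² at 55 cm/3V2F, 27.86 for the single-vine
  control);
* quality $C_i$: a logistic rise in spacing saturating near the widest
  spacings, with pruning offsets ordered 3V2F > 2V2F > 3V3F, clamped to
  [0, 1], plus an optional quadratic hill term;
* nine indicator surfaces increasing in spacing with the same pruning
  order, based near the control treatment's values.

Replicate noise is independent Gaussian per response with sd equal to
`noise_frac` × (surface range over the full grid); the generated
treatment means carry the sd/√replicates of an averaged trial
(replicates default 3, matching a three-block field design). `design =
"published"` reproduces the published 10-treatment layout (the single-vine
control appears only at the smallest spacing); `"factorial"` crosses
all levels. Synthetic phenology dates are placed at fixed fractions of
each treatment's duration so that date arithmetic and validation run on
generated data too.

What the generator does *not* emulate: block effects, spatial
correlation, treatment × replicate interaction, non-Gaussian error, or
any mechanistic growth process. Passing recovery tests therefore show
that the estimation chain is consistent under its own assumptions — not
that those assumptions hold in a real field.

### The planted-optimum recovery scenario

`recovery_scenario()` is the factorial scenario used by the end-to-end
recovery study. Its quality surface peaks at 70 cm (quadratic hill on
the logistic rise) while yield keeps falling and duration mildly rises
with spacing, making (70 cm, double-vine two-fruit) a pronounced knee:
every other front member trails its equal-weight score by ≥ 0.23 (on
the 0–3 score scale). That margin was sized from the noiseless surfaces
by propagating the 5% replicate-noise sd through the normalized scores
— under the default published-layout surfaces the optimum is a near-tie
(margin ≈ 0.03) that no estimator could recover reliably from noisy
data, which would test the scenario, not the chain. The hill makes this
scenario's quality surface deliberately non-monotone in spacing; the
directional invariants (yield strictly decreasing in spacing, duration
non-decreasing in vine count) still hold. At 5% noise the chain
recovers the planted optimum in ≥ 90% of 50 seeded runs — the
acceptance test asserts exactly that, and
`analysis/05_recovery_simulation.R` reports the realized rate on the
same seeds.

## Study sizes and runtimes

The test suite and analysis scripts use sizes chosen to keep a full run
on one CPU comfortable while preserving the contract being tested:
recovery study 50 seeds × (surrogate with 2 restarts, `split_mode =
"none"`; NSGA-II at its defaults, population 100 × 100 generations)
≈ 3 minutes; TOPSIS/phenology analyses are instantaneous; oracle
equivalence uses 100 random matrices / populations. The analysis
scripts under `analysis/` write their tables beneath `results/`.

## Known limitations

* The bundled main-text tables carry treatment means only; eight of ten
  yields exist only in supplementary files not shipped here, so
  pipeline runs on the bundled data complete them from the synthetic
  scenario surface and say so in the run manifest.
* The ~2% residual on the published separation scale (above) cannot be
  resolved without replicate-level data.
* Cost-type indicators are not supported in TOPSIS (no indicator in
  scope needed them); the extension point is the ideal-solution stage.
* The surrogate is an interpolator; its extrapolation beyond the
  trialed spacings is a property of the method, not information.
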