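---
title: "Federated statistics with local differential privacy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated statistics with local differential privacy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedstats)
```

## The problem

Multi-center clinical research often cannot move patient-level data out of
the hospitals that hold it. Federated analytics answers statistical queries
by sending the *query* to the data: each hospital node computes an aggregate
on its local table, and a coordinator pools the per-node aggregates. Two
protection layers sit on top of that architecture in this package:

* **disclosure control** — a node refuses to release any aggregate computed
  on too few patients (minimum cell counts), and
* **local differential privacy (DP)** — a node perturbs its aggregate with
  calibrated Laplace noise *before* it leaves the node, so that even the
  coordinator cannot confidently infer any individual's contribution.

The concrete study the package ships end to end compares the management of
metastatic non–small cell lung cancer patients enrolled before versus after
the first COVID-19 wave across three hospitals: first-line treatment
duration (linear regression) and disease progression within 24 months
(stratified Cox model), with bivariate screening of confounders at p < .20.

## The privacy model

A release is ε-differentially private when adding or removing any one
patient changes the probability of any output by at most a factor
$e^\varepsilon$. The package implements *pure* ε-DP with the standard
Laplace mechanism: a query with sensitivity $\Delta$ (the largest change one
record can cause, given public clamp bounds $[L, U]$) is released as

$$\tilde{q} = q + \mathrm{Laplace}\!\left(b = \Delta / \varepsilon\right),$$

with noise variance $2b^2$. One study described ε loosely as an inverse
noise variance; the calibration here is the standard one used by every
mainstream DP library, under which $\varepsilon$ is the log-likelihood-ratio
bound, not a variance. Composition is additive: a sequence of releases
costs the sum of their budgets, tracked per node in an append-only ledger.
Post-processing (rounding noisy counts to non-negative integers,
re-clamping extrema into $[L,U]$) is free and never appears in the ledger.

Per-statistic constructions:

| statistic | construction | sensitivity | budget split |
|---|---|---|---|
| count | Laplace on $n$ | 1 | ε |
| sum | Laplace on $\sum x$ | $\max(|L|,|U|)$ | ε |
| mean | noisy sum / noisy count | as above / 1 | ε/2 + ε/2 |
| variance, SD | noisy (count, sum, sum of squares) | 1, $\max(|L|,|U|)$, $\max(L^2,U^2)$ | ε/3 each |
| min, max | Laplace on clamped extremum | $U - L$ | ε |
| quantile | exponential mechanism (below) | — | ε |
| histogram | Laplace per bin | 1 per bin | ε total (parallel composition) |

The equal splits inside compound statistics are a design choice (nothing in
the study fixes them); every sub-release is logged separately so an auditor
can see how a total was spent.

**Quantiles.** Adding Laplace noise at sensitivity $U-L$ to an order
statistic would destroy a median, so quantiles use the exponential
mechanism over the clamped domain: the interval between consecutive sorted
values $z_i \le x < z_{i+1}$ has utility $u = -\,\bigl|\,i - qn\,\bigr|$ and
is sampled with probability proportional to its length times
$\exp(\varepsilon u / 2)$, then a point is drawn uniformly inside it. The
release is always within the clamp bounds. Extrema keep the simple Laplace
form: once noised they are considered releasable, whereas the plain
pipeline withholds them entirely as disclosive.

**Local versus central DP.** With local DP each of $k$ nodes adds an
independent draw, so a pooled sum carries $k$ times the noise variance of
central DP, where one draw is added after exact pooling — the package
implements both so the trade-off is measurable (the `local`/`central`
switch of `run_query()`). Central DP requires trusting the coordinator with
exact node aggregates; rank statistics are only available under local DP
here because the coordinator never holds raw values.

**Randomness.** All noise flows through a `dp_stream(seed)` object. The
i-th draw uses the substream seed $(\text{root}\cdot 48271 + i \cdot 9973)
\bmod (2^{31}-1)$, restoring the session RNG state afterwards, so a whole
federated run is byte-reproducible from one root seed and package code
never perturbs user RNG state. `noise_free = TRUE` is a test-only
degeneration switch (the ε→∞ limit): every mechanism returns its exact
counterpart while still charging the ledger, which is how the suite proves
the DP pipeline collapses onto the plain one cell for cell.

## Disclosure control

The default policy masks any release computed on fewer than 3 patients and
any count table containing a *nonzero* cell below 3. Structural zeros are
released: revealing that a category is absent does not single out an
individual, and the published study tables themselves contain a zero cell —
under a rule that masked zeros, no such table could ever have been
released. Masked nodes are dropped from pooling with a flag in the result
metadata; an opt-in `strict` mode fails the query instead. Lowering the
threshold can only unmask (masking is monotone).

## The cohort model

Each node ingests a flat CSV with one row per patient: center, inclusion
date, gender, age class, BMI class, treatment category, blood creatinine,
first-line duration, and day offsets for second-line start, death and
transfer. Two closed calendar windows define the periods (2019-03-01 to
2020-03-01; 2020-03-02 to 2021-03-31); a date in neither raises an error
rather than guessing. Progression within 24 months is proxied by the
earlier of second-line start and death; a patient whose proxy falls after
the earlier of day 730 and a transfer to another center is censored there,
with the reason recorded. Transferred patients stay in the progression
analysis (censored at transfer) but leave the duration analysis, whose
endpoint is not fully observed at the enrolling center.

Clamp bounds are public study parameters, not data-derived: creatinemia
defaults to [20, 300] µmol/L and duration to [0, 1500] days, both
user-overridable in the YAML study configuration, since plausible
physiological and protocol ranges — not observed extremes — must bound DP
sensitivities. Missing quantitative values are kept missing and analyses
are complete-case per variable.

## Synthetic cohorts and the study fixture

`generate_cohort()` draws fully random cohorts under the study conditions:
3 centers × 25 patients per period, categorical probabilities equal to the
published pooled proportions, normal creatinemia and log-normal durations
per period, Weibull progression clocks calibrated so roughly 84% (before)
and 74% (after) progress within 730 days, and ~3% transfer censoring. It
is the tool for power/size experiments; it does *not* emulate within-center
effects, covariate correlations (treatment is drawn independently of
survival), secular drift inside a period, or measurement error — so tests
passing on it say nothing about those features of real data.

`build_fixture()` is different: a deterministic construction that
reproduces the published pooled per-period tables *exactly* (sample sizes
75/74, every categorical margin, progression 12/63 and 19/55, transfers 3
and 2) so the plain pipeline's outputs are checkable against printed
values. Design choices:

* Per-center splits were never published, so pooled counts are apportioned
  across centers by a small exact search constrained to cells of 0 or ≥ 3,
  keeping every node's local table releasable under the default disclosure
  policy; labels are then shuffled independently within center under the
  seed. Only pooled margins are meaningful.
* Quantitative columns are deterministic quantile grids (log-normal for
  duration, normal for creatinemia) affinely adjusted to the printed mean
  and SD, then projected into the clamp bounds with the mean restored
  exactly (the SD is approximate; the printed combined-period duration SD
  is not derivable from per-period summaries and is not targeted).
* One creatinemia value in the after period is missing, as published;
  transfers get times strictly inside the window; every fifth progression
  proxy is a death rather than a second line.

## Inference

Categorical variables are tested on the pooled variable-by-period table:
chi-square when every observed cell holds at least 5 records, Fisher's
exact test otherwise (probability-mass two-sided criterion; other two-sided
conventions exist, so the choice is stated). The Yates continuity
correction is applied on 2×2 tables by default because it reproduces the
published p-values where the uncorrected statistic does not; `correct =
FALSE` switches it off. For r×2 tables no correction exists and the plain
Pearson statistic is used — two published r×2 p-values differ from this
computation by one unit in the second decimal, and the originating
computation is unknowable from the publication.

Quantitative variables use the pooled-variance two-sample t test computed
from sufficient statistics only (n, mean, SD per group), which is exactly
what a coordinator can see. Its DP version releases, per node and group, a
noisy count, sum and sum of squares at ε/6 each (per-node charge exactly
ε), pools them, rounds pooled counts to integers floored at 2, and applies
the same summary t test. Screening selects covariates with p strictly
below .20 for the multivariate models.

A known limitation, measured rather than hidden: at the study budget
(ε = 60) the DP t test holds its nominal 5% size on unit-scale clamped data
(empirical size ≈ 0.04–0.05), but with wide clinical clamp bounds such as
creatinemia's [20, 300] the sum-of-squares sensitivity $\max(L^2,U^2)$
makes the noisy variance estimate so dispersed that the empirical size
inflates to ≈ 0.13. A variance-aware correction (subtracting the known
injected noise variance) or an uneven budget split would mitigate this;
both are deliberately out of scope because the construction mirrors the
plain summary t test applied to noisy aggregates.

## Federated models

**Linear regression.** Each node sends $X^{\top}X$, $X^{\top}y$,
$y^{\top}y$ and its complete-case count on a shared reference-level dummy
design (factor levels are fixed by the schema, so columns align across
nodes); the coordinator solves the normal equations after rescaling to unit
diagonal for conditioning. The fit is numerically identical to centralized
least squares on the concatenated data — verified to 10⁻⁸ on randomized
federations — with t-based 95% CIs on $N - p$ degrees of freedom.

**Cox model.** Risk sets never cross centers: the model is stratified by
node, each stratum contributing the gradient and Hessian of its own Breslow
log partial likelihood per Newton–Raphson iteration (the only payloads are
a length-p vector and a p×p matrix). The coordinator iterates with step
halving from β = 0 until the gradient norm falls below 10⁻⁸ (at most 50
iterations), then reports hazard ratios with $\exp(\beta \pm 1.96\,se)$.
Stratification is a design choice: pooling risk sets across nodes would
require exchanging event-time order, which leaks order statistics. Breslow
tie handling is the simplest choice consistent with a federated
cumulative-sum implementation, and the fit matches a reference stratified
implementation to 10⁻⁶.

**Significance.** The study's decision rule is CI-based. The published
wording applies "does not contain 1" to both models; for a slope in days
the meaningful null is 0, and the package uses 0 for regression
coefficients and 1 for hazard ratios (for the published intervals the two
readings agree). DP versions of the two models are out of scope, matching
the study's own choice.

## Numerical and reporting choices

* Ledger entries carry a per-node sequence number rather than wall-clock
  time, so identical runs produce byte-identical reports and message logs.
* Noisy denominators are floored (count ≥ 1 for means, ≥ 2 for variances),
  noisy variances floored at 0, DP histogram cells rounded to non-negative
  integers — all post-processing.
* The exponential-mechanism sampler works in log-space and drops
  zero-width intervals (ties); a single observed value collapses to itself.
* Reports print p-values to two decimals with `<.001` below 0.001; full
  precision is kept in the machine-readable JSON.
* Test problem sizes: calibration checks use 10⁴–10⁵ draws; federated =
  centralized equivalence uses 100 random 3-node federations; the DP t-test
  size uses 500 null replicates; percentile-pooling accuracy uses two
  4000-point nodes. These sizes make Monte-Carlo error a small fraction of
  each tolerance while keeping the default suite under a couple of minutes.

## Worked example

```{r example, eval = FALSE}
library(fedstats)

nodes <- as_nodes(build_fixture(seed = 1))
report <- run_full_study(nodes, dp = TRUE, seed = 42)
report$flowchart
round(report$p_values, 3)
report$confounders
tidy(report$cox, exponentiate = TRUE)
autoplot(report$cox)
```

## Known limitations

* ε = 5 per univariate release and ε = 60 per t test are *large* budgets,
  chosen (as in the study the pipeline replicates) to keep results usable
  at ~50 patients per center; they should not be read as strong privacy.
* Quantile pooling is the n-weighted average of per-node quantiles — an
  approximation that is exact only when node distributions coincide.
* Pure ε-DP with additive composition only; (ε, δ)-DP, Rényi accounting
  and cryptographic secure aggregation are out of scope.
* The simulated federation is in-process message passing; network
  transport, authentication and server deployment are not modelled.
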