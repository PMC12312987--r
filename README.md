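# fedstats

Federated statistical analysis with local differential privacy for
multi-center clinical studies.

## What problem this solves

Hospitals cannot share patient-level records, but multi-center questions
need pooled answers. `fedstats` simulates the full analysis stack for that
setting: each hospital is a *node* holding a local patient table; a
*coordinator* sends statistical queries; nodes answer only with aggregate
messages (counts, sums, sums of squares, bin counts, quantiles, gradient /
Hessian pairs), after applying minimum-cell-count disclosure checks and —
optionally — local differential privacy. The package is aimed at
biostatisticians and methods researchers who want to study, teach or
prototype privacy-preserving federated analyses with a fully inspectable,
deterministic implementation.

It ships a complete replication pipeline for a real-world oncology use
case: comparing first-line treatment duration and 24-month disease
progression of metastatic non–small cell lung cancer patients enrolled
before versus after the first COVID-19 wave across three hospitals.

## The methods at its core

* **Laplace mechanism, pure ε-DP.** A query with sensitivity Δ under public
  clamp bounds [L, U] is released as q + Laplace(Δ/ε). Compound statistics
  split their budget (mean: ε/2 + ε/2; variance: ε/3 × 3); a per-node
  ledger enforces additive composition Σεᵢ. Quantiles use the exponential
  mechanism with utility −|#{x < t} − qn|; histograms get per-bin Laplace
  noise at total cost ε by parallel composition.
* **Federation.** Pooling is exact algebra on sufficient statistics:
  pooled mean Σnᵢmᵢ/Σnᵢ, pooled variance [Σ(nᵢ−1)sᵢ² + Σnᵢ(mᵢ−m̄)²]/(N−1),
  contingency tables summed cell-wise. Local DP noises before sending
  (k nodes ⇒ k× central-DP variance, and the package measures it);
  central DP adds one draw after pooling.
* **Study statistics.** Chi-square (Yates-corrected on 2×2) vs Fisher
  selected by the all-cells ≥ 5 rule; pooled-variance t tests from group
  summaries with a DP variant at ε/6 per sufficient statistic; confounder
  screening at p < .20; federated OLS by X′X / X′y sharing (identical to
  centralized least squares); Cox proportional hazards stratified by
  center, fitted by distributed Newton–Raphson with Breslow ties.

## Worked example

```r
library(fedstats)

nodes  <- as_nodes(build_fixture(seed = 1))   # 3 hospital nodes, 149 patients
report <- run_full_study(nodes)

report$flowchart
#>   period included progressed progression_free transferred duration_n
#> 1 before       75         63                9           3         72
#> 2 after        74         55               17           2         72

round(report$p_values, 3)
#>       organization             gender          age_class          bmi_class
#>              0.993              0.794              0.374              0.383
#> treatment_category        creatinemia
#>              0.000              0.458

report$confounders
#> [1] "treatment_category"

tidy(report$cox, exponentiate = TRUE)
#> # A tibble: 4 × 5
#>   term                            estimate std.error conf.low conf.high
#> 1 periodafter                        0.623     0.234    0.394     0.986
#> 2 ...treatment contrasts follow...
```

The fixture reproduces the published pooled tables exactly, so the
flowchart (72 patients per period in the duration analysis) and the
screening column (only treatment type below .20) match the study; the
model coefficients do not — they depend on patient-level structure that
was never published, which is why the per-patient columns are synthetic.

A single DP release, with its budget charged:

```r
s   <- dp_stream(42)
led <- new_ledger()
dp_mean(nodes$Toulouse$creatinemia, c(20, 300), epsilon = 5,
        stream = s, ledger = led, node = "Toulouse")
#> [1] 70.2595          # exact node mean is 68.9; Laplace noise at eps = 5
ledger_total(led, "Toulouse")
#> [1] 5
```

`run_full_study(nodes, dp = TRUE, seed = 42)` adds the DP pass: noisy
univariate descriptives (including DP min/max/median, which the plain
pipeline withholds as disclosive), noisy contingency tables, DP t tests at
ε = 60, and a full per-node budget ledger (225 per node for the default
analysis plan).

A thin command-line front end is installed with the package
(`system.file("cli", "fedstats", package = "fedstats")`) with subcommands
`simulate`, `fixture`, `run` (`--dp`, `--no-yates`, `--dump-messages`) and
`budget`.

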