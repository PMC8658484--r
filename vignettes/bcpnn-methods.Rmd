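---
title: "Case-based BCPNN disproportionality analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-based BCPNN disproportionality analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems (JADER, FAERS, VigiBase)
receive reports of *suspected* adverse drug reactions, not a census of
drug use. With no user denominator, a drug–event association is assessed
by disproportionality: does the event appear among the drug's reports
more often than among everyone else's? `pvsignal` implements this for the
four-table CSV layout of the Japanese database JADER — DEMO (one row per
case), DRUG (one row per exposure), REAC (one row per reported MedDRA
preferred term, PT), HIST (medical history; read for completeness, unused
by the analysis) — with the angioedema analysis of ACE inhibitors and
DPP-4 inhibitors as the bundled reference application.

## Counting rules

All counting is **by cases, not drug–event combinations**:

* A case reporting the same PT twice contributes one event registration
  (`case_db` stores the event *set*).
* A case is flagged for the target condition when its event set intersects
  the in-scope PT set of the SMQ definition — once, however many matching
  PTs it has. Both narrow- and broad-scope terms are used by default
  (`scope_filter = "narrow_and_broad"`), the narrower filter being an
  option.
* A case is exposed to a drug *class* when it has at least one counted
  exposure to at least one member; a case on two members counts once. The
  bundled reference counts show why this matters: the twelve ACE-inhibitor
  margins sum to 1596 while the class margin is 1578 — eighteen cases took
  two members.
* By default only exposures with role `suspected` count toward the 2×2
  table, since the analysis concerns suspected-drug-induced events; the
  combination-case listing (`find_combination_cases()`) uses all roles,
  because a patient on both classes need not have both drugs suspected.

Cases with subjective age terms ("youth", "elderly"), missing sex or
missing age are excluded before analysis (all three rules default on, each
removal tallied under its first matching reason). The retained count is
the database total N₊₊.

## The estimator

For each 2×2 table the BCPNN information component is

$$E(IC) = \log_2 \frac{(N_{11}+\gamma_{11})(N_{++}+\alpha)(N_{++}+\beta)}
{(N_{++}+\gamma)(N_{1+}+\alpha_1)(N_{+1}+\beta_1)}, \qquad
\gamma = \gamma_{11}\frac{(N_{++}+\alpha)(N_{++}+\beta)}
{(N_{1+}+\alpha_1)(N_{+1}+\beta_1)}$$

with hyperparameters γ₁₁ = 1, α₁ = β₁ = 1, α = β = 2. γ is recomputed per
table (the margin-coupled prior centred on independence), never cached
across tables. The variance is

$$V(IC) = \frac{1}{(\ln 2)^2}\left[
\frac{N_{++}-N_{11}+\gamma-\gamma_{11}}{(N_{11}+\gamma_{11})(1+N_{++}+\gamma)} +
\frac{N_{++}-N_{1+}+\alpha-\alpha_1}{(N_{1+}+\alpha_1)(1+N_{++}+\alpha)} +
\frac{N_{++}-N_{+1}+\beta-\beta_1}{(N_{+1}+\beta_1)(1+N_{++}+\beta)}
\right]$$

Two conventions deserve a note:

* The variance prefactor is $(1/\ln 2)^2$ — the delta-method conversion of
  a natural-log variance to bits². Only this reading reproduces published
  credible bounds from published counts (e.g. the enalapril interval
  2.06–2.71 from N₁₁ = 86, N₁₊ = 771, N₊₊ = 534,287).
* The 95 % credible interval is exactly $E \pm 2\sqrt{V}$, not
  $\pm 1.96\sqrt{V}$.

Internals run in log space (sums of `log()` terms, γ kept as a log) for
numerical robustness; outputs are bits. IC values print rounded to two
decimals (half-away-from-zero, like the published tables); stored values
keep full precision. Signal classification: `signal` iff IC₀₂₅ > 0,
`inverse` iff IC₉₇₅ < 0, else `none`. No multiple-testing adjustment is
applied anywhere.

Zero-exposure or zero-count rows are still computed and stored — the
priors make every table finite. Published tables are inconsistent about
*rendering* such rows (one prints an IC for a zero-count drug, another an
em-dash), so dash-rendering is a `format_ic_table(dash_zero_n11 =)`
renderer option, not a property of the statistic.

The reporting odds ratio `ror()` is included as a comparator only. Where
it could in principle serve as an alternative scorer, in this package it
is used to illustrate the small-count instability (undefined intervals at
zero cells) that motivates the shrunken IC.

## Recovering the unpublished event margin

Published signal tables print N₁₁ and N₁₊ per drug and the total N₊₊, but
rarely the event margin N₊₁. Since E(IC) is strictly monotone in N₊₁ with
the other counts fixed, a handful of published (N₁₁, N₁₊, IC) rows
over-determine it. `calibrate_margin()` recovers the integer N₊₁ by
exhaustive grid search (default 1–50,000; below the per-row maximum of
N₁₁ is infeasible and skipped) minimising the sum of squared deviations
from the published ICs, ties broken toward the smaller margin, warning if
the optimum sits on the range boundary. On the bundled thirteen
ACE-inhibitor rows this yields N₊₁ = 10,802 with an RMS residual of
0.003 bits — comfortably inside the two-decimal rounding of the published
values, which is itself the resolution limit of the method: the residual
floor implies an uncertainty of a few tens of cases on the recovered
margin, which moves third-decimal digits of downstream ICs only.

## The synthetic generator

Real reporting databases cannot be redistributed, so validation runs on
synthetic ones (`synthetic_config()` / `simulate_reports()`), generated
as:

1. sex and age band drawn from configurable categorical distributions;
2. drug exposures as independent Bernoulli draws per drug, optionally
   tilted pairwise (`co_rx` odds multipliers) to mimic co-prescription,
   optionally resampled until every case has an exposure;
3. the event occurring with probability
   $1-(1-p_0)\prod_{d\ \mathrm{exposed}}(1-p_0(\lambda_d-1))$, capped at
   0.99 (with a warning counting capped cases);
4. event cases receiving one to three distinct SMQ terms (narrow/broad
   drawn by weight) plus a background term every case gets, so case-level
   deduplication is exercised;
5. a configured fraction of cases having demographics corrupted
   (subjective age / missing sex / missing age) to feed the exclusion
   rules.

The event model anchors the baseline hazard $p_0$ at the case level and
lets each exposed drug contribute an *excess* factor $1-p_0(\lambda_d-1)$.
This makes λ the per-drug risk ratio in the small-$p_0$ limit: a
λ = 1 drug is exactly null — its asymptotic IC is 0 whatever else is in
the database — a λ = 4 drug has asymptotic IC near log₂ 4 = 2 bits, and
λ < 1 models inverse associations. The alternative of multiplying plain
per-exposure hazards $1-p_0\lambda_d$ was rejected because under it the
number of exposures itself drives the event probability, so even λ = 1
drugs score positive ICs and a null design produces spurious signals —
a masking-style artefact we keep available deliberately (a drug with huge
λ inflates N₊₁ and depresses everyone else's IC) but should not be built
into the null.

`truth_table()` gives the closed-form expected counts and asymptotic ICs;
the expectations factorize exactly for independent exposures, so
Monte-Carlo checks run with `co_rx` off and `require_exposure = FALSE`
(their defaults). `jader_like_config()` scales the reference study:
per-drug exposure probabilities matched to the published margins, λ set to
2^IC of the published scores, twenty background null drugs at 8 %
exposure each for realistic co-medication, baseline $p_0$ solved
numerically so the event prevalence equals the calibrated margin fraction
10,802/534,287, and exclusion-noise fractions of 1 % / 0.5 % / 1 %.

What the generator does **not** emulate: reporting dynamics over calendar
time (Weber effect), notoriety effects, duplicate or follow-up report
versions, correlated event terms, and realistic drug-name dirtiness.
Passing tests therefore demonstrate correctness of the counting and
scoring machinery under a known model, not robustness to real-world data
quality.

## Validation choices and problem sizes

* **Golden values**: every defined published IC and credible bound (21
  rows across both drug classes) must reproduce to ±0.02 bits with the
  calibrated margin, and classifications must match the published
  signal/inverse marks exactly.
* **Oracle equivalence**: the log-space implementation is checked against
  a plain-ratio transcription of the formulas on 100 random small tables
  (N₊₊ ≤ 5000) at 10⁻¹⁰ bits, and against frozen 50-digit
  arbitrary-precision evaluations on five fixed tables (including
  zero-count and prior-only degenerate tables) at 10⁻¹².
* **Properties**: strict monotonicity in N₁₁; shrinkage bounded by half a
  bit relative to the crude log ratio on large tables and vanishing under
  proportional upscaling (×10, ×100, ×1000); |IC| < 0.05 on exactly
  independent tables; variance strictly decreasing under table doubling.
* **Parameter recovery**: at the design n = 50,000, one drug with
  exposure 0.003 and λ = 4 over a dense null background, the ±2√V
  interval covers the asymptotic IC in ≥ 90 % of 100 seeded runs. The
  misses are upper-bound misses: the shrinkage that stabilises small
  counts biases E(IC) toward 0 by a few tenths of a bit at an expected
  N₁₁ of ~12, which is the documented cost of the prior.
* **Null calibration**: across 200 databases of 5,000 cases with eight
  all-null study drugs, the fraction of pairs classified as signals must
  stay at or below 7.5 % (nominal 2.5 % one-sided criterion plus margin;
  shrinkage keeps the observed rate near zero).

These sizes keep the whole suite under about a minute on one core while
leaving the Monte-Carlo bounds (3–4 standard errors) meaningful.

## Known limitations

* The reader targets the logical four-table schema, not the verbatim PMDA
  download (Japanese headers, multi-file releases); a column map and a
  CP932 encoding switch are provided as the bridge.
* Age handling models the published decade bands; finer ages collapse
  into them, and any unrecognized non-numeric token is treated as a
  subjective term.
* Duplicate *versions* of the same report (follow-ups) are not detected;
  deduplication is per case id and per term only.
* The margin calibration assumes all supplied rows share one database and
  one event definition; mixing releases silently degrades the fit (watch
  the reported RMS).
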