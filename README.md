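# pvsignal

Disproportionality signal detection for spontaneous adverse-drug-reaction
reporting databases, using the Bayesian Confidence Propagation Neural
Network (BCPNN) information component.

Pharmacovigilance databases such as JADER, FAERS and VigiBase collect
spontaneous reports of suspected adverse drug reactions. Because there is
no denominator of drug users, safety signals are sought by
*disproportionality*: for a drug (or drug class) and an adverse event, the
cases are cross-classified into a 2×2 contingency table

|              | target event | other events | total |
|--------------|:------------:|:------------:|:-----:|
| target drug  | N₁₁          | N₁₀          | N₁₊   |
| other drugs  | N₀₁          | N₀₀          | N₀₊   |
| total        | N₊₁          | N₊₀          | N₊₊   |

and the reporting association is scored. `pvsignal` is aimed at
pharmacoepidemiologists working with the four-table (DEMO / DRUG / REAC /
HIST) CSV layout used by JADER: it reads and deduplicates the case-level
data, applies the conventional exclusions (subjective or missing age,
missing sex), flags cases against a Standardized MedDRA Query (SMQ) event
definition, builds *case-based* tables for drugs and drug classes (a case
counts once however many member drugs or matching preferred terms it
carries), and scores them.

## The statistic

The information component is the posterior expectation of the log₂
observed-to-expected reporting ratio under Dirichlet-style priors
(γ₁₁ = 1, α₁ = β₁ = 1, α = β = 2, with the joint-cell prior scale γ
recomputed per table so the prior is centred on independence):

    E(IC) = log₂ [ (N₁₁+γ₁₁)(N₊₊+α)(N₊₊+β) / ((N₊₊+γ)(N₁₊+α₁)(N₊₁+β₁)) ]
    γ     = γ₁₁ (N₊₊+α)(N₊₊+β) / ((N₁₊+α₁)(N₊₁+β₁))

with the matching posterior variance V(IC) and the 95 % credible interval
E(IC) ± 2√V(IC). A pair is a **signal** when the lower bound IC₀₂₅ > 0 and
an **inverse signal** when the upper bound IC₉₇₅ < 0. The priors keep every
term positive, so zero-count cells score finitely — the property that makes
the BCPNN stable at small counts where the reporting odds ratio (also
provided, as `ror()`) breaks down.

## Worked example

Published JADER angioedema counts are bundled
(`angioedema_reference()`). The event margin N₊₁ is never printed in such
tables; `calibrate_margin()` recovers it once by integer grid search
against the published ACE-inhibitor ICs, after which any row can be scored:

```r
library(pvsignal)
ref <- angioedema_reference()
ace <- ref$counts[ref$counts$class == "ACE inhibitors", ]
cal <- calibrate_margin(ace$n11, ace$n1plus, ace$ic, ref$n_total)
#> Calibrated event margin N+1 = 10802 from 13 published rows (RMS residual 0.0028 bits)

fit <- bcpnn(setNames(c(86, 26, 0), c("enalapril", "sitagliptin", "delapril")),
             n1plus = c(771, 2131, 10), nplus1 = cal$nplus1,
             nplusplus = ref$n_total)
fit
#> BCPNN information-component scores (3 tables)
#>        group n11 n1plus                       ic
#>    enalapril  86    771    2.39 * (2.06 to 2.72)
#>  sitagliptin  26   2131 -0.71 † (-1.27 to -0.15)
#>     delapril   0     10    -0.29 (-3.30 to 2.72)
```

Enalapril–angioedema is a signal (IC 2.39, IC₀₂₅ = 2.06 > 0: its users
report angioedema about 2^2.39 ≈ 5 times more often than the database
background), sitagliptin an inverse signal (IC₉₇₅ = −0.15 < 0), and
delapril — with zero angioedema cases among its 10 reports — still gets a
finite, shrunken score. `coef()`, `confint()` and `summary()` work as
usual.

For end-to-end runs there is `run_analysis()` (read → exclude → flag →
count → score → write), and `simulate_reports()` generates synthetic
four-table databases with known ground truth (`truth_table()`) for
validating the whole pipeline; `jader_like_config()` mimics the reference
study's scale and structure.

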