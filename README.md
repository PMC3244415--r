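# vulnmeta

Study-level meta-analysis tools for detecting **genetic vulnerability to
LDL cholesterol**: the situation in which a common polymorphism leaves the
average disease risk unchanged yet scales how strongly LDL drives
cardiovascular risk — and therefore how much clinical benefit carriers
gain from LDL-lowering therapy.

The package is written for epidemiologists and biostatisticians who work
with published study-level data (2×2 tables, printed RRs with confidence
intervals, trial arms with achieved LDL differences) rather than
individual patient data. The motivating application is the KIF6 Trp719Arg
polymorphism and statin therapy, but every function is generic over
genotype/exposure labels.

## The model and the inference chain

Event risk is log-linear in LDL with a genotype interaction:

    π(G, L) = π₀ · exp( β_L (L − L_ref) + G · [β_G + β_GL (L − L_ref)] ),
    β_G = −β_GL (L₀ − L_ref)

so carrier and non-carrier risks cross at LDL `L₀`. The interaction
`β_GL` — the log **ratio of RRs per mmol/L** — is simultaneously:

1. the slope of the carrier-vs-non-carrier log RR across studies with
   different mean LDL (estimated by random-effects **meta-regression**);
2. the difference between carrier and non-carrier per-mmol/L treatment
   effects in genotype-stratified trials (estimated by **per-mmol/L
   standardization**, dividing each trial's log RR and SE by its
   between-arm LDL difference `Y`, then DerSimonian–Laird pooling within
   strata and a **Z-test** between them).

The package estimates both, inverts the meta-regression slope into an
*expected* benefit ratio per mmol/L of LDL lowering, `exp(−β̂_GL)`, and
compares it with the *observed* trial ratio. A synthetic-data module
simulates entire study collections (cohorts, case-control studies,
stratified trials) from the risk model above, so the whole chain is
testable end to end.

## Worked example

```r
library(vulnmeta)

model      <- vulnerability_model()   # β_L = ln 1.25, β_GL = ln 1.15, crossing at 3.5 mmol/L
collection <- simulate_paper_like_collection(model, seed = 1)
report     <- run_full_analysis(collection, seed = 1)
print(report)
```

```
== Genotype-disease association (all studies) ==
Random/fixed-effect pool of k = 37 studies
  pooled RR = 1.029 (95% CI 0.966-1.096)
  Q = 154.972 on 36 df, I2 = 76.8%, tau2 = 0.02687

== LDL meta-regression (prospective units) ==
Random-effects meta-regression (tau2 by REML), k = 19
  slope: ratio of RR per mmol/L = 1.212 (95% CI 1.142-1.286)
  residual tau2 = 0, null tau2 = 0.03034, R2 = 100.0%

== Stratified statin-trial benefit (per mmol/L) ==
carriers:     RR per mmol/L: 0.699 (95% CI 0.646-0.755), log SE 0.040
non-carriers: RR per mmol/L: 0.848 (95% CI 0.758-0.949), log SE 0.057

== Predicted vs observed differential benefit ==
expected benefit ratio per mmol/L decrease: 0.825 (0.778-0.875)
observed benefit ratio per mmol/L decrease: 0.824 (0.719-0.944)
agreement z = 0.02, p = 0.986
```

Reading the output: across all 37 simulated studies the variant shows *no
marginal association* with disease (pooled RR 1.03, CI spans 1) — yet the
meta-regression detects the interaction (the carrier RR grows 1.21-fold
per mmol/L of study LDL; its CI covers the simulated truth of 1.15), and
the benefit ratio predicted from that slope (0.825 per mmol/L of LDL
lowering) agrees almost exactly with the ratio observed in the simulated
trials (0.824, z = 0.02). This is the vulnerability signature: average
null, strong effect modification, concordant predicted and observed
differential benefit.

Working from published numbers instead of tables:

```r
slope <- estimate_from_ci(1.15, 1.06, 1.25)      # printed meta-regression ratio
confint(invert_ratio(slope))                     # 0.87 (0.80-0.94) per mmol/L decrease
cmp <- compare_estimates_z(estimate_from_ci(0.73, 0.66, 0.80),   # carriers
                           estimate_from_ci(0.83, 0.76, 0.91))   # non-carriers
confint(cmp$ratio)                               # 0.88 (0.77-1.00)
```

A thin command-line wrapper with `simulate`, `meta`, `metareg`, `trials`,
`sensitivity` and `report` verbs lives in `inst/cli/vulnmeta.R`; the CSV
schema and a YAML generator configuration example are under
`inst/extdata/`.

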