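---
title: "Detecting genetic vulnerability to LDL cholesterol from study-level data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic vulnerability to LDL cholesterol from study-level data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnmeta)
```

## The scientific question

A common SNP may leave average disease risk untouched and still matter
clinically, if it changes how strongly an exposure drives risk. The
motivating case is a kinesin-family polymorphism (KIF6 Trp719Arg) and LDL
cholesterol: carriers of the variant allele appeared to gain more from
statin therapy than non-carriers, despite identical LDL lowering and no
overall association between the allele and cardiovascular disease (CVD).
A *vulnerability* model reconciles these observations: if carriers have a
steeper log-risk slope in LDL, then

* the carrier-vs-non-carrier relative risk (RR) depends on the LDL level
  of the population under study — positive at high LDL, null at some
  crossing point, inverse at low LDL — so a collection of studies centered
  near the crossing shows no *average* association;
* carriers gain more risk per mmol/L of LDL increase, and symmetrically
  lose more risk per mmol/L of LDL decrease, so they derive a larger
  benefit from any therapy that lowers LDL.

`vulnmeta` implements the full study-level inference chain for this
hypothesis: per-study effect estimation from 2×2 tables, random-effects
meta-analysis of the genotype–disease association, meta-regression of the
study log RRs on mean LDL, per-mmol/L standardization of
genotype-stratified trial effects, and the comparison of the benefit
difference *predicted* by the meta-regression with the difference
*observed* in trials. A synthetic-data module generates whole study
collections from the vulnerability model so that every stage — and the
chain as a whole — can be validated without access to individual patient
data.

## The risk model

For genotype carrier status $G \in \{0,1\}$ and study-level LDL $L$
(mmol/L), event risk is log-linear:

$$\pi(G, L) = \pi_0 \exp\!\big(\beta_L (L - L_\mathrm{ref}) +
  G\,[\beta_G + \beta_{GL}(L - L_\mathrm{ref})]\big),$$

with $\beta_G = -\beta_{GL}(L_0 - L_\mathrm{ref})$ so that carriers and
non-carriers have equal risk exactly at the crossing LDL $L_0$. The
interaction $\beta_{GL}$ is the log *ratio of RRs* per mmol/L — both the
slope of the carrier-vs-non-carrier log RR in LDL (what meta-regression
estimates) and the difference between the carrier and non-carrier
per-mmol/L treatment effects (what stratified trials estimate). That
identity is the symmetry the package tests and exploits: the per-mmol/L
*decrease* benefit ratio is exactly $\exp(-\beta_{GL})$.

Risks are never clamped; a parameterization whose risk reaches 1 anywhere
on the declared LDL range is rejected at construction.

## Estimators

**Per-study effects.** Prospective designs (cohorts, and each trial arm
treated as a separate cohort) give an unadjusted RR with the delta-method
log standard error $\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)}$;
case-control designs give the Woolf odds ratio with SE
$\sqrt{1/a + 1/b + 1/c + 1/d}$, pooled on the same log scale as the RRs
(the rare-disease approximation, which the test suite verifies at event
fractions below 1%). When any cell is zero, the Haldane–Anscombe
correction adds 0.5 to all four cells of that table; this is a documented
package choice (published collections rarely state their zero-cell rule),
togglable via `correction = FALSE`, in which case a zero cell is an error.
All confidence limits use the exact normal quantile
($z_{0.975} = 1.959964$), not 1.96, and are symmetric on the log scale.
Published estimates enter through `estimate_from_ci()`, which recovers the
log SE as $(\ln \mathrm{hi} - \ln \mathrm{lo})/2z$.

**Pooling.** `pool_random_effects()` is DerSimonian–Laird: a fixed-effect
pass with weights $1/se_i^2$ yields Cochran's $Q$, then
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w_i - \sum w_i^2/\sum w_i)\}$
and re-weighting by $1/(se_i^2 + \hat\tau^2)$. $I^2 = \max\{0,
(Q-df)/Q\} \cdot 100$. A single study passes through with heterogeneity
flagged not estimable; the pooled CI uses the normal approximation (no
Knapp–Hartung), matching the software era of the analyses this package
emulates.

**Meta-regression.** `fit_meta_regression()` fits
$y_i = \beta_0 + \beta_1 x_i + u_i + \varepsilon_i$ with known
$\mathrm{Var}(\varepsilon_i) = se_i^2$ and $\mathrm{Var}(u_i) = \tau^2$,
the moderator $x_i$ being study mean LDL. Two $\tau^2$ estimators are
exposed, since the originating analyses predate full documentation of
their settings: restricted maximum likelihood (the default) and the
non-iterative method of moments (the $Q_E$-based generalization of
DerSimonian–Laird to a design matrix). The REML estimate is the root of
the restricted score
$-\tfrac12\,\mathrm{tr}(P) + \tfrac12\, y^\top P P y$ with
$P = W - WX(X^\top WX)^{-1}X^\top W$. We locate that root by bracketing
and Brent root-finding (tolerance $10^{-8}$ on $\tau^2$) rather than plain
Fisher scoring: on realistic collections — small $\tau^2$ against
heterogeneous within-study variances — the undamped Fisher-scoring
iteration can cycle around the optimum indefinitely, while the bracketed
root is unique in practice and found in a handful of evaluations. The
boundary estimate $\hat\tau^2 = 0$ is returned whenever the score is
non-positive at zero. Coefficients are weighted least squares at
$\hat\tau^2$; the prediction SE at any LDL uses the full coefficient
covariance.

The variance explained, $R^2 = 100\,(\hat\tau^2_\mathrm{null} -
\hat\tau^2_\mathrm{resid})/\hat\tau^2_\mathrm{null}$, refits the
intercept-only model *under the same* $\tau^2$ *method* so the comparison
is like with like, and is truncated to $[0, 100]$ — negative values are
artifacts of $\tau^2$ noise.

**Trials.** Each genotype stratum of each trial yields an intent-to-treat
RR (active vs control); its log and SE are multiplied by $1/Y$, where $Y$
is the trial's between-arm LDL difference, putting placebo-controlled and
intensity-comparison trials on one per-mmol/L scale. Standardized
estimates carry a `per_mmol` scale label, and the pooling layer refuses to
mix labeled scales. The pooled carrier and non-carrier effects are
compared by a Z-test on the log difference with SE
$\sqrt{se_1^2 + se_2^2}$; the same comparison applied to the inverted
meta-regression slope versus the observed stratum ratio quantifies
predicted-vs-observed agreement.

## The synthetic-data generator

`simulate_paper_like_collection()` emulates the *shape* of the published
evidence base: 3 large epidemiologic cohorts (12,800 persons each,
mean LDL 2.0–5.0 mmol/L), 8 two-arm trials (3,100 per arm; control-arm
LDL 3.3–4.7; $Y$ from 0.3 to 1.8 mmol/L; 5 placebo-controlled, 3
intensity comparisons) whose 16 arms double as prospective cohorts — 19
meta-regression-eligible units in all — and 18 case-control studies
(~1,550 cases and controls each) that join only the association
meta-analysis, since, as is typical, they report no usable mean LDL.
Totals echo a ~145,000-participant collection. Default model parameters
are plumbing, not estimates: allele frequency 0.37, baseline risk 0.05 at
LDL 3.0, $\beta_L = \ln 1.25$, $\beta_{GL} = \ln 1.15$, crossing at
3.5 mmol/L — chosen so the collection is approximately centered at the
crossing, reproducing the "no average association, strong interaction"
structure.

Genotypes are drawn in Hardy–Weinberg proportions; events binomially per
genotype stratum; case-control genotype mixtures come from Bayes
inversion of the population mixture against the model risks. A master
seed fans out to per-study child seeds through a stable polynomial hash
of the study id, so adding a study never perturbs the counts of another.

What the generator does **not** model — and hence what passing tests do
not certify about real data: individual-level LDL variation within a
study (the analysis consumes study means, so only the study-mean
abstraction is exercised), follow-up time, censoring and competing risks,
outcome-definition heterogeneity across studies, covariate confounding,
linkage disequilibrium and population stratification, and publication
bias. Effects estimated from real collections also carry extraction and
rounding error the simulator does not inject.

## Numerical and design choices

* Continuity correction +0.5 on all four cells, per table, only when a
  zero cell occurs; a warning-free, deterministic rule.
* REML by bracketed root-finding as described above; method of moments
  retained as `method = "mom"`.
* $\tau^2$ truncation at 0 everywhere ($Q \le df$ gives the fixed-effect
  pool); $R^2$ truncated to $[0, 100]$.
* `k = 1` pools pass through rather than erroring, so sensitivity subsets
  can isolate single studies; meta-regression requires $k \ge 3$ and a
  non-constant moderator and errors otherwise.
* One moderator only (study LDL); the binary-moderator reuse of the same
  machinery provides the alternate estimator of the observed stratum
  ratio.
* Report serialization is deterministic: identical inputs and settings
  give byte-identical JSON.

## Validation strategy and problem sizes

Every closed-form operation is checked against hand-evaluated examples
and against independent brute-force oracles written from the textbook
definitions; the REML fit is additionally cross-checked against an
independent meta-analysis package and verified to maximize a directly
computed restricted likelihood. Pipeline-level validation is Monte Carlo
under the vulnerability model at the default (paper-shaped) study sizes:
200 replicates per harness, checking that the meta-regression slope CI
covers the true interaction at its nominal rate, that slope and stratum
contrast estimate the same coefficient with opposite signs (symmetry),
that expected and observed benefit ratios agree within two joint
standard errors, and that the marginal genotype association stays null
while the interaction is detected. These sizes keep the full suite under
a minute on a single core while leaving the binomial noise small relative
to the tolerances tested.

## Limitations

Study-level meta-regression estimates an across-study relationship and is
exposed to ecological confounding that the simulator, which generates
data from the assumed model, cannot reveal. The OR-for-RR approximation
is safe only for rare outcomes; the package applies it exactly where the
emulated analyses did (case-control studies) without re-weighting. The
expected-benefit transform assumes strict log-linearity in LDL; any
curvature in the true dose–response breaks the exact reciprocity between
per-increase and per-decrease effects.
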