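---
title: "Models and methods behind diallelkit"
author: "diallelkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diallelkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelkit)
```

# The problem

Hybrid wheat breeding programs evaluate a set of inbred parents and the
F1 hybrids among them in replicated multi-environment yield trials. The
questions asked of such a trial are always the same: how much of the
phenotypic variation is genetic (heritability), how much better is a
hybrid than its parents (heterosis), and how does the genetic value of
a cross decompose into what each parent contributes on average (general
combining ability, GCA) versus what is particular to the combination
(specific combining ability, SCA). diallelkit implements this analysis
chain for the common practical case of a *partial* diallel: an
incomplete male-by-female factorial without selfs or reciprocals, here
sized after a trial of 7 male lines by 11 female testers with 23 of the
77 possible crosses realized, grown with the 18 parents in 2 locations
by 2 years by 2 replicates in an alpha-lattice-style layout.

# Trial mixed models

All single-trait analyses use the Gaussian variance-component model

$$y = X\beta + \sum_r Z_r u_r + e, \qquad
  u_r \sim N(0, \sigma^2_r I), \quad e \sim N(0, \sigma^2_e I),$$

fitted by restricted maximum likelihood (REML). Two canned
specifications mirror standard trial practice:

* **Single environment** (`spec_single_env()`): genotype plus random
  incomplete blocks (blocks nested in environment and replicate —
  the block count per replicate is design metadata the data file
  carries, so blocks are modelled generically).
* **Combined across environments** (`spec_combined()`): one fixed
  environment factor (location x year, spanning location, year and
  their interaction), random genotype-by-environment interaction, and
  random blocks.

Genotype is taken **fixed** to produce BLUEs — each genotype's
coefficient is its adjusted mean, because genotypes are coded as cell
means with sum-to-zero contrasts on the nuisance factors — and
**random** to produce BLUPs and the genotypic variance components.
BLUEs feed the trait correlations and heterosis; variance components
feed heritability.

## The REML engine

`reml_engine()` works through Henderson's mixed-model equations. It
first runs EM iterations (classical updates
$\sigma^2_r \leftarrow (\hat u_r'\hat u_r + \sigma^2_e\,
\mathrm{tr}\,C_{rr})/q_r$), each of which cannot decrease the
restricted log-likelihood — the fit object exposes the trace and the
test suite asserts monotonicity — and then polishes the *profiled*
restricted likelihood over the log variance ratios
$\gamma_r = \sigma^2_r/\sigma^2_e$ with a quasi-Newton step
(`nlminb`), the same profiling strategy the major mixed-model packages
use. The polish exists because plain EM approaches small components
geometrically slowly; with it, balanced-design fits agree with ANOVA
closed forms to $10^{-6}$ and unbalanced fits agree with an
independent REML implementation (lme4) to the same precision.

Numerical choices:

* Convergence: relative change in components below $10^{-8}$ and
  change in restricted log-likelihood below $10^{-9}$; at most 200
  iterations per phase.
* Non-negativity: a component falling below $10^{-7}$ of the response
  variance is pinned at exactly 0 and flagged `boundary`, rather than
  reported as a tiny positive.
* Aliased fixed-effect columns are dropped by pivoted QR with a
  warning naming the columns.
* Degenerate data (zero residual after the fixed effects) short-
  circuits to OLS with all components zero.
* The restricted log-likelihood includes $\log|X'V^{-1}X|$ and is
  therefore *basis dependent*; likelihood-ratio tests inside the
  package always reuse the same fixed basis, and the cross-check
  against lme4 fixes the contrasts to match.

Component significance stars use a likelihood-ratio test against the
model with that component dropped, referred to the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the standard reference for a
variance tested on its boundary.

# Genetic parameters

Broad-sense heritability is computed on an entry-mean basis,

$$H^2 = \frac{\sigma^2_g}
  {\sigma^2_g + \sigma^2_{g\times e}/n_e + \sigma^2_e/(n_e n_r)},$$

with $n_e$ environments and $n_r$ replicates. For the components
$\sigma^2_g = 21.31$, $\sigma^2_{g\times e} = 14.43$,
$\sigma^2_e = 4.84$ at $n_e = n_r = 2$ this gives
`r round(broad_sense_h2(21.31, 14.43, 4.84, 2, 2), 4)`. No small
integer $(n_e, n_r)$ maps those components to 0.94 — a reminder that a
printed heritability can only be audited together with its components;
the package always derives $H^2$ from components it has itself
estimated.

For narrow-sense heritability the package adopts the same entry-mean
formula applied to the hybrid-analysis components (so the
additive-vs-total distinction lives in *which* components enter, not
in the formula), and records that interpretation in an attribute. A
formula occasionally seen in print that duplicates $\sigma^2_g$ in the
denominator is available behind `variant = "as-printed"` for
comparison only; as printed it is internally inconsistent with its own
label.

`lsd()` is the usual $t_{1-\alpha/2,\,edf}\sqrt{2\sigma^2_e/n_r}$;
`gcv()` is $100\sqrt{\sigma^2_g}/\bar x$; `correlation_matrix()` is
pairwise-complete Pearson with two-sided t p-values and **no**
multiplicity correction (matching common reporting practice for trait
correlation tables; stars mark 0.05/0.01/0.001/0.0001).

# Heterosis

With $MP = (P_1+P_2)/2$ and $BP$ the better parent,

$$MPH = 100\,\frac{F_1 - MP}{MP}, \qquad
  BPH = 100\,\frac{F_1 - BP}{BP}.$$

All registry traits are treated as higher-is-better when picking the
best parent (matching how such trials report even days-to-heading);
the flag is per-trait metadata, so a maintainer can flip it.
`heterosis_table()` computes one record per cross, trait and scope
from BLUE tables; combined-scope records use combined-analysis BLUEs,
never averages of per-environment heterosis percentages. For strictly
positive traits $BPH \le MPH$ algebraically, and both are invariant
under rescaling all three means — the property suite checks both.

Significance is assessed as a linear contrast $F_1 - (P_1+P_2)/2$ (or
$F_1 - BP$) on the fixed-genotype fit, with the REML fixed-effect
covariance and a t reference on the residual degrees of freedom; no
multiplicity correction by default. Under an additive null this test
holds its nominal size: the acceptance suite simulates 1,000 additive
diallels and observes a rejection rate within 0.05 ± 0.02.

# Combining ability

For hybrid plots the model is

$$y_{ijk} = \mu + g_i + g_j + s_{ij} + \varepsilon_{ijk},$$

with environments entering as fixed replication effects. Because the
realized design is an incomplete factorial without reciprocals or
selfs, the classical complete-diallel method cannot be applied
directly; the package fits the model on the realized crosses and keeps
the complete-grid closed form (`griffing_oracle()`: row, column and
interaction means) purely as a verification oracle, which fixed-mode
fits match to $10^{-6}$ on complete balanced grids.

* **Random mode** (default, matching BLUP-based trial practice): one
  shared GCA variance for all 18 parents — the design matrix has a 1
  in both the female's and the male's column, so a single
  $\sigma^2_{GCA}$ is estimated even though parents appear on
  different sides of the cross (a `separate_gca` flag splits male and
  female variances when wanted) — plus $\sigma^2_{SCA}$, an optional
  $\sigma^2_{GCA\times L}$ by location, and plot error. Effects are
  BLUPs with prediction-error-variance z-tests.
* **Fixed mode**: constrained least squares. A single sum-to-zero
  constraint over all parents leaves a male-versus-female shift
  unidentified on designs without selfs
  ($\mathrm{rank}[\mathbf 1, Z_g] = n_{parents} - 1$), so the
  constraint is imposed separately within males and within females,
  which is exactly the convention of the complete-grid closed form.
  SCA effects are residual cross means of the additive fit, written as
  explicit linear functions of the data so their standard errors are
  exact; being least-squares residuals they are orthogonal to the GCA
  columns, hence each parent's realized crosses sum to zero under
  equal replication.

The ratio $\sigma^2_{GCA}/\sigma^2_{SCA}$ summarizes gene action
(above one: predominantly additive); it is undefined — rendered "-" —
when $\sigma^2_{SCA}$ is pinned at zero.

## Disconnected designs

A noteworthy property of the bundled real 23-cross plan: its crossing
graph has **three** connected components, so fixed-effect GCA
contrasts between parents in different components are confounded with
component means. `validate_design()` detects this via breadth-first
search, and the test suite verifies the flag against a brute-force
rank computation of $[\mathbf 1, Z_g]$. Fixed mode refuses
disconnected designs; random mode proceeds with a warning, since
shrinkage toward zero keeps BLUPs defined — which is how such trials
are analyzed in practice.

# The synthetic-trial generator

`simulate_diallel_trial()` draws every effect from independent
zero-mean normals (the implicit assumption of the mixed models; heavy
tails are out of scope) and assembles hybrid plots as
$\mu + env + g_f + g_m + s + (g\times e) + block + residual$. Parents
per se are $\mu + env + 2g + d$ with $d \sim N(0, \sigma^2_{parent})$:
doubling the GCA makes a purely additive configuration satisfy
$E[F_1] = MP$ exactly, so additive simulations are a true null for
heterosis, while $\sigma^2_{parent}$ lets the parents' own genetic
variance exceed the GCA variance, as separate parent/hybrid analyses
of real trials show. Default dimensions and variance components mirror
the grain-yield scale of the motivating trial (7 x 11 parents, 23/77
cross density, 2 locations x 2 years x 2 replicates, per-parent GCA
variance 0.07, SCA 0.011, plot error ~1.06 (t/ha)^2). Incomplete
blocks of about 10 plots are laid out at random within each
environment-replicate — the generator emulates block *variance*, not
spatial field trend, and there is no mechanistic model of the
sterility-inducing chemical treatment (doses are metadata only).

`simulate_floral_seedset()` draws genotype-level values of nine floral
and agronomic traits from a multivariate normal with a configurable
correlation target whose default encodes the tight observed
correlations of seed set with pollen mass (0.97), visual anther
extrusion (0.94) and pollen shedding (0.91). The target matrix is
repaired to positive semidefiniteness by eigenvalue flooring and
renormalization when its smallest eigenvalue is above -0.15 (the
default target's smallest eigenvalue is +0.0003, so it needs no
repair), and rejected beyond that. Visual scores are clipped to 1-9
after the draw; clipping attenuates their correlations slightly, so
recovery tests on clipped traits use wider tolerances.

What passing simulation-based tests does and does not show: the
generator shares the estimators' distributional assumptions, so
parameter-recovery results demonstrate internal consistency of the
implementation at realistic dimensions, not robustness to field
realities (spatial trend, outliers, non-normal scores, missing-plot
mechanisms).

# Known limits at the trial's own dimensions

With only 23 crosses carrying SCA information, the non-negativity
constraint of REML visibly inflates the *mean* SCA variance estimate:
across 500 simulated trials at the design dimensions
($\sigma^2_{GCA} = 0.25$, $\sigma^2_{SCA} = 0.05$, $\sigma^2_e = 1$),
about 30% of replicates pin $\sigma^2_{SCA}$ at zero and the mean
estimate is ~0.065-0.072, some 30-40% above truth, while the GCA and
residual components are recovered within a few percent. An independent
REML implementation (lme4) reproduces the same inflation on the same
data, and moving the truth away from the boundary
($\sigma^2_{SCA} = 0.5$) removes it — it is a property of
boundary-constrained REML at this design size, not of this
implementation. Similarly, the expected correlation between estimated
and true GCA effects at these dimensions is almost exactly 0.80 (each
parent appears in only ~2.6 crosses). Practical reading: in a 23-cross
trial, treat a small positive SCA variance — and ratios built on it —
with caution; the GCA ranking is considerably more trustworthy.

Problem sizes used by the test and acceptance suites (chosen to
exercise the estimators at and slightly above the trial's own scale):
complete grids up to 8 x 8 for oracle equivalence, 500 genotypes x 4
environments x 2 replicates for residual-variance recovery, 500
replicate partial diallels for the recovery study, and 1,000
replicates for the size of the heterosis test.

# Reporting conventions

`run_pipeline()` writes `genetic_summary.csv`, `correlations.csv`,
`heterosis.csv`, `combining.csv`, `varcomps.json` and a run log; every
CSV carries a header comment with the seed and a configuration hash,
and reruns with the same configuration are byte-identical. Numbers are
rounded only at serialization: 2 decimals for percentages and effects,
3 for variance components. Full precision is kept in the in-memory
objects.
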