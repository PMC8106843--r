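---
title: "Methods: joint ethnic-enclave and VOC exposure analysis of GDM risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint ethnic-enclave and VOC exposure analysis of GDM risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(enclaveVOC)
```

## The scientific question

Asian/Pacific Islander (API) women in the United States carry the highest
prevalence of gestational diabetes mellitus (GDM) of any racial/ethnic
group. Two community-level exposures plausibly pull in opposite directions:
residence in an *ethnic enclave* — a socially and geographically distinct
area with a high concentration of co-ethnic residents — is associated with
lower GDM risk, while high ambient air pollution, including volatile
organic compounds (VOCs), is associated with higher risk. This package
implements the joint-exposure analysis that crosses the two: does enclave
residence mitigate the harm of high VOC exposure?

The analysis operates on three tabular inputs: small-area (ZCTA-like)
demographic counts with an area-to-region crosswalk, a pregnancy cohort
table nested in regions (hospital referral region, HRR, in the motivating
study), and per-region time-resolved VOC concentration series in ppb.

## Segregation measures and enclave definition

For each region and census period we compute three area-level measures from
the unit counts $a_i$ (API), $w_i$ (White), $P_i$ (total), with region
totals $A_T$, $W_T$, $P_T$:

* **API population density** $= 100\, A_T / P_T$ (percent, 0–100);
* **Dissimilarity index** $= \tfrac12 \sum_i \lvert w_i/W_T - a_i/A_T
  \rvert$ (0–1): the share of either group that would need to relocate for
  an even distribution;
* **Isolation index** $= \sum_i (a_i/A_T)(a_i/P_i)$ (0–1): the probability
  that an API resident's random within-unit contact is also API.

Some formula tables print the isolation index with the *region* total
$P_T$ in the second factor. That form cannot reach its stated maximum of 1
for any multi-unit region, so `isolation_index()` defaults to the standard
unit-population form and offers `strict_printed_form = TRUE` for exact
reproduction of the printed variant.

A region is an **ethnic enclave** when it sits at or above the 66.667th
percentile of the between-region distribution on *all three* measures
simultaneously. Percentiles are linear-interpolation sample quantiles
(`stats::quantile` type 7); the boundary rule is "$\geq$ cutpoint ⇒ upper
tertile", the only rule consistent with an "at or above the 66th
percentile" definition, and it classifies everything as "high" when a
measure is degenerate (all regions equal). Because "population-based
percentiles" is ambiguous between region-weighted and person-weighted, both
are provided (`weighting = "none"` default, `"population"` optional);
cutpoints are always computed separately per census period, and births are
linked to periods by delivery year (2002–2004 to the decennial-census
profile, 2005 onward to the ACS-style profile).

## Exposure windows and dichotomization

Two clinical exposure windows are fixed at 91 days each: *preconception*
(the 91 days ending the day before conception) and *first trimester*
(conception through 13 gestational weeks). Concentrations are averaged with
equal weights over all series points falling in the closed window; the
estimate is invariant to timestamp resolution for step-constant series
(daily versus hourly-within-day fixtures give identical means). When only
gestational age from last menstrual period is available, conception is
delivery date minus gestational length plus 14 days.

Window averages are dichotomized per VOC and window at the 75th percentile
of the analytic sample (pooled across regions and periods — the stratum
sizes this produces, roughly 25% high, match the motivating study's
published tables; per-window or per-period cutoffs are configurable). Ties
at the cutoff are "high". Dichotomization is rank-based, hence invariant to
rescaling any one VOC.

## Joint categories and inference

Each pregnancy × VOC × window receives one of four categories: Low
VOC/Enclave (reference — anticipated lowest risk), Low VOC/No Enclave,
High VOC/Enclave, High VOC/No Enclave. Per VOC and window we fit

$$\operatorname{logit} P(\text{GDM}) = \beta_0 + \beta_{\text{cat}} +
\mathbf{x}^\top\gamma + u_{\text{region}}, \qquad u \sim N(0, \sigma^2_u),$$

adjusted for maternal age, marital status, insurance, BMI category, parity,
season of conception, hospital type, and region poverty. Fitting is
Laplace-approximate maximum likelihood via `glmmTMB` (`method = "laplace"`,
the default). For simulation studies involving thousands of fits the
`"pirls"` method (lme4's `nAGQ = 0`) is provided; on study-sized data its
fixed effects agree with Laplace to well under 1%, far inside any tolerance
used here, at roughly a tenth of the cost. The contract is the model, not
the optimizer; non-convergence is flagged on the result, never silently
dropped, and apparent complete separation (a diverging coefficient) is an
error naming the term.

**Cluster-robust variance.** About 8% of births are repeat births to the
same mother, so the fixed-effect covariance is wrapped in a cluster
sandwich over mothers, with scores conditional on the fitted random
intercepts: $V = B \left(\sum_g s_g s_g^\top\right) B$ with $s_g = \sum_{i
\in g} \mathbf{x}_i (y_i - \hat\mu_i)$ and $B$ the model-based covariance.
No small-sample factor is applied by default (CR0), so singleton clusters
reduce *exactly* to HC0 heteroskedasticity-robust errors; `cadjust = TRUE`
applies $G/(G-1)$. `re_variance` allows conditioning on a fixed
random-intercept variance (0 reduces the model to plain logistic
regression), which is also how the reduction property is verified
deterministically in the tests — with a freely estimated variance, the ML
estimate on truly-homogeneous data lands on the boundary only about half
the time, so exact agreement with a plain fit is a property of the
reduction, not of every dataset.

**Missing BMI.** BMI is missing for ~42% of the cohort and is handled as
the four standard categories (reference 18.5–<25). `impute_bmi()` draws `m
= 10` completed datasets: each imputation refits a multinomial logistic
model (on age, parity, insurance, marital status) to a bootstrap resample
of the complete cases and draws categories from the predicted
distributions, so parameter uncertainty propagates. Fits are pooled by
Rubin's rules — mean coefficients, total variance $\bar W + (1 + 1/m)B$
with $B$ the between-imputation variance (denominator $m - 1$), and
per-coefficient Rubin degrees of freedom for intervals.

**Multiplicity.** Benjamini–Hochberg step-up control at FDR $q = 0.10$; the
default family is the 3 contrasts × all VOCs within one exposure window (42
tests per window for the full panel), configurable to a single pooled
family. Decisions are computed through `stats::p.adjust(method = "BH")` and
are tested against a brute-force step-up oracle.

**Sensitivity analyses.** (1) Component models: the binary enclave
indicator and each component tertile fitted separately (low/non-enclave
reference), adjusted for the standard covariates plus dichotomized
preconception and first-trimester benzene. (2) "High multiple VOCs": PCA on
the standardized window-average matrix; VOCs whose first-component
correlation (eigenvector entry scaled by the component standard deviation)
reaches the `loading_threshold` (default 0.4) in every window form the
selected set, and a pregnancy is flagged only when high on *all* of them.
The threshold applies to component correlations rather than raw unit-norm
eigenvector entries deliberately: a perfectly correlated 7-VOC block has
raw entries $1/\sqrt 7 \approx 0.378$, which would fall below a 0.4 cut on
the raw scale no matter how strong the block is, while its component
correlations approach 1.

## The synthetic cohort generator

`study_config()` fixes the generator at the study conditions: 8350 mothers
with 7.9% of births repeat births (~9070 pregnancies), 20.8% of births in
enclave regions, covariate category frequencies from the published cohort
table, 42% MCAR missing BMI, baseline reference-category log-odds
calibrated once (−3.15) so marginal GDM prevalence is ~9.9% under the
default effects, a region random-intercept sd of 0.3, and true
joint-category odds ratios {Low/No-Enclave 1.5, High/Enclave 1.2,
High/No-Enclave 2.0}. Forty regions of 25 units are generated (the
motivating study's 15 regions are too few to emulate a meaningful tertile
distribution); a designated third of regions is made enclave-like with
API shares in 0.15–0.35 and strongly clustered within-region allocation
(Dirichlet concentration `segregation_strength`), the rest nearly evenly
mixed, so the designated subset lands in the top tertile of all three
measures and the classifier's output — the estimand — coincides with the
designation.

Exposure is generated daily (window averaging is resolution-agnostic):
log-normal fields whose region-level means *and* monthly regional
anomalies share one between-VOC correlation matrix (0.9 inside the 7-VOC
traffic block, 0.1 elsewhere), plus a VOC-specific annual sinusoid and
independent daily noise. Putting the correlation in the monthly anomalies
as well gives Spearman estimates an effective sample in the hundreds
rather than the number of regions. The GDM outcome is drawn *after* the
driver VOC (benzene, preconception) is averaged and dichotomized, so the
generating category is exactly the category the pipeline reconstructs —
parameter-recovery runs then measure estimation error, not exposure
misclassification.

What the generator does not emulate: real spatial autocorrelation of
census composition, CMAQ-style exposure fields and their error structure,
ancestry heterogeneity within the API category, or outcome
misclassification from medical records. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the stated
model, not robustness to those real-data features.

## Numerical choices and problem sizes

* Quantiles: type-7 linear interpolation throughout; `>=`-cutpoint
  boundary rule for tertiles and the 75th-percentile split.
* Percent formatting: one decimal, half-up rounding. (The motivating
  study's printed tables mix truncation and rounding and contain at least
  one arithmetic slip, so no single rule reproduces every printed cell;
  tabulations here are asserted against the underlying counts.)
* Rubin's between-imputation variance uses the standard $m-1$ denominator.
* The crude odds ratio refuses zero cells rather than applying a hidden
  continuity correction.
* Correlated draws use an eigendecomposition square root so perfectly
  correlated (singular) blocks are valid configurations.
* Simulation sizes used by the test suite, chosen as the package's own
  study conditions: the parameter-recovery study runs 200 replicates of
  5000 mothers in 40 regions with MI $m = 10$ using the `"pirls"` method;
  the PCA block-selection study runs 100 replicates of 600 mothers in 100
  regions over a 3-year conception range. The region count matters there:
  off-block sample correlations are driven by region-level mean draws, so
  their noise scales as $1/\sqrt{n_{\text{regions}}}$, and at 40 regions
  an off-block VOC crosses the 0.4 loading threshold in roughly one run
  in seven.

## Known limitations

* The enclave measure is region-level; within-region heterogeneity in
  enclave character is invisible at this geography.
* Exposure is assigned by region of delivery, not residence history;
  mobility-induced misclassification is not modelled.
* GEE-based table p-values from the motivating study are out of scope
  (their working-correlation specification is unstated); inference rests
  on the hierarchical model with mother-clustered sandwich errors.
* The component sensitivity models are fitted separately per measure; a
  single joint model over all enclave components is a documented
  alternative reading.
* `"pirls"` trades a sub-1% attenuation of fixed effects for an order of
  magnitude in speed; single fits of record should use the default
  Laplace method.
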