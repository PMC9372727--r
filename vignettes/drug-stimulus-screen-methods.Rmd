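---
title: "Models and methods behind DrugStimScreen"
author: "DrugStimScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind DrugStimScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrugStimScreen)
```

# Scope

DrugStimScreen analyses combinatorial ex vivo viability screens in which
primary tumour samples (the motivating system is chronic lymphocytic
leukaemia) are exposed on 384-well plates to a panel of drugs, a panel of
soluble microenvironmental stimuli (cytokines, TLR agonists, CD40 ligand,
anti-IgM, stroma-conditioned medium), and all drug-stimulus combinations,
with viability read out as ATP-dependent luminescence. The package covers
the full statistical path: plate normalization, robust scaling and
correlation structure, consensus clustering of stimulus-response profiles,
a linear interaction model with synergy/antagonism categorization,
bootstrap stability-selection lasso for genetic determinants, a read-ratio
trisomy-12 caller, and survival analyses. A synthetic-screen generator
with fully known ground truth backs every stage with parameter-recovery
and calibration tests.

# Normalization model

Each 384-well plate carries DMSO control wells. The reference for a plate
is the **median luminescence of its interior DMSO wells**; controls on the
outer plate edge (row 1, row 16, column 1, column 24) are excluded because
edge wells suffer evaporation artifacts. Every treated well becomes

$$\log V = \ln\!\frac{\text{luminescence}}{\mathrm{median}(\text{interior DMSO})}$$

so that $\log V = 0$ means no effect, negative values mean toxicity and
positive values a pro-survival effect. Because the reference is computed
within plate, any multiplicative plate effect (instrument drift, cell
number, reagent batch) cancels exactly; the generator plants per-plate
log-normal intercepts precisely so the tests can verify this cancellation.
Replicate wells of a condition are averaged after the log transform.

# The interaction model

For one drug $d$ and one stimulus $s$, with indicator variables $X_d$ and
$X_s$, the pooled no-intercept model across samples is

$$\log V = \beta_d X_d + \beta_s X_s + \beta_{int} X_d X_s + \varepsilon.$$

$\beta_{int}$, the interaction factor, measures how far the combination
departs from log-scale additivity of the two single treatments. DMSO rows
($X_d = X_s = 0$) are excluded from the fit: under this parameterization
they carry no design information, and the normalization itself centres
them near zero, so including them would only deflate the residual
variance. With balanced data the least-squares estimates are the three
condition means and the fitted combination value is exactly
$\beta_d + \beta_s + \beta_{int}$; with unbalanced data the least-squares
solution is authoritative. The p-value on $\beta_{int}$ is a two-sided
t-test with residual degrees of freedom; following the original screening
practice, "interaction present" means unadjusted $p < 0.05$ and no
multiplicity correction is applied at this step.

Significant interactions are classified by the sign of $\beta_{int}$ and
whether the combination is antagonistic or synergistic:

* **I** — positive $\beta_{int}$, antagonistic: a toxic drug is offset by
  the stimulus ($\beta_d < 0$, $\beta_{int} \le |\beta_d|$); the in-vivo
  reading is stimulus-induced drug resistance.
* **II** — negative $\beta_{int}$, antagonistic: the drug offsets a
  pro-survival stimulus ($\beta_s > 0$, $|\beta_{int}| \le \beta_s$).
* **III** — positive $\beta_{int}$ beyond the cancellation limit:
  synergistic pro-survival effect.
* **IV** — negative $\beta_{int}$ beyond the cancellation limit:
  synergistic toxicity.

Boundary ties (the interaction exactly cancelling the single-agent
effect) are classified as antagonistic: cancellation is the antagonism
limit, and the graphical definitions of the categories do not resolve the
tie algebraically. Fitting the same model within a single sample is
saturated, so the sample-specific coefficient reduces to the identity
$\beta_{int} = \log V_{combo} - \log V_{drug} - \log V_{stim}$, and the
cohort mean of the per-sample coefficients equals the pooled balanced
estimate exactly.

Two concentrations per drug are screened (a sublethal and a strongly
cytotoxic dose); the interaction analysis consumes one effective condition
per drug, by default the **lower** concentration (`concPolicy = "low"`),
selectable as `"high"` or `"average"`. The lower dose is the default
because synergy and protection are both observable there, whereas the
killing dose saturates.

# Robust scaling and correlations

For heatmaps and clustering, each sample's response row is centred at its
median and divided by its median absolute deviation (MAD, without the
1.4826 consistency constant — the plain MAD is the published convention
for these screens). The MAD is floored at `madFloor = 1e-8` so constant
rows map to zero, and a display copy is clipped at $\pm 4$; the stored
values are never clipped. Median-centering is used because the resulting
colour scale is signed (pro- vs anti-survival).

Pairwise Pearson correlations between single treatments are tested
two-sided and adjusted by Benjamini-Hochberg **within block** (drugs and
stimuli separately), at an FDR of 0.05. Constant columns yield undefined
correlations; they are reported missing and excluded from the adjustment.

# Consensus clustering

Stimulus-response profiles (the robust-z matrix restricted to the 17
stimulus-only conditions) are clustered by subsampled consensus: in each
repetition 80% of samples are drawn without replacement, clustered
hierarchically with the Euclidean metric and average linkage, and cut at
each candidate $k$; the consensus entry of a sample pair is its
co-clustering count divided by its co-sampling count. Average linkage is
used for both the inner and the final clustering (the published analyses
name only the metric; average linkage is the default of the consensus
clustering method they cite). The production default is 10,000
repetitions; the packaged tests use 100-500, which is already past the
point where consensus matrices on separable data are 0/1 to within 0.02.

$k$ is chosen by the standard consensus-CDF criterion: the relative
change in area under the consensus CDF, maximized over the evaluated $k$
(for the smallest $k$, the area itself). Two weak-structure signals are
reported: a flat relative-change curve (all below 0.1), and a
proportion-of-ambiguous-clustering (PAC) above 0.2 at the chosen $k$. The
PAC criterion was added because on unstructured data the CDF area keeps
rising with $k$, so the flat-curve rule alone never fires; PAC directly
measures how much of the consensus mass sits between 0.1 and 0.9, which
is the signature of subsampling noise. The full selection curve is always
returned so a user can override the choice (the motivating study fixes
$k = 4$).

# Stability-selection lasso

Three variants share one engine: samples are resampled with replacement;
within each bootstrap the predictors are standardized and an L1-penalized
model is fitted with the penalty chosen by internal 10-fold
cross-validation using the **one-standard-error rule**; the indices of
nonzero coefficients are recorded. Reported coefficients are means over
the bootstraps in which a predictor was selected, on the standardized
scale.

* **Gaussian** (stimulus response vs genetics): 30 bootstraps, keep
  predictors selected in strictly more than 75% of fits.
* **Multinomial** (cluster membership vs genetics): 50 bootstraps, keep
  predictors with selection frequency at least 60% *and* mean coefficient
  magnitude at least 0.35; the grouped multinomial penalty is used so a
  feature enters or leaves all classes jointly. Bootstrap resamples
  missing a cluster are redrawn (at most 100 attempts).
* **Modulator** (sample-specific $\beta_{int}$ vs genetics): gaussian
  engine with a strict 90% threshold; a drug-stimulus pair "has genetic
  modulators" when its kept set is non-empty. Pairs with fewer than 10
  complete-case samples are skipped.

The one-SE rule rather than the CV minimum is a deliberate choice: at the
CV-minimum penalty the lasso systematically drags null predictors into
the majority of bootstrap refits (in our calibration simulations null
features passed the 90% threshold at a 7.5% rate, and the multinomial
filter at 11.6%), which defeats the purpose of a selection-frequency
filter. With the one-SE penalty the same simulations recover every
planted predictor and keep no null ones. Selection frequencies are exact
multiples of $1/n_{boot}$, and kept sets shrink monotonically as the
frequency threshold grows.

Feature encoding follows the field's conventions: IGHV mutation status
M = 1 / U = 0; DNA methylation programming LP = 0, IP = 0.5, HP = 1;
KRAS/BRAF/NRAS collapsed into one RAS/RAF indicator; features with 20% or
more missing values dropped; complete cases only, with each analysis
recomputing its own complete-case set from the features it uses.
Univariate tests use equal-variance two-sided t-tests of carriers vs
non-carriers, excluding features with fewer than 3 carriers, with BH
adjustment across all performed tests at a 10% FDR.

# Trisomy-12 calling from ATAC peak counts

A third copy of chromosome 12 yields, on average, 1.5-fold more reads per
peak on that chromosome. The caller computes
mean(chr12 counts) / mean(other counts) and calls trisomy 12 when the
ratio strictly exceeds 1.4 — strictly, so a ratio of exactly 1.4 is a
negative call.

# Survival methods

Cox proportional-hazards models are fitted by maximum partial likelihood
with **Efron** tie handling (the default of the survival ecosystem these
analyses come from; the original reports do not state a tie method).
Categorical covariates expand against configurable reference levels
because the motivating analyses use different cluster references in
different comparisons. Kaplan-Meier curves are product-limit estimates
stepping only at event times. Continuous markers (e.g.
immunohistochemistry staining intensities) are dichotomized by maximally
selected rank statistics: all observed marker values inside the (0.1,
0.9) quantile window are candidate cutpoints, each scored by the
standardized two-group log-rank statistic, and the maximizing cutpoint is
reported. Because the maximum of dependent log-rank statistics is not
chi-squared distributed, the p-value is computed by permutation of the
marker values (seeded, 1000 permutations by default) rather than by one
of the many analytic approximations, none of which the original analysis
names.

# The synthetic-screen generator

The generator exists so that every downstream stage can be validated
against known truth. Wells are drawn from

$$\text{lum} = \text{base} \cdot \exp\!\big(\text{plate} + \beta_d X_d +
\beta_s X_s + \beta_{int} X_d X_s + \varepsilon\big), \qquad
\varepsilon \sim N(0, \sigma^2),$$

log-normal well noise because the analysis model is linear in log
viability. Defaults emulate the motivating study's structure: 192
samples, 12 drugs at two concentrations (the higher concentration doubles
the drug's log effect), 17 stimuli, 204 analysed combinations; mostly
pro-survival stimuli with IL4 and TLR agonists strongest and IL6/TGFb1
mildly toxic; four latent response clusters with planted proportions
(0.35/0.12/0.23/0.30) whose stimulus-effect offsets mirror the published
cluster phenotypes (strong IL4/TLR response in C1-C2, NFkB-amplified C2,
globally weak C3, TLR-toxic C4); IGHV-linked cluster composition and
methylation classes; recurrent lesions at realistic prevalences (trisomy
12 at 20%, TP53 12%, del13q 55%, ...); 5%
missing-completely-at-random genotypes; cluster-linked exponential
time-to-event hazards with uniform censoring; and a handful of planted
interactions of all four categories, including one trisomy-12-conditional
interaction (fludarabine x CpG-ODN). Per-sample multiplicative
heterogeneity of drug and stimulus sensitivity (sd 0.3) produces the
correlation structure that pathway-sharing treatments show across real
samples.

Cluster assignment is stratified (largest-remainder allocation to the
planted proportions) so even tiny cohorts contain every cluster. Plate
effects (sd 0.15 on the log scale) and the edge bias (-0.3, mimicking
evaporation) are placeholders — the study reports no magnitudes — and are
configurable; both exist to be *removed* by normalization, and the tests
verify exactly that. Magnitudes with no published value (noise sd 0.1,
base luminescence 1e6) were chosen once as plausible for CellTiter-Glo
screens and are not tuned.

What the generator does **not** emulate: spatial within-plate gradients
beyond the edge ring, dose-response curvature (each condition is a single
dose), measurement-batch effects shared across plates, informative
censoring, and linkage disequilibrium between genetic features. Passing
tests on generator output therefore demonstrate the statistical
correctness of the pipeline under the model's assumptions, not robustness
to every artifact of real plates.

# Numerical and degenerate-input choices

* Interior-DMSO medians require at least one interior control per plate;
  zero or negative luminescence anywhere is an error, never coerced.
* Saturated interaction fits (zero residual df) report a missing p-value.
* A constant response vector in the stability lasso returns an empty
  selection with a warning; constant predictors are zeroed after
  standardization.
* Cox fits failing to converge in 100 iterations (including complete
  separation) raise an error with the solver's diagnostic.
* Sample pairs never co-sampled in any consensus repetition (possible
  only at very small repetition counts) get consensus 0 and a warning.
* All bootstrap, subsampling and permutation procedures are seeded;
  identical seeds give byte-identical results.

# Problem sizes used by the packaged checks

The test-suite simulations use cohort sizes of 100-200 samples, 100-200
consensus repetitions, 15-30 bootstrap refits and 20-seed repetitions;
the acceptance script runs the full default cohort (192 samples, 1000
consensus repetitions) plus reduced-seed variants of the calibration
checks. These sizes were chosen so the whole battery is a routine
desk-scale run while keeping every Monte-Carlo bound far from its
tolerance.

# Known limitations

The data-backed reproduction of the motivating study requires its
deposited viability tables; this package ships only the synthetic
generator and the reader infrastructure (including configurable column
mapping) to consume such tables. The interaction model treats the two
drug concentrations separately rather than fitting dose-response curves,
and the per-sample interaction coefficient is noisier than the pooled one
by construction (it has no residual averaging). The multinomial
stability-selection coefficient threshold (0.35) is applied on the
standardized-predictor scale of the fit; on raw 0/1 features that scale
differs from the raw-coefficient scale by each feature's standard
deviation.
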