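---
title: "Modelling nonlinear brain-volume trajectories across adolescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonlinear brain-volume trajectories across adolescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural brain volumes change nonlinearly between late childhood and late
adolescence, and individuals differ both in the *pace* of that change and in
its *timing* — the age at which a region changes fastest. Quantifying those
individual differences needs dense longitudinal data (many visits per
subject) and models that separate within-subject trajectories from
between-subject variability. `braintraj` implements the full modelling chain
for accelerated longitudinal volume data: data-driven shape discovery with
penalized-smooth mixed models (GAMMs), parametric quantification with
nonlinear mixed-effects growth models (NLMMs), residual-based quality
control, and a simulator that produces cohorts with known ground truth so
every stage can be validated.

## Structural growth models

Three candidate functions describe a region's volume $y$ as a function of
age $x$, each fitted as a mixed model with subject-level random effects on
its parameters:

* **Four-parameter logistic** (S-shaped change):
  $y = A_{lower} + \dfrac{A_{upper}-A_{lower}}{1+(x/\mathrm{Inflection})^{-\mathrm{Hill}}} + \varepsilon.$
  $A_{lower}$ and $A_{upper}$ are limiting volumes (mm³), the inflection
  (years) is the age at which the curve crosses the midpoint of its
  asymptotes, and the hill (dimensionless) sets steepness and direction
  (positive: growth towards $A_{upper}$; negative: decline towards
  $A_{lower}$). The parameterization is the power-of-$(x/\mathrm{Inflection})$
  form, not the logit-in-$x$ variant — the two differ off the log-age scale.
* **Logarithmic** (decelerating change): $y = a + b\,\ln x + \varepsilon$;
  natural log ($a$ is the value at age 1 year and is not interpreted).
* **Linear**: $y = a + bx + \varepsilon$.

Two caveats are worth making explicit. First, the logistic has an exact
identifiability symmetry: swapping the asymptotes while negating the hill
leaves the curve unchanged. Fits resolve it deterministically through
initialization (below), so repeated fits with the same seed agree exactly.
Second, the inflection parameter is the *midpoint* of $y$ between the
asymptotes; on the linear-age scale the age of literal maximum $|dy/dx|$ is
slightly offset for this parameterization. The package estimates and
reports the parameter itself, which is conventionally read as the age of
most rapid change.

Covariates can shift any structural parameter (at most 8 entries for the
logistic, 4 for the others). Sex is coded with female as the reference, so
a sex coefficient is the additive male shift on that parameter. In-scanner
motion is indexed by the mean Euler number of the reconstructed cortical
surfaces (more negative = worse quality) and enters raw, as the
subject-mean across visits, on the slope-like parameter (hill or $b$):
the covariate model is subject-level, so a per-visit quality index must be
collapsed; the mean is the obvious summary and is used on both the
generating and the fitting side.

## Estimation

`fit_nlmm()` maximizes the marginal likelihood with additive Gaussian
random effects (diagonal covariance; any subset of parameters, default
all) and a constant additive residual error.

* **Linear and logarithmic models** are linear in their parameters, so the
  marginal likelihood is Gaussian and closed-form. Fixed effects are
  profiled out by GLS and the variance parameters optimized on the log
  scale. This path is exact — it must and does agree with an independent
  linear-mixed-model solver to well under 0.1% (tested against `lme4`).
* **The logistic** is estimated in two stages. A stochastic-approximation
  EM (SAEM) chain — Metropolis sampling of individual parameters, an
  annealed exploration phase and a $1/k$-smoothing phase, closed-form
  M-steps — provides a robust global search. A quasi-Newton polish of the
  Gauss-Newton Laplace marginal likelihood (penalized Gauss-Newton inner
  solves with analytic Jacobians) then tightens the estimate
  deterministically. Two independent chains are run by default
  (`n_starts = 2`; chain 1 starts from a pooled least-squares refinement of
  the data-driven initialization, later chains from the raw
  initialization), and the run with the best Laplace likelihood is kept —
  the four-parameter logistic has a flat ridge (asymptotes drifting apart
  while the hill flattens) that a single chain occasionally settles on.

Initialization is data-driven and deterministic: $A_{upper}$ = maximum
observed volume, $A_{lower}$ = minimum, inflection = median age, and the
hill sign from the Spearman correlation of age and volume — which resolves
the swap symmetry once and for all.

Standard errors come from the numeric observed information of the Laplace
objective (GLS covariance on the exact path); a singular information matrix
is reported as SEs-unavailable rather than silently dropped. Per-parameter
precision is summarized as CV% $= 100\,|SE/\hat\theta|$ with the
conventional strict gate CV < 20%.

The log-likelihood used for AIC and BIC is importance-sampled at the final
estimates (Gaussian proposal centred at each subject's conditional mode
with inflated Laplace covariance, 1000 draws per subject by default,
seeded); the Laplace value is reported alongside. On the exact path the two
coincide. AIC $= -2\ell + 2k$ and BIC $= -2\ell + k\ln(n_{subjects})$ with
$k$ = fixed effects + random-effect variances + residual variance; the
subject count is the effective sample size for between-subject parameters.
Criteria are comparable only across models fitted to the same response on
the same scale — which is why global measures are rescaled (divided by 100)
*before* any model is fitted, with the divisor recorded in the dataset
metadata. Whether eTIV should enter raw or rescaled is not fixed by
convention; the package keeps eTIV on its raw scale and the metadata makes
the response scale explicit in every report.

Individual growth parameters are the **conditional modes** of the random
effects given the population fit (empirical Bayes), labelled as such —
conditional means would differ slightly for the nonlinear model. Subjects
with few observations shrink towards their covariate-adjusted population
values; the derived scalar of interest is the inflection point (logistic)
or the rate $b$ (otherwise). Timing estimates outside the observed age
range are flagged together with the subject's observation count, since
extrapolated timing mostly reflects sparse early- or late-clustered visits.

## Shape discovery (GAMMs)

`fit_gamm()` fits
$y = \beta_0 + \beta_1\,\mathrm{sex} + s_1(\mathrm{age}) + s_2(\mathrm{age})\,\mathrm{sex} + u + \varepsilon$
by REML via `mgcv`: a k = 7 thin-plate age smooth for the reference sex
(female), an ordered-factor *difference smooth* for the male deviation
(centred, own smoothing parameter), the male−female intercept contrast, and
a subject random intercept as a penalized ridge term (optionally a random
slope). k = 7 leaves up to 6 effective degrees of freedom per smooth —
ample for trajectories this smooth, checked by the edf staying well below
the bound.

The effective degrees of freedom (edf) of the age smooth classifies the
trajectory: edf within 0.1 of 1 is called linear (a REML fit never lands on
1.0 exactly), up to 2 weakly nonlinear, above 2 nonlinear. Smooth-term
significance is the Wald-type F test the REML fit reports; its reference
df is the test df reported by `mgcv` (conventions for "reference df" vary
between softwares — both fields are reported rather than forced equal).
Calibration is verified behaviourally: under a generator with no sex
difference, the difference-smooth p-values are checked against uniformity
across seeds.

The NLMM stage is run for *all* regions regardless of the shape call — a
region can be classified nonlinear by edf while a linear function still
wins the information-criterion comparison among the three parametric
candidates (the two statements answer different questions) — and the shape
call is recorded alongside so the conditional logic remains visible.

## Quality control

`detect_outliers()` fits the adjustment GAMM (age smooth + sex + age-by-sex
+ random intercept) and takes residuals against the *population-level*
prediction, i.e. with the random intercept excluded. This choice matters:
residuals that include the subject intercept absorb exactly the
between-subject shifts the screen is meant to catch. Two rules at a common
threshold (default 2 SD):

* between-subject: subject-mean residuals at least 2 across-subject SDs
  from the mean of subject means (the alternative convention —
  standardizing by the pooled residual SD — is stricter for well-sampled
  subjects; the across-subject SD of subject means is used here and
  documented);
* within-subject: observations at least 2 SDs from their own subject's mean
  residual, with the SD pooled across subjects from subject-centred
  residuals (a per-subject SD with ~8 visits is too noisy to calibrate;
  pooling gives a false-flag rate near the nominal $2\Phi(-2) \approx
  4.6\%$, which the tests verify). Single-visit subjects are skipped by
  this rule and counted.

Flags mark records; exclusion is a separate, explicit mode — the analogous
real-data decision is human-judged, and the tool is honest about that gap.

## The synthetic cohort

`design_config()` emulates a 12-wave single-cohort accelerated longitudinal
design: 90 subjects, baseline ages uniform on [7.60, 12.90] years, visits
at offsets 0, 0.5, …, 4.5, 5.5, 8.5 years, each non-baseline visit
independently missing with probability 0.31 (baseline is never dropped — a
subject must enter the study to exist; the resulting mean of ~8.6 retained
scans per subject sits at the top of the observed-range target of ~8.3),
timing jitter SD 0.05 y (visits are never exactly on schedule; small enough
not to distort design statistics), and a 53:37 female:male split. Euler
numbers are drawn from a Normal(−150, 80) truncated above at zero;
scanner-software versions form five ordinal epochs keyed to calendar
position (all subjects share calendar time in a single cohort, so the epoch
is a function of the wave).

`preset()` turns a region's published group-level estimates into generating
truth. The study-level variance components are not published anywhere, so
the presets adopt a stated convention: between-subject SD = 5% of each
parameter's absolute value, residual SD = 2% of the asymptote midpoint
(logistic) or of the mid-age fitted value (otherwise) — values a
volumetrics practitioner would call realistic for FreeSurfer-derived
regional volumes, chosen once and not revisited. Random effects are
additive Gaussian on the natural parameter scale with diagonal covariance,
mirroring the estimator's default. Draws that would make the logistic
undefined (inflection ≤ 0) are resampled, counted and warned about. By
default a preset generates *without* covariate effects, so the published
group parameters are the unconditional truth for every subject;
`effects = "paper"` switches on the published sex shifts and motion
coefficient.

What the generator does **not** emulate: segmentation error that varies
with age or motion, scanner software effects on volume (software is a null
covariate by construction), correlated random effects, heteroscedastic
residuals, and attrition that depends on the subject (missingness is
independent across visits). Passing recovery tests therefore show that the
estimation machinery is correct under the stated generative assumptions —
not that real cortical volumes obey a four-parameter logistic.

## Numerical choices and degenerate inputs

* Inner conditional-mode solves: damped (Levenberg-style) penalized
  Gauss-Newton, relative tolerance 1e-10, warm-started across outer
  iterations; a warm start that ends worse than the unperturbed origin is
  redone from zero, keeping the objective effectively start-independent.
* Outer polish: BFGS with forward-difference gradients (step 1e-5 on each
  parameter's own scale), relative tolerance 1e-8, parameter scaling from
  the SAEM estimates.
* SAEM: 300 exploration + 200 smoothing iterations by default, one
  independence kernel plus two componentwise random-walk passes per
  iteration with acceptance-adapted step sizes, and a simulated-annealing
  floor (0.95 per iteration) that keeps variances from collapsing during
  exploration.
* Model selection: BIC decides; when AIC disagrees, the disagreement is
  recorded and BIC wins (a deterministic tie-break is required for
  automation, and BIC's consistency suits choosing among function
  families). Forward-stepwise covariate selection accepts the single best
  addition per round while BIC strictly improves — greedy one-entry-at-a-
  time, which is a documented choice where a block rule would also be
  defensible.
* Stepwise covariate structures are selected once (conventionally on
  cortical grey matter) and transferred to other regions by default, with a
  flag to re-tune per region.
* The diagnostics "clustering index" is the between-cluster share of
  variance from a 2-means split of the individual predictions —
  threshold-free, a numeric stand-in for the banding visible in diagnostic
  plots of poorly fitting models.
* No multiple-testing correction is applied anywhere; all p-values are raw
  and reported as such.

## Problem sizes used by the tests

The test suite validates recovery at the study's own scale — n = 90
subjects, the 12-wave design, five replicate cohorts per recovery target
and ten per selection consistency check — with estimation settings (250
exploration + 150 smoothing SAEM iterations, 400 importance-sampling draws)
chosen as the package's standard quick-analysis profile; the package
defaults are somewhat heavier. Calibration checks (QC false-flag rates,
difference-smooth null uniformity) pool 15–20 replicate cohorts.

## Known limitations

* Timing parameters near the edge of the sampled age range (e.g. a male
  inflection shifted into the late teens when data end at ~21.5 y) are
  weakly identified; their likelihood is asymmetric and estimates skew
  towards the data-sparse side by a few percent.
* The hill's random-effect variance is only weakly identified at ~8 visits
  per subject; its estimate is unstable across replicates even when the
  fixed effects recover well.
* The Laplace objective is the Gauss-Newton variant (the residual-weighted
  second-derivative term is dropped); with small residual noise the
  difference is negligible, and the importance-sampled likelihood provides
  the unbiased check.
* Conditional modes, not means, are reported as individual estimates.
* The exact-path models assume the response is on a numerically reasonable
  scale; global measures should be rescaled (÷100) at ingest, as
  `rescale_volumes()` enforces and records.
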