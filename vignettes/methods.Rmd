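---
title: "Methods: ex-Gaussian reaction-time predictors of cardiovascular stress responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex-Gaussian reaction-time predictors of cardiovascular stress responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exgstress)
```

## The scientific question

Exaggerated or sustained cardiovascular (CV) responses to acute mental
stress predict poor cardiovascular outcomes. A separate line of work treats
reaction-time (RT) behaviour — in particular *intraindividual RT
variability* — as a proxy for neural efficiency. `exgstress` implements the
analysis chain that connects the two: per-participant ex-Gaussian RT
parameters are used as predictors of blood-pressure, heart-rate and
heart-rate-variability reactivity to, and recovery from, a laboratory
stressor, with robust regression carrying the inferential load.

The chain is: trial-level RT cleaning → maximum-likelihood ex-Gaussian
fitting → beat-level cardiovascular reduction to five protocol periods →
reactivity/recovery change scores → repeated-measures ANOVA (manipulation
check) → SMDM robust regressions adjusted for covariates. A seeded
synthetic-cohort generator reproduces the statistical structure of such a
study so that every stage can be validated against known ground truth —
the original human data are not publicly deposited, so no part of this
package depends on them.

## The ex-Gaussian RT model

A reaction time is modelled as the sum of a Gaussian component
$N(\mu, \sigma^2)$ and an independent exponential component with mean
$\tau$ (all in ms):

$$f(x) = \frac{1}{\tau}\exp\!\left(\frac{\sigma^2}{2\tau^2}
  - \frac{x-\mu}{\tau}\right)
  \Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right),$$

with mean $\mu + \tau$, variance $\sigma^2 + \tau^2$ and skewness
$2\tau^3/(\sigma^2+\tau^2)^{3/2}$. $\mu$ and $\sigma$ describe the bulk of
responses; $\tau$ carries the long right tail of infrequent slow responses
and is the conventional index of intraindividual RT variability.

`fit_exgauss()` maximises the log-likelihood over
$(\mu, \log\sigma, \log\tau)$, which enforces positivity without
constraints. The density is evaluated in log space
(`pnorm(..., log.p = TRUE)`) so small $\tau$ cannot overflow. Starting
values come from the method of moments with the skewness-based
$\tau_0 = s\,(\text{skew}/2)^{1/3}$ clipped to $[0.05s, 0.95s]$: samples
with negligible or negative skewness would otherwise produce a degenerate
start. The optimiser is `nlminb` with a relative tolerance of `1e-8`; a fit
reports `converged = FALSE` rather than silently returning a doubtful
optimum, and the moment-based starting log-likelihood is stored so tests
can assert the optimiser never degrades it.

## Trial cleaning

`filter_trials()` applies three filters in a fixed order: (1) incorrect
trials are dropped — error-trial RTs reflect different cognitive processing;
(2) among correct trials, RTs *strictly* below 200 ms are dropped as
anticipatory (an RT of exactly 200 ms is kept); (3) RTs above the survivor
mean plus four survivor SDs (sample SD, $n-1$) are dropped, and the rule is
re-applied until no survivor exceeds the bound. The iteration matters: a
single pass can leave the reduced set violating its own 4-SD bound. Only
the upper tail is trimmed; slow-but-valid responses are exactly what the
ex-Gaussian $\tau$ is meant to absorb, which is why no tighter trimming or
log-transformation is applied. Participants with fewer than 20 retained
trials (configurable) are flagged unusable for fitting; the choice of 20 is
a pragmatic floor for a 3-parameter ML fit, not an empirical constant.

## Cardiovascular reduction

Beat-level data are reduced per period with half-open time windows
$[\text{start}, \text{end})$ in minutes from protocol start; the half-open
convention makes adjacent windows partition the timeline deterministically.
The five periods are: baseline (the last 5 min of a 30-min seated rest),
the 5-min stress task, and three 5-min recovery windows 15–20, 40–45 and
70–75 min post-stress. Heart rate converts from the mean N-N interval
(HR = 60000 / N-N ms); vagal influence is summarised by r-MSSD, the root
mean square of successive N-N differences.

Reactivity is stress minus baseline; each recovery score is the
recovery-period value minus baseline, so larger residual deviations mean
slower return to baseline (impaired recovery). Change-score distributions
are screened by a reproducible analogue of visual inspection: flags at
$|z| > 4$, report-only, never mutating the data. HRV is log-transformed for
the repeated-measures ANOVA (its distribution is right-skewed) but enters
the robust regressions untransformed — robust weighting already tames
influential observations, and coefficients stay in interpretable ms units.

## Repeated-measures ANOVA with Greenhouse-Geisser correction

The manipulation check is a one-way within-subject ANOVA across the five
periods: $F = MS_\text{period}/MS_{\text{period}\times\text{subject}}$ with
$(k-1)$ and $(k-1)(n-1)$ df. Because period covariances in such protocols
rarely satisfy sphericity, both df are multiplied by the Greenhouse-Geisser
$\hat\epsilon = (\sum\lambda_i)^2 / ((k-1)\sum\lambda_i^2)$, computed from
the eigenvalues of the double-centred period covariance matrix and bounded
in $[1/(k-1), 1]$. The sample (1959) epsilon is used rather than
Huynh-Feldt, applied whenever $k > 2$; with $k = 2$ a single contrast
cannot violate sphericity and $\epsilon = 1$. Analysis is complete-case:
a participant missing any period is excluded from that outcome's ANOVA.
Post-hoc period-vs-baseline contrasts are uncorrected paired t-tests and
are labelled descriptive.

## The SMDM robust regression estimator

The regressions of each change score on each RT parameter use an MM-type
estimator with four stages (S, M, D, M), combining a 50% breakdown point
with 95% asymptotic efficiency under normal errors — observations with
large residuals are downweighted, not discarded.

* **S**: an initial high-breakdown S-estimate minimises an M-scale of the
  residuals, $\;\sum_i \rho_{c_S}(r_i/s)/(n-p) = 1/2$, with the
  standardised bisquare $\rho$ and $c_S = 1.5476$. The minimisation uses a
  seeded fast-S search: 500 random $p$-subsets, each refined by two
  reweighting steps with a few scale iterations, the best 5 candidates
  refined to convergence. The subsample search is the only stochastic
  ingredient of the whole regression stage, and it is fully determined by
  `smdm_config(seed = )`.
* **M**: coefficients are re-estimated by IRWLS at the fixed S-scale with
  the bisquare $\psi_{c_M}$, $c_M = 4.685$ (95% normal efficiency).
* **D**: the residual scale is re-estimated by the design-adaptive
  equation $\mathrm{mean}_i\,[\psi(u_i)\,u_i] = E_\Phi[\psi(Z)Z]$ with
  $u_i = r_i/(\tau_i\,\hat\sigma)$ and $\tau_i = \sqrt{1-h_i}$, $h_i$ the
  robustness-weighted leverage. This leverage-aware scale improves the
  calibration of Wald-type inference relative to the raw S-scale.
* **M**: a final IRWLS pass for the coefficients at the D-scale.

The bisquare family is used in all stages: its tuning constants for 50%
breakdown and 95% efficiency are standard and closed-form testable; the
family is an explicit field of `smdm_config()` so the choice is visible in
every fit. Standard errors use the M-estimator sandwich at the D-scale with
Huber's small-sample correction
$K = 1 + \tfrac{p}{n}\mathrm{var}(\psi')/\overline{\psi'}^2$, and p-values
use the standard normal reference, the common convention in robust
regression reporting. $R^2$ is computed from the *unweighted, unscaled*
residuals at the robust coefficients, $1 - \sum r_i^2/\sum(y_i-\bar y)^2$,
clipped below at zero with a logged note — on contaminated data a robust
fit can have a larger raw SSE than the grand mean, and a negative "variance
explained" is not meaningful for reporting. Degenerate zero-residual
problems are handled by flooring the scale at $10^{-10}\,\mathrm{sd}(y)$,
which keeps all weights defined and returns the exact solution with unit
weights.

`ols_fit()` provides the classical least-squares companion used as the
efficiency baseline and as the oracle in contamination experiments. On
clean normal data the two agree (tested against each other and against an
independent MM implementation); under 20% gross outliers the OLS slope
breaks while the SMDM slope stays on target.

Performance note: the S/M iteration kernels are implemented in compiled
code (Rcpp/RcppArmadillo), which keeps a full 48-cell analysis of a
2000-participant cohort under two minutes on one core; all statistical
logic, seeding and reporting live in R.

## Covariate coding and the 48-cell report

Each regression cell (RT predictor × outcome × response) adjusts for the
baseline value of that cardiovascular outcome, age, sex, BMI, employment
grade (two indicators against the reference level "higher"), the number of
correct Stroop trials (a cognitive-ability marker), and dichotomised task
difficulty and involvement ratings — 11 design columns including the
intercept. The 7-point ratings are typically bimodal, hence the median
split: "high" is strictly above the sample median and ties go low, a
deterministic rule. One pooled split per rating type is used. Missing
fields drop a participant from the affected model only (listwise per
model); a participant missing a recovery period keeps contributing to every
other response. Report cells are annotated `*` for $p \le .05$ and `**` for
$p \le .09$ (the trend band).

## The synthetic cohort generator

`cohort_config()` defaults describe the study conditions the package
emulates: 262 participants; between-subject ex-Gaussian parameters drawn
lognormally (positivity) and moment-matched so the configured means/SDs are
exact, with population means $\mu = 1944.21$, $\sigma = 300$,
$\tau = 400$ ms — population mean RT $\mu + \tau = 2344.21$ ms; a 5-min
Stroop task at 0.5 s stimulus overhead, so trial counts vary with each
participant's speed (~105 trials, ~68 usable after cleaning); 63.64%
correct trials (i.i.d. Bernoulli — only the mean rate is identified by the
emulated study); 2% injected sub-200 ms anticipatory responses to exercise
the cleaning filter; baseline CV populations SBP 126.88 ± 16.1 mmHg,
DBP 74.61 ± 10.3, HR 67.15 ± 8.8 bpm, r-MSSD 23.65 ± 13.5 ms (lognormal
for positivity); period shifts equal to the emulated cohort-level period
means (e.g. SBP reactivity +31.84 mmHg); and linear effects of the centred
RT parameters injected into each change score — by default through $\tau$
only, e.g. −0.009 mmHg/ms on SBP reactivity, so the end-to-end pipeline has
detectable structure.

Choices the emulated study does not pin down, fixed here once: between-
subject SDs of the RT parameters (250, 100, 250 ms — heterogeneity
comparable to the parameter means, typical of older-adult choice-RT data);
change-score residual SDs (12/9 mmHg SBP reactivity/recovery, 7/5 DBP,
6/4 bpm HR, 8/6 ms HRV — consistent with observed period-level SDs under
moderate baseline-stress correlation); bimodal 7-point rating
distributions. N-N series are i.i.d. jitter around the period mean with
jitter SD = target r-MSSD / $\sqrt 2$ (successive differences of i.i.d.
noise have twice the variance), because only a successive-difference
statistic is consumed downstream; no autocorrelation, respiratory coupling
or circadian structure is modelled. Period values are floored at
physiological minima (e.g. r-MSSD at 1 ms), so configured deltas are exact
only away from the floor.

What passing tests on this generator do **not** show about real data:
real RT sequences are autocorrelated and non-stationary (fatigue,
strategy); real beat series have respiratory sinus arrhythmia and artefacts
that vendor preprocessing must remove; real covariates are correlated with
the predictors. The generator validates the *statistical machinery*, not
the field protocol.

## Numerical choices and problem sizes

Validation uses fixed problem sizes chosen to give stable Monte-Carlo
estimates: 2000 replicates at $n = 500$ for the normal-error efficiency of
the SMDM slope (OLS-to-SMDM variance ratio ≈ 0.95); 100 seeds × 5000 draws
for ex-Gaussian recovery (median relative errors well under 5%); 200
replicates for the 20%-contamination experiment; cohorts of 500 (null,
type-I error over the 48 cells) and 2000 (effect recovery) for the
end-to-end checks. `scripts/acceptance.R` recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

* **Errors-in-variables attenuation.** The regressions use *fitted*
  $\hat\tau$ from ~68 trials per participant; the resulting measurement
  error (SE ~ 100 ms, heteroscedastic — roughly proportional to the
  participant's $\tau$) attenuates the recovered coefficient by a
  seed-dependent factor of roughly 0.5–0.9, and robust downweighting of the
  most extreme $\hat\tau$ values compounds it. Regressions on the *true*
  parameters recover injected coefficients within Monte-Carlo error (this
  is tested), so the attenuation is a property of the design — a 5-min task
  bounds the achievable reliability of $\hat\tau$ — not of the estimator.
  Any study with this protocol, including the one emulated, reports
  attenuated coefficients.
* The D-stage uses the first-order leverage correction
  $\tau_i = \sqrt{1-h_i}$; the exact small-sample expansion of the
  design-adaptive scale is not reproduced.
* p-values use large-sample normal/F references; no multiple-testing
  correction is applied across the 48 cells (matching the reporting style
  the package emulates — interpret the cell-level trends accordingly).
* Frequency-domain HRV, respiration adjustment and vendor signal
  preprocessing are out of scope.
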