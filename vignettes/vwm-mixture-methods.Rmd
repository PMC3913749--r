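---
title: "Mixture modelling of continuous-report working memory errors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modelling of continuous-report working memory errors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwmix)
```

## The task and its data

In a dual-feature continuous-report (delayed-estimation) task, an observer
memorizes an array of one or three coloured, oriented bars; after a retention
interval, one location is probed and the observer reproduces both the
orientation and the colour of the item that was there, by adjusting the probe
continuously. Each trial therefore yields, per feature dimension, an angular
response $\hat\theta$ on a circular feature space, to be compared with the
target value $\theta$ and with the feature values $\varphi_1 \dots \varphi_m$
of the $m$ unprobed (nontarget) items ($m = 0$ at load 1, $m = 2$ at load 3).

All angles live on the half-open interval $(-\pi, \pi]$. The convention is
fixed in `wrap_angle()`: the boundary $-\pi$ maps to $+\pi$. Any half-open
convention would do; what matters is that wrapping is idempotent and every
stored angle satisfies the same invariant. Orientation is a
180°-periodic feature, so `orientation_to_angle()` doubles it onto the full
circle (90° becomes $\pi$) before any circular statistics are applied; hue is
already a full circular variable.

## The response model

Errors are modelled as a three-component mixture (the standard
target/nontarget/uniform decomposition used throughout this literature):

$$
p(\hat\theta) \;=\; \alpha\,\phi_\kappa(\hat\theta - \theta)
\;+\; \beta\,\frac{1}{m}\sum_{i=1}^{m}\phi_\kappa(\hat\theta - \varphi_i)
\;+\; \gamma\,\frac{1}{2\pi},
$$

where $\phi_\kappa$ is the von Mises density with mean zero and concentration
$\kappa$, $\alpha$ is the probability of reporting the target, $\beta$ the
probability of misreporting one of the nontargets (a misbinding or "swap"
response), and $\gamma = 1 - \alpha - \beta$ the probability of a uniform
(guessing) response. One $\kappa$ is shared between the target and nontarget
components — a deliberate fidelity choice: a swap response is assumed to be
produced by the same noisy recall process as a correct one, only anchored to
the wrong item. $\kappa$ is reported to users as the more familiar circular
standard deviation $\sigma = \sqrt{-2\ln A_1(\kappa)}$ with
$A_1 = I_1/I_0$ (`kappa_to_sd()`).

Two structural facts matter for fitting:

* at load 1 there are no nontargets, so $\beta \equiv 0$ and the model is a
  two-component (target + uniform) mixture; the code enforces this exactly
  rather than estimating a near-zero $\beta$;
* as $\kappa \to 0$ the target component itself becomes uniform, so $\alpha$
  and $\gamma$ are no longer separately identifiable. Tests in that regime
  assert only the recovery of $\alpha + \gamma$.

## Maximum likelihood by multi-start EM

`fit_vm_mixture()` maximizes the likelihood by expectation–maximization.
The E-step computes, per trial, the posterior probability that the response
came from the target, each nontarget, or the uniform component
(`responsibilities()`). The M-step updates the weights as mean
responsibilities. Because the component means are fixed (the deviations are
taken about zero), the $\kappa$ update solves
$A_1(\kappa) = \bar c$ where $\bar c$ is the responsibility-weighted mean
*cosine* of the deviations — not the resultant length, which would be the
update if a free mean direction were being estimated alongside. A
nonpositive $\bar c$ collapses to $\kappa = 0$. The inverse of $A_1$ is
computed by Newton refinement of the classical piecewise rational seed, to
a relative tolerance of $10^{-10}$, with exponentially scaled Bessel
functions so that nothing overflows at large $\kappa$.

EM settings (all user-visible arguments with defaults):

* **Starts.** A deterministic grid $\alpha_0 \in \{0.3, 0.6, 0.9\} \times
  \beta_0 \in \{0, 0.2\} \times \kappa_0 \in \{1, 4, 16\}$ (18 starts;
  9 at load 1 where $\beta_0 = 0$). The cell $\alpha_0 = 0.9,
  \beta_0 = 0.2$ would leave no room for $\gamma$, so $\beta_0$ is clipped
  to half the remaining mass there. Extra random starts are drawn only if
  more are requested.
* **Convergence.** Stop when the log-likelihood improves by less than
  `tol = 1e-6` nats; `max_iter = 1e4` per start.
* **Caps.** $\kappa$ is capped at $10^4$ ($\sigma \approx 0.01$ rad) to
  prevent degenerate spikes on pathological samples.
* **Ties.** Among equally likely starts the lowest start index wins, so
  fits are deterministic.

Within every start the log-likelihood sequence is non-decreasing (an exact
EM property; the test suite asserts it at every iteration), and on random
data sets the attained maximum is checked against an exhaustive grid search
over $(\alpha, \beta)$ at 0.05 resolution crossed with 30 log-spaced
$\kappa$ values. The inner loop is compiled (Rcpp): a 175-trial fit with the
full start grid takes a few milliseconds, which is what makes the
replicated whole-cohort simulations below affordable.

Fewer than 20 trials triggers a warning rather than an error: the smallest
cell in the emulated design has 25 trials, and a hard floor would make the
function needlessly brittle on user data.

## Recall precision and its chance correction

Model-free recall fidelity is measured as the reciprocal of the circular
standard deviation of the recall errors
($\sqrt{-2 \ln \bar R}$ on the wrapped errors), minus the value a random
responder would score. The chance level is the Monte-Carlo expectation of
$1/\mathrm{SD}$ over uniform samples of the *same size* (default $10^4$
replicates): for finite $n$ a uniform responder's resultant does not vanish,
so the uncorrected reciprocal is biased up, and the bias depends only on
$n$. `fit_cohort()` therefore caches the chance level per unique trial
count. After correction, zero means chance performance.

Two degenerate cases are handled explicitly: a vanishing resultant returns
the documented `Inf` sentinel from `circ_sd()` (whose reciprocal, 0, is the
correct precision for complete dispersion), and a zero-dispersion sample
(all errors identical, infinite raw precision) is reported as a large
finite cap of 1000 per radian with a `saturated` flag, so that cohort
regressions stay defined; a value that extreme is removed by the outlier
screen in any case.

## Nonparametric validation of misreporting

If responses are generated only from the target and/or at random, their
deviations from nontarget values are uniform on the circle, and the RMS
deviation converges to $\pi/\sqrt{3} \approx 1.814$ rad. Genuine swap
responses pull the RMS below that value. `nontarget_rms_deviation()`
computes the statistic per subject; `chance_rms_test()` runs the one-sample
$t$ test of the subject values against $\pi/\sqrt 3$. This check needs no
distributional assumptions and is the model-free counterpart of $\beta$.

## Joint distribution of errors across feature dimensions

Two cross-feature analyses are provided. First,
`error_magnitude_correlation()` Pearson-correlates the absolute wrapped
recall errors of the two dimensions across trials ("error magnitude" is
taken literally; circular–circular association measures were rejected as a
change of estimand). Second, for misreports,
`nontarget_dev_correlation()` correlates the absolute deviations of the
response from each nontarget, *paired by item* across dimensions — the
nontargets correspond across dimensions because they are features of the
same array objects. If swaps strike the same item in both dimensions, both
deviations are small together and the correlation is positive.

The benchmark for "swaps always co-occur" is
`expected_cooccurrence_correlation()`: a Monte-Carlo simulation in which a
single shared uniform draw per trial decides each dimension's component
(dimension $d$ misreports iff $u < \beta_d$, reports the target iff
$u < \beta_d + \alpha_d$, otherwise guesses), so misreports co-occur at
rate $\min(\beta_1, \beta_2)$ — the maximal coupling consistent with the
fitted marginal rates — and co-occurring swaps share the nontarget index.
Von Mises response noise uses each dimension's fitted $\kappa$. The exact
coupling scheme is underdetermined by the verbal description of the
benchmark in the source literature; maximal coupling is the declared
design choice here, since it gives the extreme point of the "occurred
together" hypothesis.

## The synthetic cohort generator

No raw data from the original study are available, so the generator is a
first-class module that emulates the study design and the statistical
structure the analysis assumes:

* 60 subjects, ages spread evenly over 19–77 years;
* two between-subject exposure groups (2 s vs 200 ms), assigned alternately
  along the age ranking so the two age distributions match;
* 25 low-load and 175 high-load trials per subject, each trial probing both
  dimensions; feature values i.i.d. uniform on the circle, target index
  uniform;
* per-subject mixture parameters drawn from linear age maps plus
  between-subject Gaussian noise.

The default age maps (intercept at age 19, slope per year, high load):

| parameter | orientation | colour | at 19 → 77 |
|---|---|---|---|
| $\sigma$ (rad) | $0.38 + 0.0045\,a$ | $0.42 + 0.004\,a$ | 0.38 → 0.64 / 0.42 → 0.65 |
| $\beta$ | $0.04 + 0.0026\,a$ | $0.01 + 0.0006\,a$ | 4% → 19% / 1% → 4.5% |
| $\gamma$ | 0.08 (flat) | 0.08 (flat) | — |

with low-load $\sigma$ from 0.28/0.30 rising by 0.0025 per year,
$\beta \equiv 0$, $\gamma = 0.05$, and between-subject noise SDs of 0.13
($\sigma$), 0.02 ($\beta$), 0.03 ($\gamma$). Only the *signs* of the age
trends are constrained by the phenomenon being emulated ($\sigma$ and
$\beta$ rise with age, $\gamma$ flat); the magnitudes are free parameters
of the generator. They were chosen once, jointly, so that (a) the misreport
range spans the few-percent-to-a-fifth range typical of young vs old
observers at these loads, and (b) individual differences are resolvable at
the design's 175 high-load trials — the between-subject spread of $\sigma$
comfortably exceeds the estimator's sampling error at that trial count, so
per-subject fits regress on their generating values near the identity and
age-quartile contrasts are detectable at $n = 60$. The generator is not
re-tuned per analysis; these defaults *are* the default study conditions.

Brief (200 ms) exposure multiplies $\sigma$ by 1.25 at both loads and adds
0.05 to $\gamma$ in the high-load condition only, and leaves $\beta$
untouched — the incomplete-encoding signature. A `coupling` parameter in
$[0, 1]$ makes the two dimensions share their latent component indicator
(and nontarget index) on that fraction of trials; the default 0 encodes
independent feature memories. Education declines modestly across birth
cohorts and span scores are driven mainly by education with a weak direct
age effect, so the span–age association is largely mediated by education —
the structure the partial-correlation analysis is there to detect.

What the generator does **not** emulate: spatial positions (location is
reduced to the target/nontarget designation), the physical colour space
(hue is a plain angle), reaction times, sequential dependencies between
trials, attention lapses that vary within a session, and motor noise
distinct from memory noise. Passing tests on these cohorts therefore
validate the estimators and the inferential pipeline under the model's own
assumptions — they cannot certify behaviour on real data, whose error
distributions may deviate from the mixture in all the ways above.

## The cohort-level pipeline

* **Outlier screen** — single pass, per outcome × dimension × load cell,
  across subjects: values more than 3 SD from the cell mean are dropped and
  logged. The rule is deliberately not iterated (an iterated rule keeps
  removing points on well-behaved data); single-pass is also idempotent on
  its own output. It is applied to all per-subject outcomes, precision
  included.
* **Age regressions** — OLS of each outcome on age, per cell and (the
  headline form) on subject means across dimensions.
* **ANCOVA** — `aov` with error strata `subject/(load*dimension)` and age
  as a continuous covariate: the classical univariate repeated-measures
  partition, in which between-subject terms (age) are tested on subject
  means with df $(1, n-2)$ and within-subject terms against their own
  strata. This is equivalent to testing age on subject-mean-centered data,
  which is how the design decision was originally phrased. Terms whose sum
  of squares is zero up to rounding (e.g. a factor across whose levels the
  outcome was duplicated) report $F = 0$, $p = 1$ rather than an arbitrary
  0/0 ratio.
* **Dependent correlations** — the high-load vs low-load age–precision
  correlations share the age variable, so they are compared with the
  Hotelling–Williams $t$ on $n - 3$ df.
* **Quartiles** — subjects are split into four equal-count age groups
  (youngest $n/4$ first; remainders go to the younger groups; ties broken
  by input order), so 60 subjects split 15/15/15/15.
* **Exposure contrasts** — two-sample $t$ tests per outcome and load.
* No multiple-testing correction is applied anywhere; raw $p$ values are
  reported.

All inferential operations are calibration-tested: under null generators
their rejection rates sit at the nominal 5% within Monte-Carlo tolerance.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale of the emulated design:
grid-oracle cross-checks on 200-trial data sets, parameter recovery over
100 replicates of 500 trials, chance calibration at the design's cell sizes
(25 and 175 trials), null calibrations over 500–1000 replicates, and the
end-to-end aging-signature check over 50 independently seeded 60-subject
cohorts (a fresh generation, 240 EM fits, and full analysis per replicate).
These sizes are the package's own validation choices: large enough that
Monte-Carlo noise does not drive the assertions, small enough to run
routinely.

## Known limitations

* The mixture assumes a single shared $\kappa$ per cell and no trial-level
  variability in precision; variable-precision and hierarchical extensions
  are out of scope.
* No model comparison beyond the reported log-likelihood (no AIC/BIC).
* The chance correction conditions on the observed trial count of the
  sample at hand; no claim is made about alternative conditioning schemes.
* The co-occurrence benchmark's maximal-coupling construction is one
  defensible reading of "misreports occur together"; other couplings with
  the same marginals would give intermediate benchmarks.
* Bootstrap confidence intervals on precision are not provided.
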