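# vwmix

Analysis of **dual-feature continuous-report visual working memory**
experiments, with a synthetic aging-cohort generator for end-to-end
validation.

In a continuous-report (delayed-estimation) task, an observer memorizes an
array of coloured, oriented bars and later reproduces the orientation and
colour of one probed item on continuous circular scales. Each trial yields an
angular error rather than a binary outcome, which makes it possible to ask
*why* recall degrades — with memory load, with brief exposure, with age: is
it noisier recall of the right item, reporting the wrong item (a misbinding
or "swap" error), or outright guessing?

`vwmix` decomposes the response distribution with the standard
three-component mixture

$$
p(\hat\theta) = \alpha\,\phi_\kappa(\hat\theta-\theta)
 + \beta\,\tfrac1m\textstyle\sum_i \phi_\kappa(\hat\theta-\varphi_i)
 + \gamma\,\tfrac1{2\pi},
$$

where $\theta$ is the target feature value, $\varphi_i$ the $m$ nontarget
values, $\phi_\kappa$ the von Mises density, and $(\alpha, \beta, \gamma)$
the probabilities of target, nontarget (swap) and uniform responses, with
$\gamma = 1-\alpha-\beta$ and $\kappa$ reported as the circular SD
$\sigma = \sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$. Fitting is by multi-start
expectation–maximization with a compiled core. Around the model sit:

* circular-statistics primitives (wrapping, orientation doubling, Fisher's
  circular SD, exact von Mises sampling, κ↔σ conversion);
* chance-corrected recall precision (1/SD of error minus the Monte-Carlo
  expectation for a random responder at the same trial count);
* a nonparametric misreport check (RMS deviation of responses from
  nontarget values against the uniform expectation π/√3);
* cross-feature error-magnitude and nontarget-deviation correlations, with
  a maximal-coupling Monte-Carlo benchmark for "swaps co-occur";
* a synthetic cohort generator emulating a 60-subject, two-load
  (1 vs 3 items), two-exposure (2 s vs 200 ms) aging study design;
* the cohort pipeline: 3-SD outlier screening, age regressions,
  repeated-measures ANCOVA with age as a continuous covariate,
  Hotelling–Williams comparison of dependent correlations, age-quartile
  summaries, exposure contrasts, and (partial) correlations with memory
  span scores.

## Worked example

Simulate a default cohort, fit every subject × dimension × load cell, and
run the cohort analysis:

```r
library(vwmix)

co  <- generate_cohort(cohort_spec(seed = 1))
est <- fit_cohort(co$trials, co$subjects, seed = 2)
rep <- analyze_cohort(est)
rep
#> <vwm_report>
#>   age-precision r: high load -0.618, low load -0.412 (Williams t(57)=-1.61, p=0.112)
#>   nontarget RMS deviation: 1.785 rad vs chance 1.814 (t(59)=-6.82, p=5.35e-09)
#>   outliers removed: 0.67% of estimates
rep$subject_age_trends
#>          outcome         slope          r            p
#> 1  precision_low -0.0220466682 -0.4123407 1.061255e-03
#> 2 precision_high -0.0087744735 -0.6184505 1.396041e-07
#> 3     sigma_high  0.0051586964  0.5842617 9.538693e-07
#> 4      beta_high  0.0015298071  0.6174522 1.481437e-07
#> 5     gamma_high  0.0003966943  0.1215927 3.547160e-01
```

Reading: chance-corrected precision falls with age, more steeply when three
items must be held than one; the fall decomposes into rising recall noise
(σ) and rising misreport rate (β), while the guessing rate (γ) stays flat —
and the misreport rise is corroborated model-free by the nontarget RMS
deviation sitting significantly below the chance value π/√3 ≈ 1.814 rad.

Single-cell fitting is just as direct:

```r
tt <- trials_for_cell(co$trials, "S001", load = 3, dimension = "orientation")
fit_vm_mixture(tt)
#> <mixture_fit> n=175 m=2  alpha=0.930 beta=0.021 gamma=0.049 kappa=30.91 sigma=0.181  logLik=-7.12  converged (17 iter, 18 starts)
```

The numbered scripts under `analysis/` run the same workflow as a
file-based pipeline (simulate → fit → analyze → figures), writing CSV
tables and a manifest under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1
Rscript analysis/02_fit_mixture.R 1
Rscript analysis/03_cohort_analysis.R
Rscript analysis/04_figures.R
```

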