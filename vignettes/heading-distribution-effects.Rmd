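---
title: "Modelling heading-distribution effects on heading perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heading-distribution effects on heading perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Observers judge their direction of self-motion (heading) from optic flow
with remarkable precision, yet their reports carry systematic biases.
Two are central here:

* **Center bias.** Perceived headings (PH) are compressed toward the
  ego-centric straight-ahead direction (0°). Fitting PH as a linear
  function of the actual heading (AH), `PH = s·AH + b`, gives slopes `s`
  well below 1 (empirically around 0.75–0.86 for headings within ±33°).
* **Central tendency.** In many perceptual domains (duration, length,
  color), current estimates are additionally attracted toward the mean of
  the *distribution* of recently experienced stimuli. Whether heading
  perception shows this attraction is the question the designs in this
  package were built to answer.

A third, finer-grained history effect is **serial dependence**: the pull
(attractive) or push (repulsive) exerted by the single previous trial's
stimulus on the current estimate.

This package provides (i) the six block designs of a three-experiment
heading-estimation study, (ii) a synthetic observer that generates trial
tables with any mixture of these effects, (iii) a grid-based Bayesian
ideal observer formalizing the central-tendency account, and (iv) the
full statistical pipeline used to detect the effects.

## The Bayesian ideal observer

For a noisy internal measurement $M_i$ of the true heading $X$, the
observer's posterior over candidate headings is

$$
p(X \mid M_i) = \frac{p(M_i \mid X)\,
p_{\mathrm{ego}}(X \mid \theta_{\mathrm{ego}})\,
p_{\mathrm{dis}}(X \mid \theta_{\mathrm{dis}})}
{\sum_j p(M_i \mid X_j)\,
p_{\mathrm{ego}}(X_j \mid \theta_{\mathrm{ego}})\,
p_{\mathrm{dis}}(X_j \mid \theta_{\mathrm{dis}})},
$$

the product of a likelihood, an ego-centric prior centred on the
straight-ahead direction $\theta_{\mathrm{ego}}$, and a prior built from
the block's heading distribution with mean $\theta_{\mathrm{dis}}$. The
key analytic property is that a *uniform* distribution prior is a
constant (for the 66°-wide design, $1/66$ per degree) and cancels from
the ratio: predictions then depend on the ego-centric prior alone. Only
a nonuniform distribution prior can move predictions — and it moves them
*toward* its mean. The package makes both properties executable
(`posterior()`, `predict_ph()`, `predicted_slope()`); the test suite
verifies the cancellation pointwise and the attraction direction under
the right-heavied prior. Since the empirical result is a bias *away*
from the heavy side, the model's prediction and the data diverge — the
pipeline is designed to demonstrate exactly that divergence.

Concrete choices the equations leave open, and what we chose:

* **Likelihood family**: Gaussian in degrees. Headings span at most
  ±33°, so linear (small-angle) space is adequate; no wrapped
  distribution is needed.
* **Grid**: $[-90°, 90°]$ at 0.1° by default — more than 5 SD beyond
  the most eccentric design heading for every parameter setting used
  here, so truncation is negligible (the conjugate-limit test passes at
  $10^{-4}$° with a 0.01° grid).
* **Distribution prior from discrete counts**: counts are smoothed with
  a Gaussian kernel (default 3°, half the 6° spacing of the heading
  grid) so the prior is a density rather than a spike train; with
  `dist_smooth_sigma = 0` the mass sits on the nearest grid points.
* **Read-out**: posterior mean by default, MAP as an option. With a
  Gaussian likelihood and ego prior the posterior-mean read-out gives
  the classic shrinkage slope
  $\sigma_{\mathrm{ego}}^2 / (\sigma_{\mathrm{ego}}^2 + \sigma_m^2)$,
  which the tests pin against an independent fine-grid quadrature oracle
  (0.941176 for $\sigma_m = 5$, $\sigma_{\mathrm{ego}} = 20$).
* **Degenerate input**: when likelihood and priors have numerically
  disjoint support the posterior has zero mass everywhere and the
  function stops with an explicit error rather than returning NaNs.

## The block designs

Six presets reproduce the study's heading distributions. Uniform blocks
show each heading 50 times; the right-heavied block redistributes 600
trials with counts 16, 16, 16, 16, 16, 22, 42, 84, 124, 124, 82, 42
over the 12 headings −33° … 33° in 6° steps (the published counts list
names 13 headings but prints 12 counts; we treat the stray "6°" as a
typo and map the 12 counts onto the standard ±3°…±33° set, which makes
the block total 600 trials like every other 50-trial design). Its
count-weighted mean is exactly 12.0°; the published text rounds this to
12.05°, which the printed counts cannot produce, so the package reports
the value implied by the counts.

```{r, eval = FALSE}
library(headingbias)
make_distribution("right_heavied_nonuniform")
distribution_mean(make_distribution("right_shifted_narrow_uniform")) # 18
```

Trial schedules are full random permutations of the block's trial
multiset (the study randomized order within block; we impose no
constraint on immediate repeats), seeded and reproducible.

## The synthetic observer

No raw behavioral data are deposited, so the pipeline's inputs are
synthetic cohorts with the statistical structure the analyses assume.
For trial $i$ with previous heading $AH_{i-1}$ and block distribution
mean $m$:

$$
PH_i = \delta + s\,[(1 - w)\,AH_i + w\,m]
  + c\,(AH_{i-1} - AH_i) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

with compression slope $s$ (`slope_s`), constant shift $\delta$
(`shift_delta`), central-tendency weight $w$ (`ct_weight`; negative
values express repulsion from the distribution mean), serial-dependence
coefficient $c$ (`sd_coef`) on the relative heading, and homoscedastic
Gaussian response noise $\sigma$ (`noise_sigma`). The first trial of a
block has no predecessor and gets no serial term.

Defaults are the study's conditions: 20 participants per cohort, full
block sizes (600/300 trials), $s = 0.8$ (the slope magnitude such
displays produce), $\sigma = 3°$ (response scatter of a few degrees),
and $\delta = w = c = 0$ (effects are switched on per analysis).
Between-participant slope variability is available as `slope_sd`; the
published slope SE of 0.031 over 20 participants implies a
between-participant SD of about 0.14, which is what the worked examples
use. What the generator does *not* emulate: lapses, motor/probe error
structure, eye movements, heading-dependent noise, learning across a
block. Passing tests therefore certify the *pipeline* under the assumed
generative structure, not any claim about real observers.

### What the two-stage serial-dependence estimator actually estimates

The analysis (below) first removes each participant's linear PH-vs-AH
trend and then regresses the residual heading error on the relative
heading $RH_i = AH_{i-1} - AH_i$. Under the generator above, the
$-c\,AH_i$ half of the serial term is collinear with $AH_i$ and is
absorbed into the stage-1 slope (whose estimand becomes $s - c$),
leaving residuals that carry only the $c\,AH_{i-1}$ half; since
$\operatorname{Cov}(AH_{i-1}, RH) / \operatorname{Var}(RH) = 1/2$ for a
shuffled schedule, the stage-2 slope converges to $c/2$, not $c$. This
is a structural property of the residual-regression method itself, not
an implementation artifact; we verified it both algebraically and by
simulation (generative $c = -0.01$ recovers $\hat{s}' \approx -0.005$
with SE $\approx 0.0007$ at 20 × 600 trials). The tests therefore pin
the estimator to its true estimand $c/2$. Readers comparing a fitted
$s'$ with a generative `sd_coef` should halve the latter.

## The statistical pipeline

* **Center-bias slopes** (`fit_center_bias`, `test_slopes_vs_one`): one
  OLS fit per participant × condition; a two-sided one-sample t on the
  slopes against 1, with Cohen's $d = |\bar{s} - 1| / SD$.
* **Distribution ANOVA** (`rm_anova`): responses are first aggregated
  to per-participant cell means (standard repeated-measures practice),
  then analysed with type-III sums of squares via a multivariate linear
  model; within effects with more than one numerator df carry a
  Greenhouse–Geisser epsilon and corrected p. With a between-subject
  factor the group term uses sum-to-zero coding so the type-III marginal
  tests average over groups. The test suite checks every number against
  a from-scratch matrix-algebra oracle on a 4-subject 2×3 fixture and
  against `aov()` error strata for the mixed design.
* **Central-tendency contrast** (`central_tendency_contrast`):
  per-heading differences in grand-mean PH at the headings two designs
  share, plus the distribution main effect restricted to those headings;
  within-subject when the two tables contain the same participants,
  mixed otherwise.
* **Serial dependence** (`serial_dependence`): the two-stage residual
  regression described above, pooled across participants. The 95% CI is
  a participant-level nonparametric bootstrap. We use the bootstrap to
  estimate the slope's SE and form a $t_{J-1}$ interval rather than
  taking bootstrap percentiles: with J = 20 participants the percentile
  interval undercovers (null rejection 7.3% over 1000 simulated null
  cohorts) while the bootstrap-SE t interval is calibrated (4.9%);
  `ci_method = "percentile"` remains available.
* **Bias decomposition** (`decompose_bias`): the serial-dependence
  contribution to a between-condition bias difference is defined as the
  condition difference of the mean per-trial predicted residual shift
  $\bar{s' \cdot RH_i}$ on the realized schedules, expressed as a
  percentage of the total difference — the only construction available
  from the quantities the analysis defines, and one that reproduces the
  worked ratio $100 \cdot (-0.031)/(-1.98) = 1.57\%$ from its printed
  inputs. Note that for any permutation schedule the mean RH of a block
  is $(AH_1 - AH_N)/(N-1)$, so induced biases on synthetic schedules
  are necessarily tiny.
* **Post-hoc per-heading comparisons** after a significant interaction
  are paired t-tests without multiplicity correction, mirroring the
  reporting style the pipeline emulates; treat isolated p ≈ .045
  results accordingly.
* $\alpha = .05$, two-sided, throughout.

## Orchestration and reproducibility

`run_pipeline()` chains simulation and all analysis stages, writing the
trial table, a results JSON, every figure with its underlying numbers as
CSV, and a manifest (config, seeds, versions). Re-running from the
manifest reproduces the numerical outputs exactly; all randomness flows
from one master seed through deterministically derived sub-seeds.
`validate_table()` schema-checks external trial tables and reports every
violation at once.

## Sizes used by the test suite

Module tests run on reduced designs (the same heading sets with 5–20
trials per heading, 3–12 participants) chosen so the whole suite
completes in about a minute; the parameter-recovery and null-calibration
checks use the full 20 × 600 design for 100 replicates and scaled-down
blocks for 1000 replicates respectively, sizes at which the Monte-Carlo
error of the checked rates is a fraction of the tolerance band.

## Known limitations

* The Bayesian module formalizes the attraction account only; it cannot
  produce the repulsive distribution effect (no efficient-coding or
  adaptation mechanism is included), and the package deliberately does
  not fit the model to data.
* Angles are treated as linear quantities; do not use the observer
  beyond roughly ±60° without switching to a wrapped likelihood.
* The generator's serial term acts on the immediately preceding trial
  only; longer-lag history effects are out of scope.
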