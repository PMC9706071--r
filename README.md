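# headingbias

Does the *distribution* of recently seen headings bias how we perceive
our direction of self-motion from optic flow?

Heading estimates show a robust **center bias**: fitting the perceived
heading (PH) as a linear function of the actual heading (AH),
`PH = s·AH + b`, gives compression slopes `s < 1` toward the
straight-ahead direction (0°). Many other perceptual dimensions
additionally show **central tendency** — attraction of current estimates
toward the mean of the recently experienced stimulus distribution —
which Bayesian observer models explain by letting that distribution act
as a prior:

    p(X | M) ∝ p(M | X) · p_ego(X | θ_ego) · p_dis(X | θ_dis)

where `p_ego` is an ego-centric prior on straight ahead and `p_dis` the
previous-heading-distribution prior. For a *uniform* heading
distribution `p_dis` is a constant (1/66 per degree for a 66°-wide
block) and cancels from the normalized posterior, so only the
ego-centric prior can bias estimates; a *nonuniform* distribution prior
does not cancel and pulls estimates toward its mean. A finer history
effect, **serial dependence**, is measured by a two-stage residual
regression: per-participant PH-vs-AH fits give residual heading errors
(RHE), which are regressed on the relative heading
`RH = AH_prev − AH_current`; a negative slope `s′` means repulsion from
the previous heading.

This package is for psychophysicists who want to simulate and analyse
such designs end to end. It provides:

* **Designs** — the six heading-distribution block designs (wide /
  narrow / shifted uniform blocks with 50 trials per heading, and a
  right-heavied nonuniform block: counts 16, 16, 16, 16, 16, 22, 42,
  84, 124, 124, 82, 42 over −33°…33°), with seeded trial schedules.
* **Synthetic observers** — a generative model with configurable
  compression slope, constant shift, central-tendency weight,
  serial-dependence coefficient and response noise, producing tidy trial
  tables (`participant, condition, trial, ah_deg, ph_deg`).
* **A Bayesian ideal observer** — grid-based posterior, posterior-mean /
  MAP read-outs, predicted perceived headings and predicted center-bias
  slopes under any prior.
* **The analysis pipeline** — slope fits and one-sample t-tests against
  1, repeated-measures and mixed ANOVAs with Greenhouse–Geisser
  correction, central-tendency contrasts, the serial-dependence
  residual regression with participant-level bootstrap CIs, and a
  decomposition of between-condition bias differences into their
  serial-dependence component.

## Worked example

Simulate a 20-participant cohort on the wide-symmetric plus
right-shifted-narrow two-block design (compression slope 0.8,
between-participant slope SD 0.14, 3° response noise), then run the core
analyses:

```r
library(headingbias)

params <- observer_params(slope_s = 0.8, noise_sigma = 3)
tab <- simulate_cohort(
  c("symmetric_wide_uniform", "right_shifted_narrow_uniform"),
  n_participants = 20, params, seed = 42, slope_sd = 0.14)

test_slopes_vs_one(fit_center_bias(tab))
#>                      condition  n mean_slope     se     t df        p cohens_d
#> 1 right_shifted_narrow_uniform 20      0.814 0.0290 -6.39 19 3.93e-06     1.43
#> 2       symmetric_wide_uniform 20      0.810 0.0285 -6.64 19 2.35e-06     1.49

rm_anova(tab[tab$ah_deg %in% seq(3, 33, 6), ],
         within = c("condition", "ah_deg"))
#>             effect df1 df2      F        p     pes gg_epsilon df1_gg df2_gg     p_gg
#> 1        condition   1  19   0.12 7.33e-01 0.00628         NA     NA     NA       NA
#> 2           ah_deg   5  95 783.93 1.45e-75 0.97634      0.213   1.07   20.3 6.85e-18
#> 3 condition:ah_deg   5  95   1.12 3.53e-01 0.05582      0.781   3.91   74.2 3.52e-01

serial_dependence(tab, "symmetric_wide_uniform", n_boot = 2000, seed = 43)
#> <serial_dependence> symmetric_wide_uniform: s' = 0.000113,
#>   95% CI [-0.001312, 0.001538] (20 participants, 11980 trials)
```

Reading the output: both blocks show a clear center bias (mean slopes
≈ 0.81, significantly below 1 with large effect sizes), the
distribution main effect and its interaction with heading are null — no
central tendency, as expected for uniform blocks with `ct_weight = 0` —
and the serial-dependence slope is indistinguishable from zero for this
no-history observer. `run_pipeline(run_config("exp1", seed = 1))` chains
all stages and writes the data, results JSON, figures and a
reproducibility manifest to a directory.

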