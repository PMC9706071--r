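test_that("closed-form OLS helper agrees with lm", {
  set.seed(42)
  x <- rnorm(50, 0, 10)
  y <- 2 + 0.7 * x + rnorm(50)
  f <- headingbias:::ols_fit(x, y)
  m <- lm(y ~ x)
  expect_equal(f$slope, unname(coef(m)[2L]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(coef(m)[1L]), tolerance = 1e-12)
  expect_equal(f$slope_se, unname(summary(m)$coefficients[2L, 2L]),
               tolerance = 1e-12)
  expect_equal(f$residuals, unname(resid(m)), tolerance = 1e-12)
})

test_that("center-bias fits recover degenerate observers and stay orthogonal", {
  sch <- generate_schedule(small_wide(), 2)
  tab <- simulate_block(sch, observer_params(slope_s = 1, noise_sigma = 0),
                        seed = 1)
  f <- fit_center_bias(tab)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)

  # pure center bias: always reporting straight ahead gives slope 0
  tab0 <- tab
  tab0$ph_deg <- 0
  f0 <- fit_center_bias(tab0)
  expect_equal(f0$slope, 0, tolerance = 1e-12)

  # residual orthogonality to the regressor
  tabn <- simulate_block(sch, observer_params(), seed = 3)
  fn <- fit_center_bias(tabn)
  res <- fn$residuals[[1L]]
  expect_lt(abs(sum(res * tabn$ah_deg)) /
              sqrt(sum(res^2) * sum(tabn$ah_deg^2)), 1e-8)

  # single-heading block is rejected by name
  bad <- tab[tab$ah_deg == 3, ]
  bad$trial <- seq_len(nrow(bad))
  expect_error(fit_center_bias(bad), "single actual-heading level")
})

test_that("slope t-test matches t.test and its effect-size invariant", {
  fits <- data.frame(
    participant = sprintf("p%02d", 1:3),
    condition = "c",
    slope = c(0.7, 0.8, 0.9)
  )
  res <- test_slopes_vs_one(fits)
  ref <- t.test(fits$slope, mu = 1)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  # Cohen's d invariant: d * se * sqrt(n) == |mean - 1|
  expect_equal(res$cohens_d * res$se * sqrt(res$n), abs(res$mean_slope - 1),
               tolerance = 1e-12)

  # slopes identically 1: t = 0, d = 0
  f1 <- fits
  f1$slope <- c(1, 1, 1) + c(1e-14, 0, -1e-14)
  r1 <- test_slopes_vs_one(f1)
  expect_equal(r1$t, 0, tolerance = 1e-6)
  expect_equal(r1$cohens_d, 0, tolerance = 1e-6)

  # summary-statistic check against the published style of reporting:
  # mean 0.79, SE 0.031, n = 20 gives t ~ -6.8 and d ~ 1.5
  t_summary <- (0.79 - 1) / 0.031
  d_summary <- abs(0.79 - 1) / (0.031 * sqrt(20))
  expect_equal(t_summary, -6.79, tolerance = 0.05)
  expect_equal(d_summary, 1.52, tolerance = 0.05)
  expect_error(test_slopes_vs_one(fits[1L, , drop = FALSE]),
               "fewer than 2 participants")
})

test_that("repeated-measures ANOVA matches the matrix-algebra oracle", {
  # 4 subjects x (2 x 3) integer within design
  Y <- matrix(c(
    5, 7, 9, 6, 8, 11,
    4, 6, 8, 5, 9, 10,
    6, 9, 9, 7, 12, 13,
    5, 8, 10, 9, 11, 14
  ), nrow = 4, byrow = TRUE)
  oracle <- rm2way_oracle(Y, A = 2, B = 3)
  long <- rm2way_long(Y, A = 2, B = 3)
  res <- rm_anova(long, within = c("condition", "ah_deg"))

  got <- function(effect) res[res$effect == effect, ]
  expect_equal(got("condition")$F, oracle$F[["A"]], tolerance = 1e-8)
  expect_equal(got("ah_deg")$F, oracle$F[["B"]], tolerance = 1e-8)
  expect_equal(got("condition:ah_deg")$F, oracle$F[["AB"]],
               tolerance = 1e-8)
  expect_equal(got("ah_deg")$df1, oracle$df1[["B"]])
  expect_equal(got("ah_deg")$df2, oracle$df2[["B"]])
  expect_equal(got("condition")$pes, oracle$pes[["A"]], tolerance = 1e-8)
  expect_equal(got("ah_deg")$gg_epsilon, oracle$gg_eps[["B"]],
               tolerance = 1e-8)
  expect_equal(got("condition:ah_deg")$gg_epsilon, oracle$gg_eps[["AB"]],
               tolerance = 1e-8)
  # corrected p equals the F tail at epsilon-scaled dfs
  b <- got("ah_deg")
  expect_equal(b$p_gg, pf(b$F, b$df1_gg, b$df2_gg, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA edge cases: null condition effect and sphericity", {
  # identical per-participant cell means across conditions -> F = 0
  set.seed(13)
  base <- expand.grid(participant = sprintf("p%02d", 1:6),
                      ah_deg = seq(3, 33, by = 6))
  base$ph_deg <- 0.8 * base$ah_deg +
    rep(rnorm(6, 0, 2), times = 6) # participant offsets
  two <- rbind(transform(base, condition = "u1"),
               transform(base, condition = "u2"))
  two$trial <- 1L
  res <- rm_anova(two, within = c("condition", "ah_deg"))
  expect_lt(res$F[res$effect == "condition"], 1e-20)

  # compound-symmetric covariance -> epsilon 1
  k <- 5
  S <- matrix(0.4, k, k)
  diag(S) <- 1
  expect_equal(gg_epsilon(S), 1, tolerance = 1e-12)
  # lower bound attained for a maximally non-spherical covariance
  S2 <- diag(c(1, rep(1e-8, k - 1)))
  expect_equal(gg_epsilon(S2), 1 / (k - 1), tolerance = 1e-3)
})

test_that("epsilon bounds hold on random covariance matrices", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(3:8, 1L)
    X <- matrix(rnorm((k + 5) * k), k + 5, k)
    S <- cov(X)
    eps <- gg_epsilon(S)
    expect_gte(eps, 1 / (k - 1) - 1e-10)
    expect_lte(eps, 1 + 1e-10)
  }
})

test_that("mixed ANOVA agrees with aov's Error-stratum decomposition", {
  set.seed(11)
  tab <- rbind(
    simulate_cohort(list(small_wide()), 6, observer_params(), seed = 21),
    within(simulate_cohort(list(small_narrow()), 6, observer_params(),
                           seed = 22),
           participant <- paste0("q", participant))
  )
  tab$group <- ifelse(startsWith(tab$participant, "q"), "narrow", "wide")
  shared <- seq(3, 33, by = 6)
  sub <- tab[tab$ah_deg %in% shared, ]
  res <- rm_anova(sub, within = "ah_deg", between = "group")

  cellm <- aggregate(ph_deg ~ participant + group + ah_deg, sub, mean)
  cellm$ah_deg <- factor(cellm$ah_deg)
  cellm$participant <- factor(cellm$participant)
  cellm$group <- factor(cellm$group)
  ref <- summary(aov(ph_deg ~ group * ah_deg +
                       Error(participant / ah_deg), cellm))
  f_group <- ref[["Error: participant"]][[1]]["group", "F value"]
  f_head <- ref[["Error: participant:ah_deg"]][[1]]["ah_deg", "F value"]
  f_int <- ref[["Error: participant:ah_deg"]][[1]]["group:ah_deg",
                                                   "F value"]
  expect_equal(res$F[res$effect == "group"], f_group, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "ah_deg"], f_head, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:ah_deg"], f_int, tolerance = 1e-8)
})

test_that("serial dependence recovers the two-stage estimand", {
  # Constructed pull: responses displaced by a known multiple of the
  # relative heading. The two-stage procedure estimates half the generative
  # relative-heading coefficient: the current-heading part of the serial
  # term is absorbed into the stage-1 slope, leaving only the
  # previous-heading part, and Cov(AH_prev, RH) / Var(RH) = 1/2.
  reps <- 12
  est <- vapply(seq_len(reps), function(r) {
    tab <- simulate_cohort(list(make_distribution("symmetric_wide_uniform")),
                           20,
                           observer_params(sd_coef = -0.01, noise_sigma = 3),
                           seed = 100 + r)
    serial_dependence(tab, "symmetric_wide_uniform", n_boot = 50,
                      seed = r)$sd_slope
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.005)), 0.001)
  expect_true(all(est < 0))

  # repulsion sign convention at zero noise
  tab <- simulate_cohort(list(small_wide(20L)), 4,
                         observer_params(sd_coef = -0.05, noise_sigma = 0),
                         seed = 9)
  sdr <- serial_dependence(tab, "wide_small", n_boot = 50, seed = 1)
  expect_lt(sdr$sd_slope, 0)
  expect_lte(sdr$ci95[1L], sdr$sd_slope)
  expect_gte(sdr$ci95[2L], sdr$sd_slope)
  # rh excludes first trials: one fewer row per participant-block
  expect_identical(nrow(sdr$trials), 4L * (240L - 1L))
  expect_error(serial_dependence(tab, "nope"), "not found")
})

test_that("null serial dependence is rarely declared significant", {
  hits <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    tab <- simulate_cohort(list(small_wide()), 20, observer_params(),
                           seed = 500 + r)
    sdr <- serial_dependence(tab, "wide_small", n_boot = 400,
                             seed = 900 + r)
    hits <- hits + (sdr$ci95[1L] > 0 || sdr$ci95[2L] < 0)
  }
  expect_lte(hits, 6L) # ~5% nominal; P(X > 6 | p = .05) < 0.01
})

test_that("bias decomposition arithmetic, nulls and scale invariance", {
  expect_equal(bias_fraction_pct(-0.031, -1.98), 1.565657,
               tolerance = 1e-6)
  expect_error(bias_fraction_pct(-0.031, 0), "undefined")

  p <- observer_params(sd_coef = -0.02, noise_sigma = 1)
  tab <- simulate_cohort(list(small_wide(10L),
                              heading_distribution(
                                c(-33, -27, -21, -15, -9, -3, 3, 9, 15, 21,
                                  27, 33),
                                c(2, 2, 2, 2, 2, 3, 5, 10, 15, 15, 10, 5),
                                "heavied_small")),
                         8, p, seed = 31)
  sd_u <- serial_dependence(tab, "wide_small", n_boot = 100, seed = 1)
  sd_h <- serial_dependence(tab, "heavied_small", n_boot = 100, seed = 2)
  dec <- decompose_bias(sd_u, sd_h, total_bias_difference = -1.5)
  expect_equal(dec$fraction_pct,
               100 * (sd_induced_bias(sd_h) - sd_induced_bias(sd_u)) / -1.5,
               tolerance = 1e-12)
  # symmetric uniform schedules have near-zero mean relative heading, so
  # the induced bias is tiny whatever the slope
  expect_lt(abs(sd_induced_bias(sd_u)), abs(sd_u$sd_slope) * 1.5)

  # zero slopes give a zero fraction
  sd0_u <- sd_u
  sd0_u$sd_slope <- 0
  sd0_h <- sd_h
  sd0_h$sd_slope <- 0
  expect_equal(decompose_bias(sd0_u, sd0_h, -1.5)$fraction_pct, 0)

  # scale invariance: scaling all responses by c rescales both the
  # serial-dependence difference and the total bias difference
  tab2 <- tab
  tab2$ph_deg <- 3 * tab2$ph_deg
  sd_u2 <- serial_dependence(tab2, "wide_small", n_boot = 100, seed = 1)
  sd_h2 <- serial_dependence(tab2, "heavied_small", n_boot = 100, seed = 2)
  dec2 <- decompose_bias(sd_u2, sd_h2, total_bias_difference = 3 * -1.5)
  expect_equal(dec2$fraction_pct, dec$fraction_pct, tolerance = 1e-8)
})

test_that("mean heading bias recovers shifts with sensible intervals", {
  sch <- small_wide()
  tab <- simulate_cohort(list(sch), 10,
                         observer_params(slope_s = 1, noise_sigma = 0),
                         seed = 3)
  b0 <- mean_ph_bias(tab, "wide_small", n_boot = 200, seed = 1)
  expect_equal(b0$mean, 0, tolerance = 1e-12) # veridical symmetric design

  tab2 <- simulate_cohort(list(sch), 10,
                          observer_params(shift_delta = -2, noise_sigma = 2),
                          seed = 4)
  b2 <- mean_ph_bias(tab2, "wide_small", n_boot = 500, seed = 2)
  expect_equal(b2$mean, -2, tolerance = 0.5)
  expect_lte(b2$ci95[1L], b2$mean)
  expect_gte(b2$ci95[2L], b2$mean)
  expect_error(mean_ph_bias(tab2, "absent"), "not found")
})
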