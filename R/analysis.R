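#' Per-participant center-bias fits
#'
#' Fits perceived heading as a linear function of actual heading,
#' `PH-hat = s * AH + intercept`, separately for every
#' (participant, condition) block. A slope below 1 indicates compression
#' toward the ego-centric direction (center bias).
#'
#' @param table a response table (`participant`, `condition`, `trial`,
#'   `ah_deg`, `ph_deg`).
#' @return `data.frame` with one row per block: `participant`, `condition`,
#'   `slope`, `intercept`, `slope_se`, `n_trials`, plus a list-column
#'   `residuals` holding the per-trial OLS residuals in trial order.
#' @export
fit_center_bias <- function(table) {
  stopifnot(all(c("participant", "condition", "ah_deg", "ph_deg") %in%
                  names(table)))
  blocks <- split(table, list(table$participant, table$condition),
                  drop = TRUE, sep = " / ")
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    b <- b[order(b$trial), , drop = FALSE]
    if (length(unique(b$ah_deg)) < 2L) {
      stop("block ", nm, " has a single actual-heading level; ",
           "cannot fit a slope", call. = FALSE)
    }
    f <- ols_fit(b$ah_deg, b$ph_deg)
    data.frame(
      participant = b$participant[1L], condition = b$condition[1L],
      slope = f$slope, intercept = f$intercept, slope_se = f$slope_se,
      n_trials = nrow(b), residuals = I(list(f$residuals)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$condition, out$participant), , drop = FALSE]
}

#' One-sample t-test of center-bias slopes against 1
#'
#' Tests, per condition, whether participants' PH-vs-AH slopes differ from
#' the veridical slope of 1. Cohen's d is `|mean - 1| / sd`, equivalently
#' `|mean - 1| / (se * sqrt(n))`.
#'
#' @param fits output of [fit_center_bias()].
#' @return `data.frame` with one row per condition: `condition`, `n`,
#'   `mean_slope`, `se`, `t`, `df`, `p`, `cohens_d`.
#' @export
test_slopes_vs_one <- function(fits) {
  stopifnot(all(c("condition", "slope") %in% names(fits)))
  out <- lapply(split(fits, fits$condition), function(g) {
    n <- nrow(g)
    if (n < 2L) {
      stop("condition ", g$condition[1L],
           " has fewer than 2 participants; t-test undefined", call. = FALSE)
    }
    m <- mean(g$slope)
    se <- stats::sd(g$slope) / sqrt(n)
    t <- (m - 1) / se
    data.frame(
      condition = g$condition[1L], n = n, mean_slope = m, se = se,
      t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
      cohens_d = abs(m - 1) / (se * sqrt(n)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor for a within-subject factor with k levels,
#' computed from the covariance matrix of the k cell scores across subjects:
#' with `E = C' S C` for an orthonormal contrast basis C (k x (k-1)),
#' `epsilon = tr(E)^2 / ((k-1) * tr(E^2))`. Bounded in \[1/(k-1), 1\].
#'
#' @param S either a k x k covariance matrix of the within-cell scores, or an
#'   n x k matrix of per-subject cell scores (its covariance is taken).
#' @return Epsilon.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || !isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    S <- stats::cov(S)
  }
  k <- ncol(S)
  if (k < 2L) stop("need at least 2 within levels", call. = FALSE)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  E <- t(C) %*% S %*% C
  sum(diag(E))^2 / ((k - 1) * sum(E * E))
}

# Aggregate to per-subject cell means and pivot to wide (subjects x cells).
# Returns list(wide matrix, idata, between factor or NULL).
.cell_means_wide <- function(table, dv, within, between, subject) {
  miss <- setdiff(c(dv, within, between, subject), names(table))
  if (length(miss) > 0L) {
    stop("missing columns in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fac <- lapply(table[within], function(x) factor(x, levels = sort(unique(x))))
  cell <- interaction(rev(fac), drop = FALSE, sep = "|")
  subj <- factor(table[[subject]])
  agg <- tapply(table[[dv]], list(subj, cell), mean)
  if (anyNA(agg)) {
    bad <- which(is.na(agg), arr.ind = TRUE)
    stop("missing design cells (subject x cell): ",
         paste(sprintf("%s x %s", rownames(agg)[bad[, 1L]],
                       colnames(agg)[bad[, 2L]]), collapse = "; "),
         call. = FALSE)
  }
  idata <- rev(expand.grid(rev(lapply(fac, levels))))
  names(idata) <- within
  idata[] <- lapply(idata, factor)
  btw <- NULL
  if (!is.null(between)) {
    map <- unique(table[, c(subject, between)])
    if (anyDuplicated(map[[subject]])) {
      stop("between factor `", between,
           "` is not constant within subjects", call. = FALSE)
    }
    btw <- factor(map[[between]][match(rownames(agg), map[[subject]])])
  }
  list(wide = agg, idata = idata, between = btw)
}

#' Repeated-measures / mixed ANOVA with Greenhouse-Geisser correction
#'
#' Aggregates the response to per-subject cell means, then runs a
#' within-subject (optionally mixed, with one between-subject factor)
#' ANOVA via a multivariate linear model (type-III sums of squares,
#' `car::Anova`). Within effects with more than one numerator df carry a
#' Greenhouse-Geisser epsilon and an epsilon-corrected p value.
#'
#' @param table a response table (or any long data.frame).
#' @param dv response column name (default `"ph_deg"`).
#' @param within character vector of within-subject factor columns
#'   (e.g. `c("condition", "ah_deg")`).
#' @param between optional between-subject factor column.
#' @param subject subject identifier column (default `"participant"`).
#' @return `data.frame` of class `anova_result`: one row per effect with
#'   `effect`, `df1`, `df2`, `F`, `p`, `pes` (partial eta squared),
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg` (NA where no correction
#'   applies).
#' @export
rm_anova <- function(table, dv = "ph_deg", within = c("condition", "ah_deg"),
                     between = NULL, subject = "participant") {
  cm <- .cell_means_wide(table, dv, within, between, subject)
  Y <- cm$wide
  colnames(Y) <- paste0("cell", seq_len(ncol(Y)))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  if (is.null(cm$between)) {
    mod <- stats::lm(Y ~ 1)
  } else {
    grp <- cm$between
    # sum-to-zero coding so type-III marginal tests average over groups
    mod <- stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  }
  av <- car::Anova(mod, idata = cm$idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  u <- s$univariate.tests
  eff <- rownames(u)
  keep <- eff != "(Intercept)"
  u <- u[keep, , drop = FALSE]
  eff <- eff[keep]
  if (!is.null(cm$between)) eff <- sub("^grp", between, eff)
  res <- data.frame(
    effect = eff,
    df1 = unname(u[, "num Df"]),
    df2 = unname(u[, "den Df"]),
    F = unname(u[, "F value"]),
    p = unname(u[, "Pr(>F)"]),
    pes = unname(u[, "Sum Sq"] / (u[, "Sum Sq"] + u[, "Error SS"])),
    gg_epsilon = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_,
    p_gg = NA_real_,
    stringsAsFactors = FALSE
  )
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj) > 0L) {
    radj <- rownames(adj)
    if (!is.null(cm$between)) radj <- sub("^grp", between, radj)
    # epsilon is undefined (NA) when there are fewer subjects than within
    # levels; leave those rows uncorrected
    ok <- is.finite(adj[, "GG eps"]) & radj %in% res$effect
    i <- match(radj[ok], res$effect)
    res$gg_epsilon[i] <- adj[ok, "GG eps"]
    res$df1_gg[i] <- res$df1[i] * res$gg_epsilon[i]
    res$df2_gg[i] <- res$df2[i] * res$gg_epsilon[i]
    res$p_gg[i] <- adj[ok, "Pr(>F[GG])"]
  }
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Central-tendency contrast between two conditions
#'
#' Compares mean perceived headings between two response tables at a shared
#' set of actual headings: the per-heading difference in grand-mean PH
#' (participant means first), plus the distribution main-effect ANOVA
#' restricted to the shared headings. If the two tables contain the same
#' participants the contrast is within-subject; otherwise the table factor
#' is treated as between-subject (mixed ANOVA).
#'
#' @param table_a,table_b response tables, one condition each.
#' @param shared_headings actual headings present in both tables.
#' @return List of class `ct_contrast`: `differences` (`data.frame` with
#'   `ah_deg`, `mean_ph_a`, `mean_ph_b`, `diff` = b - a), `anova`
#'   ([rm_anova()] result), `design` (`"within"` or `"between"`).
#' @export
central_tendency_contrast <- function(table_a, table_b, shared_headings) {
  shared_headings <- as.numeric(shared_headings)
  if (length(shared_headings) == 0L) {
    stop("`shared_headings` is empty", call. = FALSE)
  }
  for (tb in list(a = table_a, b = table_b)) {
    missing_h <- setdiff(shared_headings, unique(tb$ah_deg))
    if (length(missing_h) > 0L) {
      stop("headings absent from one table: ",
           paste(missing_h, collapse = ", "), call. = FALSE)
    }
  }
  sub_a <- table_a[table_a$ah_deg %in% shared_headings, , drop = FALSE]
  sub_b <- table_b[table_b$ah_deg %in% shared_headings, , drop = FALSE]
  grand <- function(tb) {
    pm <- stats::aggregate(ph_deg ~ participant + ah_deg, tb, mean)
    stats::aggregate(ph_deg ~ ah_deg, pm, mean)
  }
  ga <- grand(sub_a)
  gb <- grand(sub_b)
  diffs <- data.frame(
    ah_deg = sort(shared_headings),
    mean_ph_a = ga$ph_deg[match(sort(shared_headings), ga$ah_deg)],
    mean_ph_b = gb$ph_deg[match(sort(shared_headings), gb$ah_deg)]
  )
  diffs$diff <- diffs$mean_ph_b - diffs$mean_ph_a
  sub_a$distribution <- "a"
  sub_b$distribution <- "b"
  combined <- rbind(sub_a[, c("participant", "distribution", "ah_deg",
                              "ph_deg")],
                    sub_b[, c("participant", "distribution", "ah_deg",
                              "ph_deg")])
  within_subjects <- setequal(unique(table_a$participant),
                              unique(table_b$participant))
  av <- if (within_subjects) {
    rm_anova(combined, dv = "ph_deg", within = c("distribution", "ah_deg"))
  } else {
    combined$participant <- paste(combined$distribution,
                                  combined$participant)
    rm_anova(combined, dv = "ph_deg", within = "ah_deg",
             between = "distribution")
  }
  structure(
    list(differences = diffs, anova = av,
         design = if (within_subjects) "within" else "between"),
    class = "ct_contrast"
  )
}

# Per-participant sufficient statistics of the pooled RHE ~ RH regression.
.serial_stats <- function(trials) {
  by_p <- split(trials, trials$participant)
  t(vapply(by_p, function(g) {
    c(n = nrow(g), sx = sum(g$rh), sy = sum(g$rhe),
      sxx = sum(g$rh^2), sxy = sum(g$rh * g$rhe))
  }, numeric(5)))
}

.pooled_slope <- function(stats_mat) {
  s <- colSums(stats_mat)
  (s["n"] * s["sxy"] - s["sx"] * s["sy"]) /
    (s["n"] * s["sxx"] - s["sx"]^2)
}

#' Serial-dependence residual regression
#'
#' Two-stage analysis of the pull of the previous trial's heading. Stage 1:
#' per participant, PH is regressed on AH and the residual heading error
#' (RHE) retained. Stage 2: RHE is regressed, pooled across participants, on
#' the relative heading `RH = AH_(i-1) - AH_i`. The first trial of each
#' block has no predecessor and is excluded. A negative slope s' means
#' estimates are repelled from the previous heading; a positive slope means
#' attraction.
#'
#' The CI comes from a participant-level nonparametric bootstrap. By
#' default (`ci_method = "boot_t"`) the bootstrap estimates the slope's SE
#' and the interval is `slope +- t(J-1, 1-(1-conf)/2) * SE` for J
#' participants; this choice is calibrated at J = 20, whereas the plain
#' percentile interval (`ci_method = "percentile"`, also available)
#' undercovers at cluster counts this small and rejects a true-zero slope
#' too often.
#'
#' @param table a response table.
#' @param condition condition label to analyse.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed optional seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param ci_method `"boot_t"` (default) or `"percentile"`; see Details.
#' @return List of class `serial_dependence_result`: `condition`,
#'   `sd_slope` (s'), `ci95`, `se`, `ci_method`, `n_participants`,
#'   `n_trials`, `n_boot`, and `trials` (`data.frame` with `participant`,
#'   `trial`, `rh`, `rhe`).
#' @export
serial_dependence <- function(table, condition, n_boot = 10000, seed = NULL,
                              conf = 0.95,
                              ci_method = c("boot_t", "percentile")) {
  ci_method <- match.arg(ci_method)
  sub <- table[table$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("condition \"", condition, "\" not found in table; available: ",
         paste(unique(table$condition), collapse = ", "), call. = FALSE)
  }
  by_p <- split(sub, sub$participant)
  trials <- do.call(rbind, lapply(by_p, function(b) {
    b <- b[order(b$trial), , drop = FALSE]
    if (nrow(b) < 2L) {
      stop("participant ", b$participant[1L],
           " has fewer than 2 trials in condition ", condition,
           call. = FALSE)
    }
    f <- ols_fit(b$ah_deg, b$ph_deg)
    data.frame(
      participant = b$participant[-1L], trial = b$trial[-1L],
      rh = b$ah_deg[-nrow(b)] - b$ah_deg[-1L],
      rhe = f$residuals[-1L],
      stringsAsFactors = FALSE
    )
  }))
  rownames(trials) <- NULL
  stats_mat <- .serial_stats(trials)
  slope <- unname(.pooled_slope(stats_mat))
  J <- nrow(stats_mat)
  boot <- function() {
    idx <- matrix(sample.int(J, n_boot * J, replace = TRUE), n_boot, J)
    comps <- vapply(1:5, function(k) {
      rowSums(matrix(stats_mat[idx, k], n_boot, J))
    }, numeric(n_boot))
    (comps[, 1L] * comps[, 5L] - comps[, 2L] * comps[, 3L]) /
      (comps[, 1L] * comps[, 4L] - comps[, 2L]^2)
  }
  slopes_b <- if (is.null(seed)) boot() else with_seed(seed, boot())
  alpha <- (1 - conf) / 2
  se <- stats::sd(slopes_b)
  ci <- if (ci_method == "boot_t") {
    slope + c(-1, 1) * stats::qt(1 - alpha, J - 1L) * se
  } else {
    unname(stats::quantile(slopes_b, c(alpha, 1 - alpha), names = FALSE))
  }
  structure(
    list(condition = condition, sd_slope = slope, ci95 = ci, se = se,
         ci_method = ci_method, n_participants = J,
         n_trials = nrow(trials), n_boot = n_boot, trials = trials),
    class = "serial_dependence_result"
  )
}

#' @export
print.serial_dependence_result <- function(x, ...) {
  cat(sprintf(paste0("<serial_dependence> %s: s' = %.4g, %d%% CI ",
                     "[%.4g, %.4g] (%d participants, %d trials)\n"),
              x$condition, x$sd_slope, 95L, x$ci95[1L], x$ci95[2L],
              x$n_participants, x$n_trials))
  invisible(x)
}

#' Serial-dependence-induced heading bias of one condition
#'
#' Mean over trials of the predicted residual shift `s' * RH_i` on the
#' condition's realized schedules. For a symmetric uniform block the mean
#' relative heading is near zero, so the induced bias vanishes whatever s'.
#'
#' @param sd_result a [serial_dependence()] result.
#' @return Bias in degrees.
#' @export
sd_induced_bias <- function(sd_result) {
  stopifnot(inherits(sd_result, "serial_dependence_result"))
  sd_result$sd_slope * mean(sd_result$trials$rh)
}

#' Fraction of a bias difference in percent
#'
#' @param sd_induced_difference degrees.
#' @param total_bias_difference degrees; must be nonzero.
#' @return `100 * sd_induced_difference / total_bias_difference`.
#' @export
bias_fraction_pct <- function(sd_induced_difference, total_bias_difference) {
  if (total_bias_difference == 0) {
    stop("total bias difference is 0: fraction undefined", call. = FALSE)
  }
  100 * sd_induced_difference / total_bias_difference
}

#' Decompose a between-condition heading-bias difference
#'
#' Splits the total difference in mean perceived heading between two
#' conditions (e.g. a right-heavied nonuniform block minus a symmetric
#' uniform block) into the part predicted by serial dependence: the
#' condition difference of [sd_induced_bias()], expressed as a percentage of
#' the total.
#'
#' @param sd_a [serial_dependence()] result for the reference condition
#'   (e.g. uniform).
#' @param sd_b [serial_dependence()] result for the comparison condition
#'   (e.g. nonuniform).
#' @param total_bias_difference observed total bias difference in degrees
#'   (b - a); must be nonzero.
#' @return List of class `decomposition_result`:
#'   `sd_induced_bias_per_condition` (named, degrees),
#'   `sd_induced_difference` (degrees), `total_bias_difference` (degrees),
#'   `fraction_pct`.
#' @export
decompose_bias <- function(sd_a, sd_b, total_bias_difference) {
  stopifnot(inherits(sd_a, "serial_dependence_result"),
            inherits(sd_b, "serial_dependence_result"))
  bias_a <- sd_induced_bias(sd_a)
  bias_b <- sd_induced_bias(sd_b)
  diff <- bias_b - bias_a
  per_cond <- c(bias_a, bias_b)
  names(per_cond) <- c(sd_a$condition, sd_b$condition)
  structure(
    list(sd_induced_bias_per_condition = per_cond,
         sd_induced_difference = diff,
         total_bias_difference = total_bias_difference,
         fraction_pct = bias_fraction_pct(diff, total_bias_difference)),
    class = "decomposition_result"
  )
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(paste0("<decomposition> serial-dependence-induced difference ",
                     "%.4g deg of %.4g deg total (%.3g%%)\n"),
              x$sd_induced_difference, x$total_bias_difference,
              x$fraction_pct))
  invisible(x)
}

#' Mean perceived-heading bias of a condition
#'
#' Grand mean perceived heading (participant means first, then averaged)
#' with SE and a participant-level bootstrap percentile CI.
#'
#' @param table a response table.
#' @param condition condition label.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed optional seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return List: `condition`, `mean` (deg), `se`, `ci95`, `n_participants`.
#' @export
mean_ph_bias <- function(table, condition, n_boot = 10000, seed = NULL,
                         conf = 0.95) {
  sub <- table[table$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("condition \"", condition, "\" not found in table; available: ",
         paste(unique(table$condition), collapse = ", "), call. = FALSE)
  }
  pm <- tapply(sub$ph_deg, sub$participant, mean)
  pm <- as.numeric(pm)
  n <- length(pm)
  boot <- function() {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    rowMeans(matrix(pm[idx], n_boot, n))
  }
  means_b <- if (is.null(seed)) boot() else with_seed(seed, boot())
  alpha <- (1 - conf) / 2
  list(
    condition = condition, mean = mean(pm),
    se = stats::sd(pm) / sqrt(n),
    ci95 = unname(stats::quantile(means_b, c(alpha, 1 - alpha),
                                  names = FALSE)),
    n_participants = n
  )
}
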