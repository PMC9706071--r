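#' Prior specification for the Bayesian ideal observer
#'
#' The observer's prior over headings is the product of two components:
#' an ego-centric prior — a Gaussian centred on the straight-ahead direction
#' — and a previous-heading-distribution prior built from the trial counts of
#' the block. When the heading distribution is uniform its prior is a
#' constant over the support and cancels from the normalized posterior, so
#' predictions depend on the ego-centric prior alone; a nonuniform
#' distribution prior does not cancel and pulls estimates toward its mean.
#'
#' @param ego_center ego-centric direction in degrees (normally 0).
#' @param ego_sigma SD in degrees of the Gaussian ego-centric prior; must be
#'   positive. Smaller values give stronger center bias.
#' @param dist_prior either `"uniform"` (constant density, cancels),
#'   `NULL` (no distribution prior at all), or a [heading_distribution()]
#'   whose counts are turned into a density.
#' @param dist_smooth_sigma SD in degrees of the Gaussian kernel used to
#'   smooth the discrete trial counts into a density; `0` places the count
#'   mass on the nearest grid points.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(ego_center = 0, ego_sigma = 20, dist_prior = "uniform",
                       dist_smooth_sigma = 3) {
  if (!is.numeric(ego_sigma) || ego_sigma <= 0) {
    stop("`ego_sigma` must be > 0", call. = FALSE)
  }
  if (dist_smooth_sigma < 0) {
    stop("`dist_smooth_sigma` must be >= 0", call. = FALSE)
  }
  if (!(is.null(dist_prior) ||
        identical(dist_prior, "uniform") ||
        inherits(dist_prior, "heading_distribution"))) {
    stop("`dist_prior` must be \"uniform\", NULL, or a heading_distribution",
         call. = FALSE)
  }
  structure(
    list(ego_center = ego_center, ego_sigma = ego_sigma,
         dist_prior = dist_prior, dist_smooth_sigma = dist_smooth_sigma),
    class = "prior_spec"
  )
}

#' Density of a uniform heading prior
#'
#' For a uniform heading distribution the observer may encode a constant
#' probability per degree over the block's heading range, `1 / width`: for
#' the 66-degree wide design this is 1/66 per degree.
#'
#' @param dist a [heading_distribution()].
#' @return Density in probability per degree.
#' @export
uniform_prior_density <- function(dist) {
  stopifnot(inherits(dist, "heading_distribution"))
  width <- diff(range(dist$headings))
  if (width <= 0) stop("distribution has zero width", call. = FALSE)
  1 / width
}

# Unnormalized distribution-prior density evaluated on the grid.
dist_prior_density <- function(prior, grid) {
  dp <- prior$dist_prior
  if (is.null(dp) || identical(dp, "uniform")) {
    return(rep(1, length(grid)))
  }
  w <- dp$counts / sum(dp$counts)
  if (prior$dist_smooth_sigma > 0) {
    dens <- numeric(length(grid))
    for (k in seq_along(dp$headings)) {
      dens <- dens + w[k] * stats::dnorm(grid, dp$headings[k],
                                         prior$dist_smooth_sigma)
    }
    dens
  } else {
    dens <- numeric(length(grid))
    idx <- vapply(dp$headings, function(h) which.min(abs(grid - h)), 1L)
    for (k in seq_along(idx)) dens[idx[k]] <- dens[idx[k]] + w[k]
    dens
  }
}

#' Posterior over headings for one noisy measurement
#'
#' Discretized posterior `p(X | M) \propto p(M | X) p_ego(X) p_dis(X)` on a
#' regular grid of candidate headings. The likelihood is Gaussian in degrees
#' with SD `meas_sigma`; the ego prior is Gaussian; the distribution prior is
#' the smoothed count density (constant for `"uniform"`).
#'
#' @param measurement noisy heading measurement M in degrees.
#' @param prior a [prior_spec()].
#' @param meas_sigma measurement (likelihood) SD in degrees, > 0.
#' @param grid_step grid resolution in degrees (default 0.1).
#' @param grid_range grid support in degrees (default `c(-90, 90)`, at least
#'   5 SD beyond the most eccentric headings used in any design).
#' @return An object of class `posterior_grid`: `grid`, `mass` (sums to 1),
#'   `measurement`.
#' @export
posterior <- function(measurement, prior, meas_sigma, grid_step = 0.1,
                      grid_range = c(-90, 90)) {
  stopifnot(inherits(prior, "prior_spec"), meas_sigma > 0, grid_step > 0)
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  un <- stats::dnorm(measurement, grid, meas_sigma) *
    stats::dnorm(grid, prior$ego_center, prior$ego_sigma) *
    dist_prior_density(prior, grid)
  tot <- sum(un)
  if (!is.finite(tot) || tot <= 0) {
    stop("posterior mass is zero on the grid: likelihood and priors have ",
         "disjoint support (measurement = ", measurement, ")", call. = FALSE)
  }
  structure(
    list(grid = grid, mass = un / tot, measurement = measurement),
    class = "posterior_grid"
  )
}

#' Posterior-mean read-out of a posterior grid
#' @param pg a [posterior()] result.
#' @return Posterior mean heading in degrees.
#' @export
posterior_mean <- function(pg) {
  stopifnot(inherits(pg, "posterior_grid"))
  sum(pg$grid * pg$mass)
}

#' Maximum-a-posteriori read-out of a posterior grid
#' @param pg a [posterior()] result.
#' @return Grid heading with the largest posterior mass, in degrees.
#' @export
posterior_map <- function(pg) {
  stopifnot(inherits(pg, "posterior_grid"))
  pg$grid[which.max(pg$mass)]
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(paste0("<posterior_grid> M = %.2f deg, %d points, ",
                     "mean = %.3f deg, MAP = %.2f deg\n"),
              x$measurement, length(x$grid), posterior_mean(x),
              posterior_map(x)))
  invisible(x)
}

#' Model-predicted perceived heading for a true heading
#'
#' Monte-Carlo expectation of the observer's point estimate: measurements are
#' drawn `M ~ N(ah, meas_sigma^2)`, the posterior is computed for each, and
#' the chosen read-out (posterior mean by default) is averaged.
#'
#' @param ah true heading in degrees (vectorized).
#' @param prior a [prior_spec()].
#' @param meas_sigma measurement SD in degrees.
#' @param estimator `"posterior_mean"` (default) or `"map"`.
#' @param n_mc number of simulated measurements per heading (>= 1).
#' @param seed optional seed for the measurement draws.
#' @param grid_step,grid_range passed to [posterior()].
#' @return Predicted perceived heading(s) in degrees.
#' @export
predict_ph <- function(ah, prior, meas_sigma,
                       estimator = c("posterior_mean", "map"), n_mc = 200,
                       seed = NULL, grid_step = 0.1, grid_range = c(-90, 90)) {
  estimator <- match.arg(estimator)
  stopifnot(n_mc >= 1)
  read_out <- if (estimator == "posterior_mean") posterior_mean else posterior_map
  one <- function(a, ms) {
    mean(vapply(ms, function(m) {
      read_out(posterior(m, prior, meas_sigma, grid_step, grid_range))
    }, numeric(1)))
  }
  draws <- function() {
    vapply(ah, function(a) one(a, stats::rnorm(n_mc, a, meas_sigma)),
           numeric(1))
  }
  if (is.null(seed)) draws() else with_seed(seed, draws())
}

#' Center-bias slope predicted by the ideal observer
#'
#' OLS slope of the model-predicted perceived heading against the actual
#' heading over a heading set — the model-side analogue of the empirical
#' PH-versus-AH slope fit.
#'
#' @param prior a [prior_spec()].
#' @param meas_sigma measurement SD in degrees.
#' @param heading_set actual headings in degrees; needs >= 2 distinct values.
#' @param ... passed to [predict_ph()] (`n_mc`, `seed`, `estimator`, grid
#'   controls).
#' @return Unitless slope (1 = veridical; < 1 = center bias).
#' @export
predicted_slope <- function(prior, meas_sigma, heading_set, ...) {
  heading_set <- as.numeric(heading_set)
  if (length(unique(heading_set)) < 2L) {
    stop("`heading_set` must contain at least 2 distinct headings",
         call. = FALSE)
  }
  preds <- predict_ph(heading_set, prior, meas_sigma, ...)
  ols_fit(heading_set, preds)$slope
}
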