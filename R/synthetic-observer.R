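#' Synthetic-observer parameters
#'
#' Parameterizes the generative model used to simulate perceived headings.
#' Each parameter maps onto one effect the downstream analyses test for:
#'
#' * `slope_s` — descriptive center-bias compression slope toward 0 deg
#'   (empirical blocks give slopes around 0.75-0.86; default 0.8).
#' * `shift_delta` — constant response shift in degrees (e.g. an overall
#'   leftward bias is a negative shift).
#' * `ct_weight` — central-tendency attraction weight in \[0, 1\] toward the
#'   block's distribution mean (0 = no attraction; negative values are
#'   permitted to express repulsion from the distribution mean).
#' * `sd_coef` — serial-dependence coefficient applied to the relative
#'   heading (previous minus current actual heading); negative = repulsion.
#' * `noise_sigma` — SD in degrees of additive Gaussian response noise
#'   (default 3 deg, in line with the few-degree precision of heading
#'   reports from dense flow fields).
#'
#' @param slope_s,shift_delta,ct_weight,sd_coef,noise_sigma see Details.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(slope_s = 0.8, shift_delta = 0, ct_weight = 0,
                            sd_coef = 0, noise_sigma = 3) {
  stopifnot(is.numeric(slope_s), is.numeric(shift_delta),
            is.numeric(ct_weight), is.numeric(sd_coef),
            is.numeric(noise_sigma))
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (ct_weight > 1) stop("`ct_weight` must be <= 1", call. = FALSE)
  structure(
    list(slope_s = slope_s, shift_delta = shift_delta, ct_weight = ct_weight,
         sd_coef = sd_coef, noise_sigma = noise_sigma),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(paste0("<observer_params> slope_s=%.3g shift_delta=%.3g ",
                     "ct_weight=%.3g sd_coef=%.3g noise_sigma=%.3g\n"),
              x$slope_s, x$shift_delta, x$ct_weight, x$sd_coef,
              x$noise_sigma))
  invisible(x)
}

#' Simulate one block of perceived headings
#'
#' Generative model for trial i with actual heading `AH_i`, previous-trial
#' heading `AH_(i-1)` and block distribution mean `m`:
#'
#' `PH_i = shift_delta + slope_s * ((1 - ct_weight) * AH_i + ct_weight * m)
#'        + sd_coef * (AH_(i-1) - AH_i) + eps_i`,  `eps_i ~ N(0, noise_sigma^2)`.
#'
#' The first trial of a block has no predecessor, so its serial term is 0.
#'
#' @param schedule a [generate_schedule()] result.
#' @param params an [observer_params()].
#' @param seed nonnegative integer seed for the response noise.
#' @param participant participant label.
#' @param condition condition label; defaults to the schedule's
#'   distribution name.
#' @return A response table: `data.frame` with columns `participant`,
#'   `condition`, `trial`, `ah_deg`, `ph_deg`.
#' @examples
#' sch <- generate_schedule(make_distribution("symmetric_wide_uniform"), 1)
#' head(simulate_block(sch, observer_params(noise_sigma = 0), seed = 1))
#' @export
simulate_block <- function(schedule, params, seed, participant = "p01",
                           condition = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "observer_params"))
  ah <- schedule$order
  n <- length(ah)
  m <- distribution_mean(schedule$distribution)
  prev <- c(NA_real_, ah[-n])
  serial <- params$sd_coef * (prev - ah)
  serial[1L] <- 0
  eps <- if (params$noise_sigma > 0) {
    with_seed(seed, stats::rnorm(n, 0, params$noise_sigma))
  } else {
    numeric(n)
  }
  ph <- params$shift_delta +
    params$slope_s * ((1 - params$ct_weight) * ah + params$ct_weight * m) +
    serial + eps
  data.frame(
    participant = as.character(participant),
    condition = as.character(condition %||% schedule$distribution$name),
    trial = seq_len(n),
    ah_deg = ah,
    ph_deg = ph,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of synthetic participants
#'
#' Runs each participant through every block of the design, with a fresh
#' randomized schedule per participant and block. Per-participant and
#' per-block sub-seeds are drawn deterministically from the master seed, so
#' the full table is reproducible. Between-participant heterogeneity in the
#' center-bias slope is available through `slope_sd` (per-participant slopes
#' drawn from `N(slope_s, slope_sd^2)`).
#'
#' @param design character vector of preset names (see [heading_presets()])
#'   or a list of [heading_distribution()] objects; one block each.
#' @param n_participants number of synthetic participants (the empirical
#'   cohorts used 20 per experiment).
#' @param params an [observer_params()] shared by the cohort, or a list of
#'   one `observer_params` per participant.
#' @param seed master nonnegative integer seed.
#' @param slope_sd SD of between-participant variation in `slope_s`
#'   (ignored when `params` is a per-participant list).
#' @return A response table covering all participants and blocks.
#' @examples
#' tab <- simulate_cohort("right_shifted_narrow_uniform", 2,
#'                        observer_params(), seed = 7)
#' nrow(tab) # 2 x 300
#' @export
simulate_cohort <- function(design, n_participants, params = observer_params(),
                            seed = 1, slope_sd = 0) {
  stopifnot(n_participants >= 1)
  dists <- if (is.character(design)) {
    lapply(design, make_distribution)
  } else if (inherits(design, "heading_distribution")) {
    list(design)
  } else {
    lapply(design, function(d) {
      stopifnot(inherits(d, "heading_distribution"))
      d
    })
  }
  n_blocks <- length(dists)
  per_participant <- is.list(params) && !inherits(params, "observer_params")
  if (per_participant && length(params) != n_participants) {
    stop("per-participant `params` must have length `n_participants`",
         call. = FALSE)
  }
  # All sub-seeds and participant slopes come from one seeded draw so the
  # cohort is a pure function of (design, n_participants, params, seed).
  setup <- with_seed(seed, {
    list(
      seeds = matrix(
        sample.int(.Machine$integer.max - 1L, 2L * n_participants * n_blocks),
        nrow = n_participants
      ),
      slopes = if (!per_participant && slope_sd > 0) {
        stats::rnorm(n_participants, params$slope_s, slope_sd)
      } else NULL
    )
  })
  out <- vector("list", n_participants * n_blocks)
  k <- 0L
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%02d", i)
    p_i <- if (per_participant) {
      params[[i]]
    } else if (!is.null(setup$slopes)) {
      obs <- params
      obs$slope_s <- setup$slopes[i]
      obs
    } else {
      params
    }
    for (b in seq_len(n_blocks)) {
      k <- k + 1L
      sch <- generate_schedule(dists[[b]], setup$seeds[i, 2L * b - 1L])
      out[[k]] <- simulate_block(sch, p_i, seed = setup$seeds[i, 2L * b],
                                 participant = pid)
    }
  }
  do.call(rbind, out)
}

#' Write a response table as CSV
#'
#' Header is exactly `participant,condition,trial,ah_deg,ph_deg`.
#'
#' @param table a response table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  cols <- c("participant", "condition", "trial", "ah_deg", "ph_deg")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a response table CSV, validating its schema
#'
#' @param path CSV written by [write_response_table()] (or any file with the
#'   same columns).
#' @return The validated response table.
#' @seealso [validate_table()] for the violation report.
#' @export
read_response_table <- function(path) {
  v <- validate_table(path)
  if (length(v$violations) > 0L) {
    stop("invalid response table ", path, ":\n  ",
         paste(v$violations, collapse = "\n  "), call. = FALSE)
  }
  v$table
}
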