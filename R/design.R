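#' Heading distributions: the block designs of the three experiments
#'
#' A heading distribution is a named set of actual headings (degrees, positive
#' rightward of the ego-centric straight-ahead at 0 deg) with a per-heading
#' trial count. The six presets reproduce the block designs used across the
#' three experiments: wide/narrow uniform blocks with 50 trials per heading,
#' and a right-heavied nonuniform block in which right-of-center headings are
#' heavily over-represented.
#'
#' @param headings numeric vector of heading angles in degrees, strictly
#'   increasing, all within \[-90, 90\].
#' @param counts positive integer trial counts, one per heading.
#' @param name label for the distribution.
#' @return An object of class `heading_distribution` with fields `name`,
#'   `headings`, `counts`.
#' @examples
#' d <- heading_distribution(c(-15, 0, 15), c(10, 10, 10), "demo")
#' distribution_mean(d)
#' @export
heading_distribution <- function(headings, counts, name = "custom") {
  headings <- as.numeric(headings)
  counts <- as.numeric(counts)
  if (length(headings) < 1L) {
    stop("at least one heading is required", call. = FALSE)
  }
  if (length(counts) != length(headings)) {
    stop("`counts` must have one entry per heading (got ",
         length(counts), " counts for ", length(headings), " headings)",
         call. = FALSE)
  }
  if (any(diff(headings) <= 0)) {
    stop("`headings` must be strictly increasing and unique", call. = FALSE)
  }
  if (any(abs(headings) > 90)) {
    stop("all |headings| must be <= 90 degrees", call. = FALSE)
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("`counts` must be positive integers (>= 1 trial per heading)",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), headings = headings,
         counts = as.integer(counts)),
    class = "heading_distribution"
  )
}

# Preset designs. Uniform blocks use 50 trials per heading; the right-heavied
# block redistributes 600 trials so that most fall right of 0 deg. The
# right-heavied counts are mapped onto the 12 headings -33..33 in ascending
# order.
.design_presets <- function() {
  wide <- c(-33, -27, -21, -15, -9, -3, 3, 9, 15, 21, 27, 33)
  list(
    symmetric_wide_uniform = list(
      headings = wide, counts = rep(50L, 12L)),
    right_shifted_narrow_uniform = list(
      headings = c(3, 9, 15, 21, 27, 33), counts = rep(50L, 6L)),
    symmetric_narrow_uniform = list(
      headings = c(-15, -9, -3, 3, 9, 15), counts = rep(50L, 6L)),
    left_shifted_narrow_uniform = list(
      headings = c(-33, -27, -21, -15, -9, -3), counts = rep(50L, 6L)),
    symmetric_uniform_exp3 = list(
      headings = wide, counts = rep(50L, 12L)),
    right_heavied_nonuniform = list(
      headings = wide,
      counts = c(16L, 16L, 16L, 16L, 16L, 22L, 42L, 84L, 124L, 124L, 82L, 42L))
  )
}

#' List the available design presets
#'
#' @return Character vector of preset names accepted by [make_distribution()].
#' @export
heading_presets <- function() names(.design_presets())

#' Build one of the preset heading distributions
#'
#' @param name preset label, one of [heading_presets()].
#' @return A [heading_distribution()].
#' @examples
#' make_distribution("right_shifted_narrow_uniform")
#' @export
make_distribution <- function(name) {
  presets <- .design_presets()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown design preset ", deparse(substitute(name)), " (",
         paste(deparse(name), collapse = ""), "); valid presets are: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  heading_distribution(p$headings, p$counts, name = name)
}

#' Count-weighted mean of a heading distribution
#'
#' The distribution mean is the quantity a central-tendency account predicts
#' responses are attracted to.
#'
#' @param dist a [heading_distribution()].
#' @return Mean heading in degrees.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "heading_distribution"))
  stats::weighted.mean(dist$headings, dist$counts)
}

#' Total number of trials implied by a distribution
#'
#' @param dist a [heading_distribution()].
#' @return Integer trial count (sum of per-heading counts).
#' @export
n_trials <- function(dist) {
  stopifnot(inherits(dist, "heading_distribution"))
  sum(dist$counts)
}

#' Randomized trial schedule for one block
#'
#' Produces a uniformly random permutation of the trial multiset implied by
#' the distribution (each heading repeated `counts` times), reproducible for
#' a fixed seed. The caller's RNG state is left untouched.
#'
#' @param dist a [heading_distribution()].
#' @param seed nonnegative integer seed.
#' @return An object of class `trial_schedule`: `distribution`, `order`
#'   (actual heading per trial, degrees), `seed`.
#' @export
generate_schedule <- function(dist, seed) {
  stopifnot(inherits(dist, "heading_distribution"))
  pool <- rep(dist$headings, dist$counts)
  order <- with_seed(seed, sample(pool, length(pool), replace = FALSE))
  structure(
    list(distribution = dist, order = order, seed = as.integer(seed)),
    class = "trial_schedule"
  )
}

#' @export
print.heading_distribution <- function(x, ...) {
  cat("<heading_distribution> ", x$name, "\n", sep = "")
  cat("  headings (deg): ", paste(x$headings, collapse = ", "), "\n", sep = "")
  cat("  counts:         ", paste(x$counts, collapse = ", "), "\n", sep = "")
  cat(sprintf("  trials: %d, mean: %.2f deg\n",
              n_trials(x), distribution_mean(x)))
  invisible(x)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s: %d trials, seed %d\n",
              x$distribution$name, length(x$order), x$seed))
  invisible(x)
}

#' @export
as.data.frame.trial_schedule <- function(x, ...) {
  data.frame(trial = seq_along(x$order), ah_deg = x$order)
}

#' Serialize a heading distribution to JSON
#'
#' Writes `{name, headings, counts}` so designs can be consumed outside R.
#'
#' @param dist a [heading_distribution()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(dist, path) {
  stopifnot(inherits(dist, "heading_distribution"))
  jsonlite::write_json(
    list(name = dist$name, headings = dist$headings, counts = dist$counts),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a heading distribution from a JSON design file
#'
#' @param path file written by [write_design_json()].
#' @return A [heading_distribution()].
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  heading_distribution(x$headings, x$counts, name = x$name)
}
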