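# YAML serialization of observer and prior settings, so simulation runs can
# be driven from plain-text config files.

#' Write observer parameters to YAML
#' @param params an [observer_params()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observer_yaml <- function(params, path) {
  stopifnot(inherits(params, "observer_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read observer parameters from YAML
#' @param path file written by [write_observer_yaml()].
#' @return An [observer_params()].
#' @export
read_observer_yaml <- function(path) {
  do.call(observer_params, yaml::read_yaml(path))
}

#' Write a prior specification to YAML
#'
#' A `heading_distribution` distribution prior is stored inline as
#' `{name, headings, counts}`.
#'
#' @param prior a [prior_spec()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_prior_yaml <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  x <- unclass(prior)
  if (inherits(x$dist_prior, "heading_distribution")) {
    x$dist_prior <- unclass(x$dist_prior)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a prior specification from YAML
#' @param path file written by [write_prior_yaml()].
#' @return A [prior_spec()].
#' @export
read_prior_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  dp <- x$dist_prior
  if (is.list(dp)) {
    dp <- heading_distribution(unlist(dp$headings), unlist(dp$counts),
                               dp$name %||% "custom")
  }
  prior_spec(x$ego_center, x$ego_sigma, dp, x$dist_smooth_sigma)
}
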