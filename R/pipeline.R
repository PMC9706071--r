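# End-to-end orchestration: simulate a cohort, run every analysis stage,
# write tables/figures and a reproducibility manifest.

.experiment_presets <- function(experiment) {
  switch(experiment,
    exp1 = c("symmetric_wide_uniform", "right_shifted_narrow_uniform"),
    exp2 = c("symmetric_narrow_uniform", "left_shifted_narrow_uniform"),
    exp3 = c("symmetric_uniform_exp3", "right_heavied_nonuniform"),
    stop("unknown experiment \"", experiment,
         "\"; use exp1, exp2, exp3 or custom", call. = FALSE)
  )
}

#' Configuration for a full simulation-and-analysis run
#'
#' @param experiment `"exp1"`, `"exp2"`, `"exp3"`, or `"custom"` (supply
#'   `presets`). exp1: symmetric wide + right-shifted narrow uniform blocks;
#'   exp2: symmetric narrow + left-shifted narrow; exp3: symmetric uniform +
#'   right-heavied nonuniform.
#' @param seed master seed for the whole run.
#' @param observer an [observer_params()].
#' @param prior optional [prior_spec()]; when given, model-predicted slopes
#'   and perceived headings are added to the report.
#' @param n_participants cohort size (default 20).
#' @param slope_sd between-participant slope SD (see [simulate_cohort()]).
#' @param presets preset names for `experiment = "custom"`.
#' @param n_boot bootstrap resamples for CIs.
#' @param output_dir directory the pipeline writes into.
#' @return List of class `run_config`.
#' @export
run_config <- function(experiment = c("exp1", "exp2", "exp3", "custom"),
                       seed = 1, observer = observer_params(), prior = NULL,
                       n_participants = 20, slope_sd = 0, presets = NULL,
                       n_boot = 10000, output_dir = tempfile("headingbias-")) {
  experiment <- match.arg(experiment)
  presets <- if (experiment == "custom") {
    if (is.null(presets)) stop("custom runs need `presets`", call. = FALSE)
    presets
  } else {
    .experiment_presets(experiment)
  }
  unknown <- setdiff(presets, heading_presets())
  if (length(unknown) > 0L) {
    stop("unknown presets: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(observer, "observer_params"),
            is.null(prior) || inherits(prior, "prior_spec"))
  structure(
    list(experiment = experiment, seed = as.integer(seed),
         observer = observer, prior = prior,
         n_participants = as.integer(n_participants), slope_sd = slope_sd,
         presets = presets, n_boot = as.integer(n_boot),
         output_dir = output_dir),
    class = "run_config"
  )
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message("[headingbias] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Write a ggplot, preferring PNG and falling back to PDF on devices
# without PNG support. Returns the path actually written.
.save_plot <- function(plot, path_stem, width = 6, height = 4.5) {
  png_path <- paste0(path_stem, ".png")
  ok <- tryCatch({
    grDevices::png(png_path, width = width * 100, height = height * 100,
                   res = 100)
    print(plot)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (ok) return(png_path)
  pdf_path <- paste0(path_stem, ".pdf")
  grDevices::pdf(pdf_path, width = width, height = height)
  print(plot)
  grDevices::dev.off()
  pdf_path
}

#' Run the full simulate-and-analyse pipeline
#'
#' Stages: simulate the cohort; fit per-participant center-bias slopes and
#' test them against 1; run the distribution-by-heading ANOVA on the
#' headings shared between conditions; run the serial-dependence regression
#' per condition; estimate each condition's mean heading bias and, for
#' two-condition runs, decompose the bias difference into its
#' serial-dependence component; optionally overlay ideal-observer
#' predictions. Writes `data.csv`, `results.json`, figure files with their
#' underlying numbers as CSV, and `manifest.json` (config + versions) into
#' `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with all stage results (`table`, `fits`,
#'   `slope_tests`, `anova`, `serial`, `bias`, `decomposition`, `model`,
#'   `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  table <- .stage("simulate", quiet, simulate_cohort(
    config$presets, config$n_participants, config$observer,
    seed = config$seed, slope_sd = config$slope_sd))
  write_response_table(table, out("data.csv"))

  fits <- .stage("center-bias fits", quiet, fit_center_bias(table))
  slope_tests <- .stage("slope t-tests", quiet, test_slopes_vs_one(fits))

  conds <- unique(table$condition)
  shared <- Reduce(intersect,
                   lapply(conds, function(cn) {
                     unique(table$ah_deg[table$condition == cn])
                   }))
  anova_res <- NULL
  if (length(conds) >= 2L && length(shared) >= 2L) {
    anova_res <- .stage("distribution ANOVA", quiet, rm_anova(
      table[table$ah_deg %in% shared, , drop = FALSE],
      within = c("condition", "ah_deg")))
  }

  serial <- .stage("serial dependence", quiet, {
    res <- lapply(conds, function(cn) {
      serial_dependence(table, cn, n_boot = config$n_boot,
                        seed = config$seed + 1L)
    })
    names(res) <- conds
    res
  })

  bias <- .stage("mean bias", quiet, {
    res <- lapply(conds, function(cn) {
      mean_ph_bias(table, cn, n_boot = config$n_boot,
                   seed = config$seed + 2L)
    })
    names(res) <- conds
    res
  })

  decomposition <- NULL
  if (length(conds) == 2L) {
    total <- bias[[2L]]$mean - bias[[1L]]$mean
    if (total != 0) {
      decomposition <- .stage("bias decomposition", quiet,
                              decompose_bias(serial[[1L]], serial[[2L]],
                                             total))
    }
  }

  model <- NULL
  if (!is.null(config$prior)) {
    model <- .stage("model predictions", quiet, {
      res <- lapply(conds, function(cn) {
        hs <- sort(unique(table$ah_deg[table$condition == cn]))
        preds <- predict_ph(hs, config$prior, meas_sigma = 5,
                            n_mc = 200, seed = config$seed + 3L)
        list(heading_set = hs, predicted_ph = preds,
             predicted_slope = ols_fit(hs, preds)$slope)
      })
      names(res) <- conds
      res
    })
  }

  files <- .stage("figures", quiet, {
    fig_ph <- plot_ph_by_ah(table)
    utils::write.csv(fig_ph$data, out("fig_ph_vs_ah.csv"), row.names = FALSE)
    paths <- c(.save_plot(fig_ph, out("fig_ph_vs_ah")))
    for (cn in conds) {
      fig_sd <- plot_serial_dependence(serial[[cn]])
      safe <- gsub("[^A-Za-z0-9_-]", "_", cn)
      utils::write.csv(fig_sd$data, out(paste0("fig_serial_", safe, ".csv")),
                       row.names = FALSE)
      paths <- c(paths, .save_plot(fig_sd, out(paste0("fig_serial_", safe))))
    }
    paths
  })

  results <- list(
    slope_tests = slope_tests,
    anova = if (!is.null(anova_res)) as.data.frame(anova_res) else NULL,
    serial = lapply(serial, function(s) {
      s[c("condition", "sd_slope", "ci95", "n_participants", "n_trials")]
    }),
    mean_bias = bias,
    decomposition = if (!is.null(decomposition)) {
      unclass(decomposition)
    } else NULL,
    model = model
  )
  jsonlite::write_json(results, out("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  manifest <- list(
    experiment = config$experiment, presets = config$presets,
    seed = config$seed, n_participants = config$n_participants,
    slope_sd = config$slope_sd, n_boot = config$n_boot,
    observer = unclass(config$observer),
    prior = if (!is.null(config$prior)) {
      p <- unclass(config$prior)
      if (inherits(p$dist_prior, "heading_distribution")) {
        p$dist_prior <- unclass(p$dist_prior)
      }
      p
    } else NULL,
    n_rows = nrow(table),
    package_version = as.character(utils::packageVersion("headingbias")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(table = table, fits = fits, slope_tests = slope_tests,
                 anova = anova_res, serial = serial, bias = bias,
                 decomposition = decomposition, model = model,
                 files = c(files, out("data.csv"), out("results.json"),
                           out("manifest.json")),
                 output_dir = config$output_dir))
}

#' Re-run a pipeline from its manifest
#'
#' Rebuilds the [run_config()] recorded in a `manifest.json` and runs the
#' pipeline again; with the same package version the numerical outputs are
#' identical.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir where to write the re-run (defaults to a fresh
#'   temporary directory).
#' @param quiet suppress stage messages.
#' @return See [run_pipeline()].
#' @export
run_pipeline_from_manifest <- function(manifest_path,
                                       output_dir = tempfile("headingbias-"),
                                       quiet = FALSE) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  obs <- do.call(observer_params, m$observer)
  prior <- NULL
  if (length(m$prior) > 0L) {
    dp <- m$prior$dist_prior
    if (is.list(dp)) {
      dp <- heading_distribution(dp$headings, dp$counts, dp$name)
    }
    prior <- prior_spec(m$prior$ego_center, m$prior$ego_sigma, dp,
                        m$prior$dist_smooth_sigma)
  }
  config <- run_config(
    experiment = m$experiment, seed = m$seed, observer = obs, prior = prior,
    n_participants = m$n_participants, slope_sd = m$slope_sd,
    presets = if (m$experiment == "custom") m$presets else NULL,
    n_boot = m$n_boot, output_dir = output_dir
  )
  run_pipeline(config, quiet = quiet)
}

#' Validate a response-table file or data frame
#'
#' Schema checks: required columns (`participant`, `condition`, `trial`,
#'   `ah_deg`, `ph_deg`), numeric trial/heading columns without NA, unique
#' (participant, condition, trial) keys, and trial indices consecutive from
#' 1 within each block. All violations are collected, not just the first.
#'
#' @param x a file path (CSV) or a data.frame.
#' @return List: `ok` (logical), `table` (the parsed table, or `NULL` when
#'   the file cannot be read), `violations` (character vector; empty when
#'   valid).
#' @export
validate_table <- function(x) {
  violations <- character()
  tab <- if (is.character(x)) {
    if (!file.exists(x)) {
      return(list(ok = FALSE, table = NULL,
                  violations = paste0("file not found: ", x)))
    }
    tryCatch(utils::read.csv(x, stringsAsFactors = FALSE),
             error = function(e) {
               violations <<- paste0("malformed CSV: ", conditionMessage(e))
               NULL
             })
  } else {
    as.data.frame(x)
  }
  if (is.null(tab)) {
    return(list(ok = FALSE, table = NULL, violations = violations))
  }
  required <- c("participant", "condition", "trial", "ah_deg", "ph_deg")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    violations <- c(violations,
                    paste0("missing column: ", missing_cols))
    return(list(ok = FALSE, table = tab, violations = violations))
  }
  for (col in c("trial", "ah_deg", "ph_deg")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      violations <- c(violations, paste0("column ", col, " is not numeric"))
    } else if (anyNA(v)) {
      violations <- c(violations, paste0("column ", col, " contains NA"))
    }
  }
  if (length(violations) == 0L) {
    key <- paste(tab$participant, tab$condition, tab$trial)
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      violations <- c(violations,
                      paste0("duplicated (participant, condition, trial) ",
                             "keys: ", paste(dups, collapse = "; ")))
    }
    blocks <- split(tab$trial, list(tab$participant, tab$condition),
                    drop = TRUE, sep = " / ")
    for (nm in names(blocks)) {
      tr <- sort(blocks[[nm]])
      if (!identical(as.integer(tr), seq_len(length(tr)))) {
        violations <- c(violations,
                        paste0("block ", nm, ": trial indices are not ",
                               "consecutive from 1"))
      }
    }
  }
  list(ok = length(violations) == 0L, table = tab, violations = violations)
}
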