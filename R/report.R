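# Pipeline entry points tying the stages into the three experiments:
# steady-state report, hormone-free +/-60% ensemble, and the three-way
# hormone comparison with daily statistics.  Each writes CSV outputs plus
# a YAML metadata sidecar sufficient to reproduce the run byte-for-byte.
# A thin command-line wrapper over these functions is installed at
# inst/scripts/synovasim-cli.R.

.resolve_params <- function(config) {
  if (!is.null(config$parameter_file)) load_parameter_set(config$parameter_file)
  else if (identical(config$parameters, "synthetic"))
    generate_nominal_parameters(seed = config$seed %||% 1L)
  else default_parameters()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration file
#'
#' YAML with optional keys \code{parameter_file}, \code{parameters}
#' (\code{"default"} or \code{"synthetic"}), \code{seed}, \code{n_samples},
#' \code{fraction}, \code{t_end}, \code{grid}, \code{out_dir}.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Pipeline stage: healthy steady-state report
#'
#' @param config list of settings (see \code{\link{read_pipeline_config}});
#'   may be an empty list for all defaults.
#' @return Data frame of mediator steady-state concentrations with
#'   convergence diagnostics, invisibly written to
#'   \code{<out_dir>/steady_state.csv} when \code{out_dir} is set.
#' @export
report_steady_state <- function(config = list()) {
  params <- .resolve_params(config)
  hs <- healthy_steady_state(params)
  out <- data.frame(species = mediator_ids(),
                    concentration_pg_ml = unname(hs[mediator_ids()]),
                    residual = attr(hs, "residual"),
                    newton_iters = attr(hs, "newton_iters"),
                    row.names = NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "steady_state.csv"),
                     row.names = FALSE)
  }
  out
}

.write_summary_csvs <- function(summary, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in species_ids()) {
    df <- data.frame(time_h = summary$times, median = summary$median[, s],
                     q1 = summary$q1[, s], q3 = summary$q3[, s])
    utils::write.csv(df, file.path(out_dir, paste0(prefix, s, ".csv")),
                     row.names = FALSE)
  }
}

#' Pipeline stage: hormone-free uncertainty ensemble
#'
#' Runs the Latin hypercube ensemble (default +/-60%, n = 2000) without
#' hormones and writes one median/IQR summary CSV per species.
#'
#' @param config list of settings; honoured keys: \code{n_samples},
#'   \code{fraction}, \code{seed}, \code{t_end}, \code{grid},
#'   \code{out_dir}.
#' @return The \code{ensemble_summary}, invisibly.
#' @export
report_ensemble <- function(config = list()) {
  params <- .resolve_params(config)
  ens <- run_ensemble(params,
                      n_samples = config$n_samples %||% 2000,
                      fraction = config$fraction %||% 0.60,
                      seed = config$seed %||% 1L,
                      t_end = config$t_end %||% 480,
                      grid = config$grid %||% 1)
  su <- summarize_ensemble(ens)
  if (!is.null(config$out_dir)) {
    .write_summary_csvs(su, config$out_dir, "ensemble_")
    yaml::write_yaml(ens$meta, file.path(config$out_dir,
                                         "ensemble_meta.yaml"))
  }
  invisible(su)
}

#' Pipeline stage: hormone-condition comparison
#'
#' Runs the male / female-low-estrogen / female-peak-estrogen conditions
#' with +/-20% coefficient variation, writes per-condition summary CSVs
#' and the daily Kruskal-Wallis / Mann-Whitney statistics table.
#'
#' @param config list of settings; honoured keys: \code{n_samples} (per
#'   condition), \code{fraction}, \code{seed}, \code{t_end}, \code{grid},
#'   \code{days}, \code{out_dir}.
#' @return List with the statistics data frame (\code{tests}) and the
#'   per-condition summaries (\code{summaries}).
#' @export
report_hormone_comparison <- function(config = list()) {
  params <- .resolve_params(config)
  n <- config$n_samples %||% 2000
  seed <- config$seed %||% 1L
  conditions <- c("male", "female_low_e", "female_peak_e")
  ensembles <- list()
  for (i in seq_along(conditions))
    ensembles[[conditions[i]]] <-
      run_condition(params, conditions[i], n = n,
                    seed = seed + i - 1L,
                    fraction = config$fraction %||% 0.20,
                    t_end = config$t_end %||% 480,
                    grid = config$grid %||% 1)
  tests <- daily_condition_tests(ensembles,
                                 days = config$days %||% 1:20)
  summaries <- lapply(ensembles, summarize_ensemble)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conditions)
      .write_summary_csvs(summaries[[cond]], config$out_dir,
                          paste0(cond, "_"))
    utils::write.csv(tests, file.path(config$out_dir, "daily_tests.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(seed = seed, n_samples = n,
                          fraction = config$fraction %||% 0.20),
                     file.path(config$out_dir, "hormone_meta.yaml"))
  }
  list(tests = tests, summaries = summaries)
}
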