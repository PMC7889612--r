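#' Read and validate a run configuration
#'
#' Configurations are plain YAML or JSON with a `subcommand` field
#' (`generate`, `trajectory-table`, `design-study`, `lookback-sweep` or
#' `selection-analysis`), an integer `seed`, an optional `preset`
#' (`"small"` or `"paper"`) and an optional `params` block overriding
#' [generator_params()] fields, plus subcommand-specific knobs (`n_reps`,
#' `n_per_arm`, `n_models`, `n_trials`, `lookbacks`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated config list of class `tempbias_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist.", path),
          class = "tempbias_invalid_config")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  subcommands <- c("generate", "trajectory-table", "design-study",
                   "lookback-sweep", "selection-analysis")
  if (is.null(cfg$subcommand) || !cfg$subcommand %in% subcommands) {
    abort(sprintf("config: `subcommand` must be one of %s.",
                  paste(subcommands, collapse = ", ")),
          class = "tempbias_invalid_config")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("config: a single numeric `seed` is required.",
          class = "tempbias_invalid_config")
  }
  if (!is.null(cfg$preset) && !cfg$preset %in% c("small", "paper")) {
    abort("config: `preset` must be 'small' or 'paper'.",
          class = "tempbias_invalid_config")
  }
  structure(cfg, class = "tempbias_config")
}

# Merge preset + config overrides into generator parameters.
config_params <- function(cfg) {
  over <- cfg$params
  if (identical(cfg$preset, "paper")) {
    base <- list(n_cases = 30000L, n_controls = 30000L)
  } else {
    base <- list()
  }
  over <- utils::modifyList(base, if (is.null(over)) list() else over)
  do.call(generator_params, c(list(seed = as.integer(cfg$seed)), over))
}

format_month <- function(m, year = 2015L) sprintf("%d-%02d", year, m)

write_result_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run a configured pipeline stage and write its artifacts
#'
#' Thin, reproducible entry point over the package's analysis functions:
#' generates the configured synthetic inputs, runs the requested stage,
#' and writes flat CSV result tables plus a JSON run summary (config echo,
#' seed, package versions, wall clock) into `out_dir`. Calendar months are
#' serialized as ISO `YYYY-MM`.
#'
#' @param config A `tempbias_config` (from [read_run_config()]) or a plain
#'   list with the same fields.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a character vector of file paths written.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_pipeline(list(subcommand = "trajectory-table", seed = 1,
#'                   n_reps = 3, n_per_arm = 1000), dir)
#' list.files(dir)
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "tempbias_config")) config
         else validate_run_config(config)
  t0 <- Sys.time()
  params <- config_params(cfg)
  small <- !identical(cfg$preset, "paper")

  # Stage outputs are assembled in full before anything is written, so an
  # invalid run leaves no partial artifacts behind.
  outputs <- list()
  if (cfg$subcommand == "generate") {
    cc <- gen_claims_cohort(params)
    pts <- cc$patients
    pts$delivery_month <- ifelse(is.na(pts$delivery_month), "",
                                 format_month(pts$delivery_month))
    ev <- cc$events
    ev$month <- format_month(ev$month)
    lc <- gen_longitudinal_cohort(params)
    rm <- gen_repeated_measures(params)
    outputs <- list(
      "centiles.csv" = make_standin_centiles(params),
      "claims_patients.csv" = pts,
      "claims_events.csv" = ev,
      "longitudinal.csv" = tibble::as_tibble(lc),
      "repeated_measures.csv" = tibble::as_tibble(rm)
    )
  } else if (cfg$subcommand == "trajectory-table") {
    laws <- standin_laws(params)
    n_reps <- cfg$n_reps %||% if (small) 20L else 100L
    n_per_arm <- cfg$n_per_arm %||% if (small) 20000L else 150000L
    res <- relative_effect_summary(laws$case, laws$control,
                                   n_reps = n_reps, n_per_arm = n_per_arm,
                                   seed = params$seed)
    outputs <- list("trajectory_table.csv" = tibble::as_tibble(res))
  } else if (cfg$subcommand == "design-study") {
    cc <- match_controls(gen_claims_cohort(params), seed = params$seed)
    n_models <- cfg$n_models %||% 10L
    designs <- list(
      cc_cc = list(study_design("event_indexed"), study_design("event_indexed")),
      cc_cohort = list(study_design("event_indexed"), study_design("calendar_fixed")),
      cohort_cohort = list(study_design("calendar_fixed"), study_design("calendar_fixed"))
    )
    studies <- purrr::imap(designs, function(d, nm) {
      run_design_study(cc, d[[1]], d[[2]], n_models = n_models,
                       seed = params$seed)
    })
    auroc <- dplyr::bind_rows(purrr::imap(studies, function(s, nm) {
      dplyr::mutate(s$auroc, study = nm, .before = 1)
    }))
    summaries <- dplyr::bind_rows(purrr::map(studies, glance))
    outputs <- list("design_auroc.csv" = auroc,
                    "design_summary.csv" = summaries)
  } else if (cfg$subcommand == "lookback-sweep") {
    lc <- gen_longitudinal_cohort(params)
    n_trials <- cfg$n_trials %||% if (small) 50L else 200L
    lookbacks <- cfg$lookbacks %||% 1:4
    sw <- lookback_sweep(lc, lookbacks = lookbacks, n_trials = n_trials,
                         seed = params$seed)
    outputs <- list("lookback_results.csv" = sw$results,
                    "lookback_summary.csv" = sw$summary)
  } else if (cfg$subcommand == "selection-analysis") {
    rm <- gen_repeated_measures(params)
    sel <- selection_effect_analysis(rm, seed = params$seed)
    outputs <- list("selection_effects.csv" = tibble::as_tibble(sel),
                    "intra_individual.csv" = intra_individual_variation(rm))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(outputs, function(df, nm) {
    write_result_csv(df, out_dir, nm)
  })
  summary <- list(
    subcommand = cfg$subcommand,
    seed = as.integer(cfg$seed),
    preset = cfg$preset %||% "small",
    config = unclass(cfg),
    versions = list(tempbias = as.character(utils::packageVersion("tempbias")),
                    R = R.version.string),
    wall_clock_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = unname(paths)
  )
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message(sprintf("[tempbias] %s: wrote %d artifact(s) to %s in %.1fs",
                  cfg$subcommand, length(paths) + 1L, out_dir,
                  summary$wall_clock_seconds))
  invisible(c(paths, summary_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
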