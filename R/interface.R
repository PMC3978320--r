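# Configuration and the end-to-end reproduction pipeline.

derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Load a simulation configuration
#'
#' Reads a YAML key-value file and fills every unspecified field with the
#' model's reference defaults, so an empty file reproduces the default
#' parameterisation (threshold 0.8, noise SD 0.11, 22 participants, the
#' full 440-item stimulus set). Recognised top-level keys: \code{seed},
#' \code{out_dir}, \code{stimuli} (sub-keys \code{n_per_cell},
#' \code{n_fillers}, \code{budget}) and \code{control} (any
#' [dfc_control()] parameter). Unknown keys are rejected by name.
#'
#' @param path path to a YAML file, or \code{NULL} for pure defaults.
#' @return list of class \code{"dfc_config"} with elements \code{seed},
#'   \code{out_dir}, \code{stimuli}, \code{control}.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    out <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop(sprintf("malformed configuration file '%s': %s", path,
                   conditionMessage(e))))
    if (is.null(out)) list() else out
  }
  allowed <- c("seed", "out_dir", "stimuli", "control")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  stim_defaults <- list(n_per_cell = 40L, n_fillers = 120L, budget = 10000L)
  bad_stim <- setdiff(names(raw$stimuli), names(stim_defaults))
  if (length(bad_stim))
    stop("unknown stimuli key(s): ", paste(bad_stim, collapse = ", "))
  stim <- utils::modifyList(stim_defaults, raw$stimuli %||% list())
  ctrl_over <- raw$control %||% list()
  for (nm in c("task_activation", "response_weight"))
    if (!is.null(ctrl_over[[nm]])) ctrl_over[[nm]] <- unlist(ctrl_over[[nm]])
  control <- do.call(dfc_control, ctrl_over)
  structure(list(seed = as.integer(raw$seed %||% 1L),
                 out_dir = raw$out_dir %||% "dfc-output",
                 stimuli = stim, control = control),
            class = "dfc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproduce the full simulated experiment
#'
#' Executes the whole pipeline with one master seed: train the comparison
#' networks, generate the constrained stimulus set, simulate all
#' participants, and analyse the run. All artifacts are written as plain
#' text under \code{out_dir}: trained weights, the stimulus list, the
#' trial-level table, effect tables, a plain-text report and a manifest
#' recording seed, configuration and package version.
#'
#' @param config a [load_config()] result (defaults reproduce the reference
#'   parameterisation).
#' @param out_dir output directory (overrides the config's).
#' @return invisibly, a list with \code{model}, \code{stimuli},
#'   \code{run}, \code{summary} and \code{paths}.
#' @export
reproduce <- function(config = load_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "dfc_config"))
  seeds <- derive_seeds(config$seed, 3L)
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e))))

  model <- stage("train", dfc_model(config$control, seed = seeds[1L]))
  stimuli <- stage("generate-stimuli", {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seeds[2L])
    dfc_stimuli(config$stimuli$n_per_cell, config$stimuli$n_fillers,
                budget = config$stimuli$budget)
  })
  run <- stage("simulate",
               run_experiment(model, stimuli,
                              n_participants = config$control$n_participants,
                              seed = seeds[3L]))
  summ <- stage("analyze", summarize_run(run))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_comparator(model$digit, p("weights_digit.csv"))
  write_comparator(model$length, p("weights_length.csv"))
  write_stimuli(stimuli, p("stimuli.csv"))
  write_run(run, p("trials.csv"))
  utils::write.csv(summ$rt_cells, p("rt_cells.csv"), row.names = FALSE)
  utils::write.csv(summ$er_cells, p("er_cells.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(summ$rt_anova), p("rt_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summ$er_anova), p("er_anova.csv"),
                   row.names = FALSE)
  sink(p("report.txt")); print(summ); sink()

  cfg_yaml <- yaml::as.yaml(list(
    seed = config$seed,
    stimuli = config$stimuli,
    control = unclass(config$control)))
  writeLines(cfg_yaml, p("config.yaml"))
  manifest <- list(
    package = "dfcomp",
    version = as.character(utils::packageVersion("dfcomp")),
    master_seed = config$seed,
    stage_seeds = as.list(stats::setNames(seeds,
                                          c("train", "stimuli", "run"))),
    config_md5 = unname(tools::md5sum(p("config.yaml"))),
    n_trials = nrow(run))
  writeLines(yaml::as.yaml(manifest), p("manifest.yaml"))

  invisible(list(model = model, stimuli = stimuli, run = run,
                 summary = summ,
                 paths = vapply(c("weights_digit.csv", "weights_length.csv",
                                  "stimuli.csv", "trials.csv", "report.txt",
                                  "manifest.yaml"), p, "")))
}
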