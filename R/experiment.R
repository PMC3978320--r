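# Simulated experiment: n participants x full item set, per-participant
# noise stream and trial order, trial-by-trial control adaptation.

participant_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the simulated comparison experiment
#'
#' Each simulated participant works through every stimulus pair exactly
#' once in an independently shuffled order. Per-step Gaussian noise makes
#' simulated RT (steps to threshold) and errors differ between
#' participants; task-demand couplings evolve across a participant's
#' session through conflict-driven Hebbian adaptation and are reset to
#' baseline between participants. Per-participant seeds are derived from
#' the master seed, so any single participant can be re-simulated in
#' isolation with [run_participant()].
#'
#' @param model a trained [dfc_model()].
#' @param stimuli a [dfc_stimuli()] data.frame.
#' @param n_participants number of simulated participants.
#' @param seed master seed for trial orders and noise.
#' @return a data.frame of class \code{"dfc_run"} with one row per trial:
#'   \code{participant}, \code{trial}, \code{item}, \code{type},
#'   \code{relation}, \code{steps}, \code{response}, \code{correct},
#'   \code{conflict}. Attributes record the master seed, participant seeds
#'   and control parameters.
#' @export
run_experiment <- function(model, stimuli,
                           n_participants = model$control$n_participants,
                           seed = 1L) {
  stopifnot(inherits(model, "dfc_model"), inherits(stimuli, "data.frame"))
  if (is.na(model$digit$accuracy) || model$digit$accuracy < 1)
    stop("cannot run the experiment with an incompletely trained digit network")
  seeds <- participant_seeds(seed, n_participants)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants))
    out[[p]] <- run_participant(model, stimuli, seed = seeds[p], id = p)
  run <- do.call(rbind, out)
  rownames(run) <- NULL
  attr(run, "seed") <- seed
  attr(run, "participant_seeds") <- seeds
  attr(run, "control") <- model$control
  class(run) <- c("dfc_run", "data.frame")
  run
}

#' @rdname run_experiment
#' @param id participant number recorded in the output.
#' @export
run_participant <- function(model, stimuli, seed, id = 1L) {
  force(model); force(stimuli)  # evaluate before touching the RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- model$control
  n <- nrow(stimuli)
  ord <- sample.int(n)
  evidence <- lapply(seq_len(n), function(i)
    trial_evidence(model, as.list(stimuli[i, ])))
  couplings <- params$task_activation
  steps <- integer(n); resp <- character(n); corr <- logical(n)
  confl <- numeric(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    res <- sim_trial(evidence[[i]], couplings, params)
    steps[k] <- res$steps
    resp[k] <- if (is.na(res$side)) "none" else c("first", "second")[res$side]
    corr[k] <- !is.na(res$side) && resp[k] == stimuli$larger[i]
    confl[k] <- res$conflict
    couplings <- adapt_task_weights(couplings, res$conflict, res$post, params)
  }
  data.frame(participant = id, trial = seq_len(n),
             item = stimuli$item[ord], type = stimuli$type[ord],
             relation = stimuli$relation[ord], steps = steps,
             response = resp, correct = corr, conflict = confl,
             stringsAsFactors = FALSE)
}

#' Exclude error trials from a simulated run
#'
#' Drops every trial that was answered incorrectly or hit the step cap
#' without a response (capped trials count as errors), mirroring the
#' error-exclusion applied to the simulated RT analyses. No further
#' trimming is applied to simulated steps.
#'
#' @param run a [run_experiment()] result.
#' @return list with \code{trials} (the correct-only rows) and
#'   \code{loss_fraction} (fraction of trials removed).
#' @export
exclude_errors <- function(run) {
  stopifnot(is.data.frame(run), "correct" %in% names(run))
  keep <- run$correct
  list(trials = run[keep, , drop = FALSE],
       loss_fraction = mean(!keep))
}

#' @export
print.dfc_run <- function(x, ...) {
  cat(sprintf("Simulated run: %d participants x %d trials\n",
              length(unique(x$participant)),
              nrow(x) / length(unique(x$participant))))
  cat(sprintf("  error trials: %.2f%%\n", 100 * mean(!x$correct)))
  ok <- x[x$correct, ]
  cat("  mean steps by type (correct trials):\n")
  print(round(tapply(ok$steps, ok$type, mean), 2))
  invisible(x)
}

#' Write or read a trial-level run table as CSV
#' @param run a \code{dfc_run} data.frame.
#' @param path file path.
#' @return \code{read_run} returns the \code{dfc_run} data.frame.
#' @export
write_run <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("dfc_run", "data.frame")
  out
}
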