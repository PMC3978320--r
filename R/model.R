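#' Fit the decimal-fraction comparison model
#'
#' Trains the model's comparison networks and bundles them with the
#' control-network configuration. One 10-node single-digit network is
#' trained with the delta rule under zero-biased digit frequencies and its
#' weights are reused for the unit, tenth and hundredth comparisons; a
#' separate 4-node, broadly tuned network is trained for the comparison of
#' the number of digits. The returned object is the "model bundle" that
#' [predict.dfc_model()], [simulate.dfc_model()] and [run_experiment()]
#' operate on.
#'
#' @param control a [dfc_control()] configuration.
#' @param seed integer seed for weight initialisation and training-pair
#'   sampling; training is bit-reproducible given the seed.
#' @return an object of class \code{"dfc_model"} with components
#'   \code{digit} and \code{length} (trained [train_comparator()]
#'   networks), \code{control} and \code{seed}.
#' @examples
#' \donttest{
#' m <- dfc_model(seed = 1)
#' coef(m)$digit[, 1:5]
#' }
#' @export
dfc_model <- function(control = dfc_control(), seed = 1L) {
  stopifnot(inherits(control, "dfc_control"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  digit <- train_comparator(digit_spec(), control$digit_trials,
                            control$digit_learning_rate,
                            control$digit_freq_weights)
  len <- train_comparator(length_spec(), control$length_trials,
                          control$length_learning_rate)
  for (nm in c("digit", "length")) {
    comp <- if (nm == "digit") digit else len
    if (comp$accuracy < 1)
      warning(sprintf(
        "%s network reached only %.1f%% accuracy on ordered pairs after %d trials",
        nm, 100 * comp$accuracy, comp$n_trials))
  }
  structure(list(digit = digit, length = len, control = control,
                 seed = seed, call = match.call()),
            class = "dfc_model")
}

#' @export
print.dfc_model <- function(x, ...) {
  cat("Decimal-fraction comparison model\n")
  cat(sprintf("  digit networks : shared weights, %d training trials, accuracy %.3f\n",
              x$digit$n_trials, x$digit$accuracy))
  cat(sprintf("  length network : %d training trials, accuracy %.3f\n",
              x$length$n_trials, x$length$accuracy))
  ta <- x$control$task_activation; wr <- x$control$response_weight
  cat("  task activation:", paste(sprintf("%s=%g", names(ta), ta),
                                  collapse = ", "), "\n")
  cat("  response weight:", paste(sprintf("%s=%g", names(wr), wr),
                                  collapse = ", "), "\n")
  cat(sprintf("  threshold %.2f at %s layer, max %d steps, noise sd %.2f\n",
              x$control$theta, x$control$threshold_layer,
              x$control$max_steps, x$control$noise_sd))
  invisible(x)
}

#' @export
summary.dfc_model <- function(object, ...) {
  vals <- 0:9
  dist_sep <- sapply(1:9, function(d) {
    pairs <- which(outer(vals, vals, function(a, b) abs(a - b)) == d,
                   arr.ind = TRUE)
    mean(apply(pairs, 1L, function(ij) {
      a <- comparator_forward(object$digit, vals[ij[1L]], vals[ij[2L]],
                              fixed_point = FALSE)
      abs(a[1L] - a[2L])
    }))
  })
  out <- list(model = object, digit_distance_separation = dist_sep)
  class(out) <- "summary.dfc_model"
  out
}

#' @export
print.summary.dfc_model <- function(x, ...) {
  print(x$model)
  cat("\nMean |aL - aR| of the digit network by numerical distance:\n")
  print(round(stats::setNames(x$digit_distance_separation, 1:9), 3))
  invisible(x)
}

#' @export
coef.dfc_model <- function(object, ...) {
  list(digit = object$digit$W, length = object$length$W)
}

#' Deterministic model predictions for stimulus pairs
#'
#' Runs each pair through the trial dynamics with the noise switched off,
#' giving the model's deterministic response and steps-to-threshold.
#'
#' @param object a [dfc_model()].
#' @param newdata a [dfc_stimuli()] data.frame (or any data.frame with the
#'   same digit columns).
#' @param ... unused.
#' @return \code{newdata} with columns \code{steps}, \code{response} and
#'   \code{correct} appended.
#' @export
predict.dfc_model <- function(object, newdata, ...) {
  params <- object$control
  params$noise_sd <- 0
  couplings <- params$task_activation
  res <- lapply(seq_len(nrow(newdata)), function(i) {
    tr <- run_trial(object, as.list(newdata[i, ]), params, couplings)
    data.frame(steps = tr$steps, response = tr$response,
               correct = tr$correct)
  })
  cbind(as.data.frame(newdata), do.call(rbind, res))
}

#' Simulate the full comparison experiment
#'
#' \code{simulate()} on a fitted model runs the simulated experiment:
#' \code{nsim} virtual participants each compare every stimulus pair once
#' in an independently shuffled order, with independent per-step Gaussian
#' noise; task-demand couplings adapt across trials within a participant
#' and reset between participants.
#'
#' @param object a [dfc_model()].
#' @param nsim number of simulated participants.
#' @param seed master seed; per-participant seeds are derived from it so
#'   that any participant can be re-simulated in isolation (see
#'   [run_participant()]).
#' @param stimuli a [dfc_stimuli()] set; generated with the defaults when
#'   omitted.
#' @param ... unused.
#' @return a \code{"dfc_run"} object, see [run_experiment()].
#' @export
simulate.dfc_model <- function(object, nsim = object$control$n_participants,
                               seed = 1L, stimuli = NULL, ...) {
  if (is.null(stimuli)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stimuli <- dfc_stimuli()
  }
  run_experiment(object, stimuli, n_participants = nsim, seed = seed)
}

#' @export
plot.dfc_run <- function(x, ...) {
  ex <- exclude_errors(x)
  tr <- ex$trials
  crit <- tr[tr$type %in% c("a.0c", "a.b0", "a.bc"), ]
  rt_type <- tapply(crit$steps, crit$type, mean)
  ab <- x[x$type == "a.b", ]
  er <- tapply(!ab$correct, ab$relation, mean) * 100
  abok <- tr[tr$type == "a.b", ]
  rt_ab <- tapply(abok$steps, abok$relation, mean)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::barplot(rt_type, ylab = "simulated RT (steps)",
                    main = "RT by decimal type", ...)
  graphics::barplot(rt_ab[c("congruent", "incongruent")],
                    ylab = "simulated RT (steps)",
                    main = "String-length congruity (RT)")
  graphics::barplot(er[c("congruent", "incongruent")],
                    ylab = "simulated ER (%)",
                    main = "String-length congruity (ER)")
  invisible(x)
}
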