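# Cognitive-control layer: the four comparison networks (units, tenths,
# hundredths, number of digits) run under leaky dynamics, gated by
# task-demand couplings, feeding two response nodes with mutual inhibition.
# A conflict monitor reads co-activation of the response nodes and drives
# Hebbian adaptation of the task-demand couplings between trials.

clip01 <- function(x) pmin(1, pmax(0, x))

ATTRS <- c("unit", "tenth", "hundredth", "length")

#' Control-network parameters and task-demand configuration
#'
#' All dynamics constants of the simulation with their default values:
#' activation persistence \code{tau} = 0.8, input gain \code{beta_in} =
#' 0.2, response-layer lateral inhibition \code{w_inh_resp} = -0.5,
#' baseline comparison gain \code{C} = 0.7, conflict gain \code{beta_con} =
#' 1, conflict smoothing \code{lambda_con} = 0.8, Hebbian persistence
#' \code{lambda_w} = 0.7, Hebbian gain \code{alpha_w} = 1, baseline
#' restoring scale \code{beta_w} = 0.5, response threshold \code{theta} =
#' 0.8, step cap \code{max_steps} = 200 and per-step Gaussian noise
#' \code{noise_sd} = 0.11. Attentional weighting of the four compared
#' attributes follows the relative fixation frequencies on the digits:
#' task activations 0 (unit), 1.5 (tenth), 0.01 (hundredth), 1.0 (number
#' of digits) and comparison-to-response weights 0.1, 1.0, 0.1, 0.7.
#'
#' Training defaults: the shared digit network trains for 120000 delta-rule
#' trials with sampling frequencies of digit 0 raised by 15\% and digit 1
#' by 5\%; the number-of-digits network trains for 100000 trials with
#' uniform sampling over lengths 1-4.
#'
#' @param ... name = value overrides of any listed default. Unknown names
#'   are an error. Overrides are recorded in the returned object's
#'   \code{"overridden"} attribute.
#' @return an object of class \code{"dfc_control"}.
#' @export
dfc_control <- function(...) {
  defaults <- list(
    tau = 0.8, beta_in = 0.2, w_inh_resp = -0.5, C = 0.7,
    beta_con = 1, lambda_con = 0.8, lambda_w = 0.7, alpha_w = 1,
    beta_w = 0.5, theta = 0.8, max_steps = 200L, noise_sd = 0.11,
    task_activation = c(unit = 0, tenth = 1.5, hundredth = 0.01,
                        length = 1.0),
    response_weight = c(unit = 0.1, tenth = 1.0, hundredth = 0.1,
                        length = 0.7),
    threshold_layer = "response",
    digit_trials = 120000L, length_trials = 100000L,
    digit_learning_rate = 2, length_learning_rate = 0.2,
    digit_freq_weights = c(1.15, 1.05, rep(1, 8)),
    n_participants = 22L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown control parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (nm %in% c("task_activation", "response_weight")) {
      v <- over[[nm]]
      stopifnot(!is.null(names(v)), all(names(v) %in% ATTRS))
      defaults[[nm]][names(v)] <- v
    } else defaults[[nm]] <- over[[nm]]
  }
  stopifnot(defaults$threshold_layer %in% c("response", "comparison"))
  structure(defaults, class = "dfc_control",
            overridden = names(over))
}

# Feedforward evidence for one displayed pair: a 4 x 2 matrix of net inputs
# to the (L, R) comparison nodes of each attribute network. An absent
# hundredth digit contributes a zero input bank.
trial_evidence <- function(model, pair) {
  dW <- model$digit$W
  lW <- model$length$W
  n <- model$digit$spec$n_nodes
  dcode <- function(j) model$digit$codes[, j + 1L]
  zero <- numeric(n)
  hb <- function(h) if (is.na(h)) zero else dcode(h)
  lcode <- function(l) model$length$codes[, l]
  ff <- rbind(
    unit = drop(dW %*% c(dcode(pair$unit1), dcode(pair$unit2))),
    tenth = drop(dW %*% c(dcode(pair$tenth1), dcode(pair$tenth2))),
    hundredth = drop(dW %*% c(hb(pair$hundredth1), hb(pair$hundredth2))),
    length = drop(lW %*% c(lcode(pair$len1), lcode(pair$len2))))
  colnames(ff) <- c("L", "R")
  ff
}

#' Conflict of the response layer
#'
#' The instantaneous conflict is the energy-style co-activation measure
#' \code{beta_con * |w_inh_resp| * aL * aR}: zero when either response node
#' is silent and strictly increasing in the product of the two response
#' activations. During a trial it is exponentially smoothed with rate
#' \code{lambda_con}.
#'
#' @param aL,aR response-node activations in [0, 1].
#' @param params a [dfc_control()] object.
#' @return non-negative scalar.
#' @export
conflict_energy <- function(aL, aR, params = dfc_control()) {
  stopifnot(aL >= 0, aL <= 1, aR >= 0, aR <= 1)
  params$beta_con * abs(params$w_inh_resp) * aL * aR
}

#' Hebbian adaptation of task-demand couplings
#'
#' After each trial the coupling of every task-demand node onto its
#' comparison network is updated by a conflict-gated Hebbian rule:
#' \code{w <- lambda_w * w + (1 - lambda_w) *
#'   (w0 + beta_w * alpha_w * conflict * pre * post)},
#' clipped to be non-negative, where \code{w0} is the attribute's baseline
#' task activation, \code{pre} the task-node activation (its baseline) and
#' \code{post} the attribute network's strongest comparison activation on
#' the trial. With zero conflict the couplings decay geometrically to their
#' baselines; high-conflict trials transiently strengthen the couplings of
#' the attributes that were active, which carries interference adaptation
#' (a Gratton-type sequence effect) from one trial to the next.
#'
#' @param couplings current coupling per attribute (named numeric, length
#'   4).
#' @param conflict the trial's smoothed conflict at decision time.
#' @param post strongest comparison-node activation per attribute at
#'   decision time.
#' @param params a [dfc_control()] object.
#' @return updated coupling vector.
#' @export
adapt_task_weights <- function(couplings, conflict, post,
                               params = dfc_control()) {
  w0 <- params$task_activation
  pre <- w0
  target <- w0 + params$beta_w * params$alpha_w * conflict * pre * post
  pmax(params$lambda_w * couplings + (1 - params$lambda_w) * target, 0)
}

# One step of the leaky network dynamics. State is a list with comparison
# activations `cmp` (4 x 2), response activations `resp` (length 2),
# smoothed `conflict` and `step`. Information cascades within a step
# (input -> comparison -> response); Gaussian noise perturbs every node's
# activation each step and activations are clipped to [0, 1].
step_core <- function(state, ff, couplings, params) {
  tau <- params$tau
  gain <- params$C * couplings
  arg <- params$beta_in * (gain * ff + W_INH_COMP * state$cmp[, 2:1])
  cmp <- tau * state$cmp + (1 - tau) * sigmoid(arg)
  if (params$noise_sd > 0)
    cmp <- cmp + stats::rnorm(8L, 0, params$noise_sd)
  cmp <- matrix(clip01(cmp), 4L, 2L)
  wr <- params$response_weight
  net <- c(sum(wr * cmp[, 1L]) + params$w_inh_resp * state$resp[2L],
           sum(wr * cmp[, 2L]) + params$w_inh_resp * state$resp[1L])
  resp <- tau * state$resp + (1 - tau) * net
  if (params$noise_sd > 0)
    resp <- resp + stats::rnorm(2L, 0, params$noise_sd)
  resp <- clip01(resp)
  conflict <- params$lambda_con * state$conflict +
    (1 - params$lambda_con) * conflict_energy(resp[1L], resp[2L], params)
  list(cmp = cmp, resp = resp, conflict = conflict, step = state$step + 1L)
}

W_INH_COMP <- -2

#' Advance the network dynamics by one step
#'
#' Exposed mainly for inspection and testing; [run_trial()] iterates this
#' update until a decision. Comparison nodes are leaky-integrated sigmoids
#' of their gained feedforward evidence minus lateral inhibition from the
#' opposing node; response nodes leaky-integrate the response-weighted
#' comparison activations minus response inhibition, clipped to [0, 1].
#'
#' @param state list with \code{cmp} (4 x 2 comparison activations),
#'   \code{resp} (length-2 response activations), \code{conflict} and
#'   \code{step}; use [trial_state()] for the zero initial state.
#' @param model a trained [dfc_model()].
#' @param pair one stimulus row (list with the digit fields of
#'   [dfc_stimuli()]).
#' @param params a [dfc_control()].
#' @param couplings task-demand couplings (defaults to the baseline task
#'   activations).
#' @return the updated state.
#' @export
step_dynamics <- function(state, model, pair, params = model$control,
                          couplings = params$task_activation) {
  if (state$step >= params$max_steps)
    stop("trial already at the maximum number of steps")
  step_core(state, trial_evidence(model, pair), couplings, params)
}

#' @rdname step_dynamics
#' @export
trial_state <- function() {
  list(cmp = matrix(0, 4L, 2L, dimnames = list(ATTRS, c("L", "R"))),
       resp = c(0, 0), conflict = 0, step = 0L)
}

# Core trial loop on precomputed evidence; returns steps, side (1, 2 or NA),
# final conflict and the per-attribute peak comparison activations.
sim_trial <- function(ff, couplings, params) {
  state <- trial_state()
  theta <- params$theta
  side <- NA_integer_
  post <- numeric(4L)
  repeat {
    state <- step_core(state, ff, couplings, params)
    post <- pmax(post, apply(state$cmp, 1L, max))
    a <- if (params$threshold_layer == "response") state$resp
         else apply(state$cmp, 2L, max)
    if (any(a >= theta)) {
      side <- if (a[1L] > a[2L]) 1L
              else if (a[2L] > a[1L]) 2L
              else sample(1:2, 1L)
      break
    }
    if (state$step >= params$max_steps) break
  }
  list(steps = state$step, side = side, conflict = state$conflict,
       post = post)
}

#' Simulate one comparison trial
#'
#' Iterates the network dynamics from a zero-activation state until a
#' response node reaches the threshold \code{theta} or \code{max_steps} is
#' hit. The response is the side of the first node to cross (the more
#' active node if both cross on the same step; an exact tie is resolved at
#' random). Capped trials have no response and count as errors.
#'
#' @inheritParams step_dynamics
#' @param couplings current task-demand couplings.
#' @return list of class \code{"dfc_trial"}: \code{steps} (the simulated
#'   RT), \code{response} (\code{"first"}, \code{"second"} or
#'   \code{"none"}), \code{correct}, \code{conflict} (smoothed conflict at
#'   decision) and \code{couplings} (the couplings after post-trial Hebbian
#'   adaptation).
#' @export
run_trial <- function(model, pair, params = model$control,
                      couplings = params$task_activation) {
  stopifnot(inherits(model, "dfc_model"))
  if (is.na(model$digit$accuracy) || model$digit$accuracy < 1)
    stop("digit comparison network is not fully trained")
  res <- sim_trial(trial_evidence(model, pair), couplings, params)
  response <- if (is.na(res$side)) "none" else c("first", "second")[res$side]
  correct <- !is.na(res$side) && response == pair$larger
  structure(list(
    steps = res$steps, response = response, correct = correct,
    conflict = res$conflict,
    couplings = adapt_task_weights(couplings, res$conflict, res$post,
                                   params)),
    class = "dfc_trial")
}

#' Steps for a comparison network alone to reach threshold
#'
#' Runs a single attribute network's leaky dynamics in isolation (no
#' response layer, no noise) and counts the steps until one of its
#' comparison nodes reaches \code{theta}. Used to verify that the broadly
#' tuned, more heavily trained number-of-digits comparison resolves faster
#' than the tenth-digit comparison.
#'
#' @param comp a [train_comparator()] object.
#' @param left,right attribute values.
#' @param gain multiplicative gain on the feedforward input (baseline
#'   \code{C} plus the attribute's task activation).
#' @param params a [dfc_control()].
#' @return integer steps (capped at \code{max_steps}).
#' @export
comparator_latency <- function(comp, left, right, gain,
                               params = dfc_control()) {
  x <- c(encode_value(left, comp$spec), encode_value(right, comp$spec))
  ff <- drop(comp$W %*% x)
  a <- c(0, 0)
  for (t in seq_len(params$max_steps)) {
    arg <- params$beta_in * (gain * ff + comp$w_inh * rev(a))
    a <- params$tau * a + (1 - params$tau) * sigmoid(arg)
    if (max(a) >= params$theta) return(t)
  }
  params$max_steps
}
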