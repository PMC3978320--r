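# Two-choice comparison networks: two concatenated place-coding banks (left
# value, right value) fully connected to two comparison nodes ("left larger",
# "right larger") with fixed lateral inhibition w_inh = -2 between them.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sample an ordered training pair under frequency-biased sampling
#'
#' Each member of the pair is drawn independently from the bank's value set
#' with probability proportional to its frequency weight; pairs with equal
#' values are redrawn (equality defines no comparison target). The default
#' digit weights over-represent 0 by 15\% and 1 by 5\% relative to the other
#' digits, so that comparisons involving small digits - especially zero -
#' are trained more often.
#'
#' @param n number of pairs to draw.
#' @param values integer values to sample from.
#' @param freq_weights positive relative sampling weight per value.
#' @return integer matrix with \code{n} rows and columns \code{left},
#'   \code{right}; rows never have equal entries.
#' @export
sample_training_pair <- function(n, values, freq_weights = rep(1, length(values))) {
  stopifnot(length(freq_weights) == length(values), all(freq_weights > 0))
  p <- freq_weights / sum(freq_weights)
  left <- sample(values, n, replace = TRUE, prob = p)
  right <- sample(values, n, replace = TRUE, prob = p)
  eq <- which(left == right)
  while (length(eq) > 0L) {
    right[eq] <- sample(values, length(eq), replace = TRUE, prob = p)
    eq <- eq[left[eq] == right[eq]]
  }
  cbind(left = left, right = right)
}

#' Train a two-choice comparison network with the delta rule
#'
#' Connection weights from the two input banks to the two comparison nodes
#' are initialised uniformly in [-1, 1] and updated per trial toward the
#' target (1, 0) when the left value is larger and (0, 1) otherwise:
#' \code{W <- W + rate * (target - sigmoid(W x)) x'}. Training is a static
#' single feedforward pass (the recurrent inhibition between comparison
#' nodes operates only during trial dynamics, not during training).
#'
#' @param spec a [tuning_spec()] describing each input bank.
#' @param n_trials number of training trials (120000 for the digit
#'   networks; 100000 for the 4-node number-of-digits network, which gives
#'   the length comparison roughly six times more training per ordered pair
#'   than any digit pair receives).
#' @param learning_rate constant delta-rule step size.
#' @param freq_weights relative sampling weight per encodable value.
#' @return an object of class \code{"dfc_comparator"}: the trained weight
#'   matrix \code{W} (2 x 2 n_nodes), the fixed lateral inhibition
#'   \code{w_inh = -2}, the training configuration, and the post-training
#'   \code{accuracy} over all ordered unequal value pairs.
#' @export
train_comparator <- function(spec, n_trials,
                             learning_rate = 0.05,
                             freq_weights = rep(1, length(spec$values))) {
  stopifnot(inherits(spec, "tuning_spec"), n_trials >= 0)
  n <- spec$n_nodes
  W <- matrix(stats::runif(2L * 2L * n, -1, 1), nrow = 2L)
  codes <- vapply(spec$values, encode_value, numeric(n), spec = spec)
  colnames(codes) <- spec$values
  if (n_trials > 0) {
    pairs <- sample_training_pair(n_trials, seq_along(spec$values), freq_weights)
    vals <- spec$values
    for (t in seq_len(n_trials)) {
      l <- pairs[t, 1L]; r <- pairs[t, 2L]
      x <- c(codes[, l], codes[, r])
      a <- sigmoid(W %*% x)
      target <- if (vals[l] > vals[r]) c(1, 0) else c(0, 1)
      W <- W + learning_rate * (target - a) %*% t(x)
    }
  }
  comp <- structure(
    list(W = W, w_inh = -2, spec = spec, codes = codes,
         n_trials = n_trials, learning_rate = learning_rate,
         freq_weights = freq_weights, accuracy = NA_real_),
    class = "dfc_comparator")
  comp$accuracy <- comparator_accuracy(comp)
  comp
}

#' Comparison-node activations for a pair of place codes
#'
#' Evaluates the comparison nodes for static inputs: the sigmoid of the
#' feedforward net input plus the lateral inhibition \code{w_inh} times the
#' opposing node's activation, iterated to a fixed point. During simulated
#' trials the same quantities are instead embedded in the control network's
#' leaky dynamics (see [run_trial()]).
#'
#' @param comp a trained [train_comparator()] object.
#' @param left,right either single integer values or place-code vectors of
#'   length \code{comp$spec$n_nodes}.
#' @param fixed_point iterate the mutual inhibition to convergence; if
#'   \code{FALSE}, a single feedforward pass with the opposing node at 0
#'   (the training regime).
#' @return named numeric vector \code{c(L = , R = )} in (0, 1): evidence
#'   that the left (right) value is the larger one.
#' @export
comparator_forward <- function(comp, left, right, fixed_point = TRUE) {
  stopifnot(inherits(comp, "dfc_comparator"))
  as_code <- function(v) {
    if (length(v) == 1L) return(encode_value(v, comp$spec))
    if (length(v) != comp$spec$n_nodes)
      stop(sprintf("input bank has %d nodes, got a code of length %d",
                   comp$spec$n_nodes, length(v)))
    v
  }
  x <- c(as_code(left), as_code(right))
  ff <- drop(comp$W %*% x)
  a <- sigmoid(ff)
  if (fixed_point) {
    for (i in 1:100) {
      a_new <- sigmoid(ff + comp$w_inh * rev(a))
      if (max(abs(a_new - a)) < 1e-10) { a <- a_new; break }
      a <- a_new
    }
  }
  names(a) <- c("L", "R")
  a
}

# Fraction of ordered unequal value pairs decided correctly (single
# feedforward pass, the criterion used at the end of training).
comparator_accuracy <- function(comp) {
  vals <- comp$spec$values
  grid <- expand.grid(l = seq_along(vals), r = seq_along(vals))
  grid <- grid[vals[grid$l] != vals[grid$r], ]
  ok <- mapply(function(l, r) {
    a <- sigmoid(drop(comp$W %*% c(comp$codes[, l], comp$codes[, r])))
    (vals[l] > vals[r]) == (a[1L] > a[2L])
  }, grid$l, grid$r)
  mean(ok)
}

#' @export
print.dfc_comparator <- function(x, ...) {
  cat(sprintf(
    "Two-choice comparison network: %d-node banks, sharpness %g\n",
    x$spec$n_nodes, x$spec$sharpness))
  cat(sprintf("  trained for %d trials (rate %g), accuracy %d/%d ordered pairs\n",
              x$n_trials, x$learning_rate,
              round(x$accuracy * sum(outer(x$spec$values, x$spec$values, "!="))),
              sum(outer(x$spec$values, x$spec$values, "!="))))
  invisible(x)
}

#' Write or read trained comparator weights as plain text
#'
#' The CSV carries one row per comparison node and one column per input
#' node; the header records the tuning specification and training
#' configuration as comment lines.
#'
#' @param comp a \code{dfc_comparator}.
#' @param path file path.
#' @return \code{read_comparator} returns a \code{dfc_comparator} (with
#'   accuracy recomputed from the restored weights).
#' @export
write_comparator <- function(comp, path) {
  hdr <- c(
    sprintf("# n_nodes: %d", comp$spec$n_nodes),
    sprintf("# sharpness: %.17g", comp$spec$sharpness),
    sprintf("# values: %s", paste(comp$spec$values, collapse = " ")),
    sprintf("# n_trials: %d", comp$n_trials),
    sprintf("# learning_rate: %.17g", comp$learning_rate),
    sprintf("# freq_weights: %s", paste(format(comp$freq_weights, digits = 17),
                                        collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(comp$W, digits = 17), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_comparator
#' @export
read_comparator <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  spec <- tuning_spec(as.integer(get("n_nodes")), as.numeric(get("sharpness")),
                      as.integer(strsplit(get("values"), " +")[[1]]))
  W <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)], sep = ","))
  dimnames(W) <- NULL
  comp <- structure(
    list(W = W, w_inh = -2, spec = spec,
         codes = vapply(spec$values, encode_value, numeric(spec$n_nodes),
                        spec = spec),
         n_trials = as.integer(get("n_trials")),
         learning_rate = as.numeric(get("learning_rate")),
         freq_weights = as.numeric(strsplit(get("freq_weights"), " +")[[1]]),
         accuracy = NA_real_),
    class = "dfc_comparator")
  comp$accuracy <- comparator_accuracy(comp)
  comp
}
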