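#' Tuning specification for a bank of magnitude-coded input nodes
#'
#' A place-coding bank represents one attribute value (a digit, or the number
#' of digits in a string) by graded activation over magnitude-ordered nodes.
#' The node for the encoded value is maximally active and activation falls
#' off exponentially with the distance between a node's preferred value and
#' the encoded value. Digit banks use 10 sharply tuned nodes; the
#' number-of-digits bank uses 4 broadly tuned nodes, reflecting the coarser
#' tuning of non-symbolic magnitude.
#'
#' @param n_nodes number of input nodes in the bank.
#' @param sharpness non-negative decay rate of the tuning curve; activation
#'   of node \code{i} for value \code{j} is
#'   \code{exp(-sharpness * abs(i - peak(j)))}.
#' @param values integer values the bank can encode, one node per value in
#'   increasing order: node \code{i} prefers the bank's \code{i}-th
#'   smallest value. For the digit bank (values 0-9) the peak node for
#'   digit \code{j} is therefore node \code{j + 1}; for the length bank
#'   (values 1-4) length \code{j} peaks at node \code{j}.
#' @return an object of class \code{"tuning_spec"}.
#' @seealso [encode_value()], [digit_spec()], [length_spec()]
#' @export
tuning_spec <- function(n_nodes, sharpness, values) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1, n_nodes == round(n_nodes))
  if (!is.numeric(sharpness) || length(sharpness) != 1L || sharpness < 0)
    stop("'sharpness' must be a single non-negative number")
  values <- as.integer(values)
  if (length(values) != n_nodes || any(diff(values) != 1L))
    stop("'values' must be a run of consecutive integers, one per node")
  structure(list(n_nodes = as.integer(n_nodes), sharpness = sharpness,
                 values = values),
            class = "tuning_spec")
}

#' @describeIn tuning_spec 10-node bank for digits 0-9 (sharpness 10).
#' @export
digit_spec <- function() tuning_spec(10L, 10, 0:9)

#' @describeIn tuning_spec 4-node bank for string lengths 1-4 (sharpness 1).
#' @export
length_spec <- function() tuning_spec(4L, 1, 1:4)

#' Encode an attribute value as a place code
#'
#' Activation of node \code{i} (1-based) for value \code{j} is
#' \code{exp(-sharpness * abs(i - peak(j)))} where \code{peak(j)} is the
#' node preferring \code{j}: exactly 1 at the peak node (node \code{j + 1}
#' for digits) and decaying symmetrically with node distance.
#'
#' @param j integer attribute value (a digit 0-9 for digit banks, a string
#'   length 1-4 for the length bank).
#' @param spec a [tuning_spec()].
#' @return numeric vector of length \code{spec$n_nodes} with values in
#'   (0, 1].
#' @examples
#' encode_value(3, digit_spec())   # peak at node 4
#' encode_value(2, length_spec())  # peak at node 3, neighbours exp(-1)
#' @export
encode_value <- function(j, spec) {
  stopifnot(inherits(spec, "tuning_spec"))
  if (length(j) != 1L || is.na(j) || j != round(j) || !(j %in% spec$values)) {
    kind <- if (spec$sharpness >= 10) "digit" else "number-of-digits"
    stop(sprintf("value %s is outside the admissible %s range [%d, %d]",
                 format(j), kind, min(spec$values), max(spec$values)))
  }
  i <- seq_len(spec$n_nodes)
  peak <- j - spec$values[1L] + 1L
  exp(-spec$sharpness * abs(i - peak))
}
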