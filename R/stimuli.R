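# Stimulus construction: pairs of decimal fractions with identical unit
# digits, classified by tenth-hundredth compatibility or string-length
# congruity, with per-cell distance and problem-size matching.

#' Parse a decimal-fraction string into positional digits
#'
#' @param x character like \code{"2.04"} (three digits) or \code{"2.4"}
#'   (two digits); unit digit 1-9, fractional digits 0-9.
#' @return list with \code{unit}, \code{tenth}, \code{hundredth} (\code{NA}
#'   when absent), \code{n_digits} (2 or 3) and numeric \code{value}.
#' @export
parse_decimal <- function(x) {
  stopifnot(length(x) == 1L)
  if (!grepl("^[1-9]\\.[0-9][0-9]?$", x))
    stop(sprintf("'%s' is not a decimal fraction of the form a.b or a.bc", x))
  d <- strsplit(sub("\\.", "", x), "")[[1]]
  d <- as.integer(d)
  list(unit = d[1L], tenth = d[2L],
       hundredth = if (length(d) == 3L) d[3L] else NA_integer_,
       n_digits = length(d), value = as.numeric(x))
}

format_decimal <- function(unit, tenth, hundredth) {
  if (is.na(hundredth)) sprintf("%d.%d", unit, tenth)
  else sprintf("%d.%d%d", unit, tenth, hundredth)
}

#' Classify a decimal-fraction pair
#'
#' Three-digit vs three-digit pairs with differing tenth digits are
#' \emph{compatible} when the tenth-digit comparison and the
#' hundredth-digit comparison point to the same number as larger, else
#' \emph{incompatible}. Pairs with differing string lengths are
#' \emph{congruent} when the number with more digits is also the
#' numerically larger one, else \emph{incongruent}. Pairs with identical
#' tenth digits are fillers and get the label \code{"none"}.
#'
#' @param a,b decimal-fraction strings (see [parse_decimal()]).
#' @return one of \code{"compatible"}, \code{"incompatible"},
#'   \code{"congruent"}, \code{"incongruent"}, \code{"none"}.
#' @examples
#' classify_pair("9.07", "9.39")  # compatible
#' classify_pair("3.29", "3.67")  # incompatible
#' classify_pair("2.7", "2.91")   # congruent
#' @export
classify_pair <- function(a, b) {
  pa <- parse_decimal(a); pb <- parse_decimal(b)
  if (pa$tenth == pb$tenth) return("none")
  if (pa$n_digits != pb$n_digits) {
    longer_larger <- (pa$n_digits > pb$n_digits) == (pa$value > pb$value)
    return(if (longer_larger) "congruent" else "incongruent")
  }
  if (is.na(pa$hundredth) || is.na(pb$hundredth) ||
      pa$hundredth == pb$hundredth) return("none")
  same_sign <- sign(pa$tenth - pb$tenth) == sign(pa$hundredth - pb$hundredth)
  if (same_sign) "compatible" else "incompatible"
}

#' Distance and problem-size metrics of a pair
#'
#' @param a,b decimal-fraction strings.
#' @return named numeric vector: \code{overall} (absolute value
#'   difference), \code{tenth} and \code{hundredth} absolute digit
#'   distances (an absent hundredth digit counts as 0 for the metric), and
#'   \code{problem_size} (sum of the two values).
#' @export
pair_metrics <- function(a, b) {
  pa <- parse_decimal(a); pb <- parse_decimal(b)
  h <- function(p) if (is.na(p$hundredth)) 0L else p$hundredth
  c(overall = abs(pa$value - pb$value),
    tenth = abs(pa$tenth - pb$tenth),
    hundredth = abs(h(pa) - h(pb)),
    problem_size = pa$value + pb$value)
}

#' Per-cell matching targets for the critical stimulus cells
#'
#' Target means (and tolerances, taken as the reported dispersions) for
#' overall distance, tenth distance, hundredth distance and problem size in
#' each decimal type x relation cell. The a.0c cells have a lower problem
#' size than the others because one member's fractional part starts with a
#' zero, which is definitional rather than a matching failure.
#'
#' @return data.frame with one row per (type, relation) cell.
#' @export
matching_targets <- function() {
  data.frame(
    type = rep(c("a.0c", "a.b0", "a.bc", "a.b"), each = 2L),
    relation = c("compatible", "incompatible", "compatible", "incompatible",
                 "compatible", "incompatible", "congruent", "incongruent"),
    overall = c(0.40, 0.41, 0.40, 0.40, 0.40, 0.40, 0.40, 0.40),
    overall_sd = rep(0.02, 8L),
    tenth = c(3.66, 4.42, 3.69, 4.37, 3.67, 4.39, 3.67, 4.39),
    tenth_sd = c(0.25, 0.22, 0.25, 0.22, 0.23, 0.17, 0.23, 0.17),
    hundredth = c(3.48, 3.44, 3.62, 3.56, 3.50, 3.48, 3.77, 3.69),
    hundredth_sd = c(0.15, 0.26, 0.15, 0.26, 0.23, 0.14, 0.23, 0.14),
    problem_size = c(10.62, 10.50, 11.36, 10.85, 11.26, 10.79, 11.23, 10.80),
    problem_size_sd = c(0.63, 0.47, 0.63, 0.47, 0.50, 0.35, 0.50, 0.35),
    stringsAsFactors = FALSE)
}

# Enumerate every admissible (reference, other) digit combination for one
# critical cell. The reference member is always the all-nonzero a.bc
# number; units are identical and all other digits differ.
enumerate_cell <- function(type, relation) {
  g <- expand.grid(u = 1:9, b = 1:9, c = 1:9, b2 = 0:9, c2 = 0:9)
  keep <- switch(paste(type, relation),
    "a.0c compatible"   = g$b2 == 0 & g$c2 >= 1 & g$c2 < g$c,
    "a.0c incompatible" = g$b2 == 0 & g$c2 >= 1 & g$c2 > g$c,
    "a.b0 compatible"   = g$c2 == 0 & g$b2 >= 1 & g$b2 < g$b,
    "a.b0 incompatible" = g$c2 == 0 & g$b2 >= 1 & g$b2 > g$b,
    "a.bc compatible"   = g$b2 >= 1 & g$c2 >= 1 & g$b2 != g$b & g$c2 != g$c &
                          sign(g$b - g$b2) == sign(g$c - g$c2),
    "a.bc incompatible" = g$b2 >= 1 & g$c2 >= 1 & g$b2 != g$b & g$c2 != g$c &
                          sign(g$b - g$b2) != sign(g$c - g$c2),
    "a.b congruent"     = g$c2 == -1,  # placeholder, handled below
    "a.b incongruent"   = g$c2 == -1,
    stop("unknown cell"))
  if (type == "a.b") {
    g <- expand.grid(u = 1:9, b = 1:9, c = 1:9, b2 = 1:9, c2 = NA_integer_)
    keep <- if (relation == "congruent") g$b2 < g$b else g$b2 > g$b
  }
  cells <- g[keep & in_value_range(g), , drop = FALSE]
  # Keep each pair's own overall distance near the matched cell mean of
  # ~0.40: pairs further than a factor ~2 from it would make the matching
  # nominal only. This also reproduces the asymmetry of the matched design:
  # with overall distance equated, incompatible/incongruent pairs (where
  # the hundredth comparison opposes the tenth) require larger tenth
  # distances than compatible ones.
  ov <- cell_metrics(cells)[, "overall"]
  cells <- cells[ov >= 0.2 & ov <= 0.9, , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

cell_metrics <- function(cand) {
  v1 <- cand$u + cand$b / 10 + cand$c / 100
  h2 <- ifelse(is.na(cand$c2), 0L, cand$c2)
  v2 <- cand$u + cand$b2 / 10 + h2 / 100
  cbind(overall = abs(v1 - v2), tenth = abs(cand$b - cand$b2),
        hundredth = abs(cand$c - h2), problem_size = v1 + v2)
}

# Pick n candidates whose metric means match the cell targets: start from a
# random subset and accept random single-item swaps that reduce the summed
# squared standardised deviation. The search aims at the target means
# themselves (it stops early only once every mean is within a quarter of
# its tolerance), so cell means centre on the targets instead of drifting
# to the near edge of the tolerance band.
match_subset <- function(metrics, n, target, tol, budget = 10000L) {
  m <- nrow(metrics)
  stopifnot(m >= n)
  idx <- sample.int(m, n)
  dev <- function(i) {
    mu <- colMeans(metrics[i, , drop = FALSE])
    sum(((mu - target) / tol)^2)
  }
  ok <- function(i, slack) {
    mu <- colMeans(metrics[i, , drop = FALSE])
    all(abs(mu - target) <= slack * tol)
  }
  j_cur <- dev(idx)
  for (k in seq_len(budget)) {
    if (ok(idx, 0.25)) break
    out <- sample.int(n, 1L)
    repl <- sample.int(m, 1L)
    if (repl %in% idx) next
    cand <- idx; cand[out] <- repl
    j_new <- dev(cand)
    if (j_new < j_cur) { idx <- cand; j_cur <- j_new }
  }
  list(idx = idx, matched = ok(idx, 1), deviation = j_cur)
}

# Fillers share the tenth digit, so neither the decision-relevant tenth
# comparison nor the unit comparison separates them; the three-digit
# member (whose non-zero hundredth makes it the larger number) differs
# from its two-digit partner in string length.
filler_pool <- function() {
  g <- expand.grid(u = 1:9, b = 1:9, c = 1:9, b2 = 1:9, c2 = NA_integer_)
  g <- g[g$b2 == g$b & in_value_range(g), ]
  rownames(g) <- NULL
  g
}

# both members must lie in the design range [1.04, 9.96]
in_value_range <- function(g) {
  v1 <- g$u + g$b / 10 + g$c / 100
  v2 <- g$u + g$b2 / 10 + ifelse(is.na(g$c2), 0L, g$c2) / 100
  v1 >= 1.04 & v1 <= 9.96 & v2 >= 1.04 & v2 <= 9.96
}

#' Generate a constrained decimal-fraction stimulus set
#'
#' Builds the full item list for the simulated comparison task: four
#' critical pair types (one member always the all-nonzero a.bc reference
#' number) split evenly into compatible/incompatible or congruent/
#' incongruent cells and matched per cell on overall, tenth and hundredth
#' distance and problem size ([matching_targets()]); plus filler pairs with
#' identical tenth digits (three- vs two-digit pairs, so that neither the
#' tenth nor the unit comparison separates the pair). The position of the
#' larger number is counterbalanced within every cell. With the defaults
#' (40 pairs per cell, 120 fillers) the set has 440 items.
#'
#' @param n_per_cell critical pairs per (type, relation) cell.
#' @param n_fillers number of filler pairs (even).
#' @param targets matching targets, see [matching_targets()].
#' @param budget swap iterations allowed per cell when matching.
#' @return data.frame of class \code{"dfc_stimuli"}: item id, type,
#'   relation, the two displayed numbers \code{first} and \code{second}
#'   (display order already counterbalanced), their digits, lengths and
#'   values, \code{larger} (\code{"first"}/\code{"second"}) and the pair
#'   metrics. Attribute \code{"unmatched"} names any cell whose metric
#'   means could not be brought within tolerance inside the budget.
#' @export
dfc_stimuli <- function(n_per_cell = 40L, n_fillers = 120L,
                        targets = matching_targets(), budget = 10000L) {
  stopifnot(n_fillers %% 2L == 0L, n_per_cell >= 2L)
  rows <- list()
  unmatched <- character()
  for (i in seq_len(nrow(targets))) {
    tt <- targets[i, ]
    pool <- enumerate_cell(tt$type, tt$relation)
    met <- cell_metrics(pool)
    sel <- match_subset(met, n_per_cell,
                        target = c(tt$overall, tt$tenth, tt$hundredth,
                                   tt$problem_size),
                        tol = c(tt$overall_sd, tt$tenth_sd, tt$hundredth_sd,
                                tt$problem_size_sd),
                        budget = budget)
    if (!sel$matched)
      unmatched <- c(unmatched, sprintf("%s/%s", tt$type, tt$relation))
    rows[[length(rows) + 1L]] <-
      build_rows(pool[sel$idx, ], tt$type, tt$relation)
  }
  pool <- filler_pool()
  sel <- pool[sample.int(nrow(pool), n_fillers), ]
  rows[[length(rows) + 1L]] <- build_rows(sel, "filler", "none")
  out <- do.call(rbind, rows)
  out$item <- sprintf("%s_%s_%03d", out$type, substr(out$relation, 1, 6),
                      stats::ave(seq_len(nrow(out)),
                                 paste(out$type, out$relation),
                                 FUN = seq_along))
  out <- out[, c("item", setdiff(names(out), "item"))]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  class(out) <- c("dfc_stimuli", "data.frame")
  out
}

# Turn selected digit combinations into display rows, counterbalancing the
# position of the larger number within the cell.
build_rows <- function(sel, type, relation) {
  n <- nrow(sel)
  ref <- mapply(format_decimal, sel$u, sel$b, sel$c)
  oth <- mapply(format_decimal, sel$u, sel$b2, sel$c2)
  v_ref <- sel$u + sel$b / 10 + sel$c / 100
  v_oth <- sel$u + sel$b2 / 10 + ifelse(is.na(sel$c2), 0L, sel$c2) / 100
  larger_first <- sample(rep(c(TRUE, FALSE), length.out = n))
  ref_is_larger <- v_ref > v_oth
  ref_first <- ref_is_larger == larger_first
  first <- ifelse(ref_first, ref, oth)
  second <- ifelse(ref_first, oth, ref)
  met <- t(mapply(pair_metrics, first, second))
  p1 <- lapply(first, parse_decimal)
  p2 <- lapply(second, parse_decimal)
  gi <- function(p, f) vapply(p, `[[`, numeric(1), f)
  data.frame(
    type = type, relation = relation, first = first, second = second,
    unit1 = gi(p1, "unit"), tenth1 = gi(p1, "tenth"),
    hundredth1 = gi(p1, "hundredth"), len1 = gi(p1, "n_digits"),
    unit2 = gi(p2, "unit"), tenth2 = gi(p2, "tenth"),
    hundredth2 = gi(p2, "hundredth"), len2 = gi(p2, "n_digits"),
    value1 = gi(p1, "value"), value2 = gi(p2, "value"),
    larger = ifelse(larger_first, "first", "second"),
    overall_distance = met[, "overall"], tenth_distance = met[, "tenth"],
    hundredth_distance = met[, "hundredth"],
    problem_size = met[, "problem_size"],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.dfc_stimuli <- function(x, ...) {
  cat(sprintf("Decimal-fraction stimulus set: %d pairs\n", nrow(x)))
  print(table(type = x$type, relation = x$relation))
  agg <- stats::aggregate(
    x[x$type != "filler",
      c("overall_distance", "tenth_distance", "hundredth_distance",
        "problem_size")],
    by = list(type = x$type[x$type != "filler"],
              relation = x$relation[x$type != "filler"]),
    FUN = mean)
  cat("\nCell means (critical pairs):\n")
  print(agg, digits = 3)
  if (length(attr(x, "unmatched")))
    cat("Unmatched cells:", paste(attr(x, "unmatched"), collapse = ", "), "\n")
  invisible(x)
}

#' Write or read a stimulus set as CSV
#' @param stimuli a \code{dfc_stimuli} data.frame.
#' @param path file path.
#' @return \code{read_stimuli} returns the \code{dfc_stimuli} data.frame.
#' @export
write_stimuli <- function(stimuli, path) {
  utils::write.csv(as.data.frame(stimuli), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(first = "character",
                                        second = "character"))
  class(out) <- c("dfc_stimuli", "data.frame")
  out
}
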