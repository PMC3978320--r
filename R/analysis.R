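# Statistical summaries of simulated runs: variance-stabilised error
# rates, repeated-measures ANOVA with Greenhouse-Geisser correction,
# paired tests, partial eta-squared effect sizes.

#' Arcsine square-root transform of a proportion
#'
#' The variance-stabilising transform applied to error proportions before
#' analysis: \code{asin(sqrt(p))}. Strictly monotone on [0, 1], so the
#' ordering of condition error rates is preserved.
#'
#' @param p proportion(s) in [0, 1].
#' @return transformed value(s) in [0, pi/2].
#' @export
arcsine_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-participant ANOVA for one or two factors. Sums of squares
#' come from the multivariate linear model route; for effects with more
#' than one degree of freedom the sphericity assumption is checked with
#' Mauchly's test and, when violated at alpha = 0.05, the
#' Greenhouse-Geisser corrected p-value is reported together with the
#' epsilon coefficient and the uncorrected degrees of freedom. Partial
#' eta-squared is \code{SS_effect / (SS_effect + SS_error)}.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param id name of the participant column.
#' @param within character vector (length 1 or 2) of within-participant
#'   factor columns.
#' @return data.frame of class \code{"dfc_anova"} with one row per effect:
#'   \code{F}, \code{df1}, \code{df2}, \code{gg_eps}, \code{mauchly_p},
#'   \code{p} (GG-corrected when sphericity is rejected), \code{p_uncorrected}
#'   and \code{eta_p_sq}.
#' @export
rm_anova <- function(data, dv, id, within) {
  stopifnot(is.data.frame(data), length(within) %in% 1:2,
            all(c(dv, id, within) %in% names(data)))
  cell <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  counts <- table(data[[id]], cell)
  if (any(counts != 1L))
    stop("design is unbalanced: each participant needs exactly one value per ",
         paste(within, collapse = " x "), " cell")
  fac <- lapply(data[within], function(f) factor(f))
  levs <- lapply(fac, levels)
  idata <- rev(expand.grid(rev(levs), stringsAsFactors = TRUE))
  names(idata) <- within
  wide <- stats::reshape(
    data.frame(id = data[[id]], cell = cell, y = data[[dv]]),
    idvar = "id", timevar = "cell", direction = "wide")
  cols <- paste0("y.", do.call(function(...) interaction(..., lex.order = TRUE),
                               idata))
  Y <- as.matrix(wide[, cols])
  mod <- stats::lm(Y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      # expected in small or degenerate designs: HF epsilon capped at 1,
      # or sphericity tests unavailable for a zero error SSP matrix
      if (grepl("HF eps|error SSP matrix", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  uni <- s$univariate.tests
  effects <- setdiff(rownames(uni), "(Intercept)")
  adj <- s$pval.adjustments
  sph <- s$sphericity.tests
  out <- do.call(rbind, lapply(effects, function(e) {
    df1 <- uni[e, "num Df"]; df2 <- uni[e, "den Df"]
    ss <- uni[e, "Sum Sq"]; sse <- uni[e, "Error SS"]
    p_unc <- uni[e, "Pr(>F)"]
    gg <- if (!is.null(adj) && e %in% rownames(adj)) adj[e, "GG eps"] else NA_real_
    p_gg <- if (!is.null(adj) && e %in% rownames(adj)) adj[e, "Pr(>F[GG])"] else NA_real_
    mau <- if (!is.null(sph) && e %in% rownames(sph)) sph[e, "p-value"] else NA_real_
    violated <- !is.na(mau) && mau < 0.05
    data.frame(effect = e, F = uni[e, "F value"], df1 = df1, df2 = df2,
               gg_eps = gg, mauchly_p = mau,
               p = if (violated) p_gg else p_unc,
               p_uncorrected = p_unc,
               eta_p_sq = ss / (ss + sse),
               sphericity_violated = violated,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dfc_anova", "data.frame")
  out
}

#' @export
print.dfc_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- round(y$F, 2)
  y$gg_eps <- round(y$gg_eps, 2)
  y$eta_p_sq <- round(y$eta_p_sq, 2)
  y$p <- signif(y$p, 3)
  y$p_uncorrected <- signif(y$p_uncorrected, 3)
  y$mauchly_p <- signif(y$mauchly_p, 3)
  print(y)
  invisible(x)
}

#' Paired comparison of two within-participant conditions
#'
#' Paired t-test reported in F-form (\code{F(1, n-1) = t^2}) with partial
#' eta-squared \code{t^2 / (t^2 + df)}. A zero-variance non-zero
#' difference is flagged as degenerate.
#'
#' @param x,y equal-length paired condition values (one per participant).
#' @return list of class \code{"dfc_paired"}: \code{t}, \code{F},
#'   \code{df1}, \code{df2}, \code{p}, \code{eta_p_sq}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length")
  d <- x - y
  n <- length(d)
  if (stats::sd(d) <= .Machine$double.eps^0.5 * max(abs(mean(d)), 1)) {
    tval <- if (mean(d) == 0) 0 else Inf
    return(structure(list(t = tval, F = tval^2, df1 = 1, df2 = n - 1,
                          p = if (tval == 0) 1 else 0,
                          eta_p_sq = if (tval == 0) 0 else 1,
                          mean_diff = mean(d), degenerate = mean(d) != 0),
                     class = "dfc_paired"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tval <- unname(tt$statistic)
  structure(list(t = tval, F = tval^2, df1 = 1, df2 = n - 1,
                 p = tt$p.value,
                 eta_p_sq = tval^2 / (tval^2 + (n - 1)),
                 mean_diff = mean(d), degenerate = FALSE),
            class = "dfc_paired")
}

#' @export
print.dfc_paired <- function(x, ...) {
  cat(sprintf("paired test: F(1,%d) = %.2f, p = %.4g, eta_p^2 = %.2f, mean diff = %.3f\n",
              x$df2, x$F, x$p, x$eta_p_sq, x$mean_diff))
  if (x$degenerate) cat("  (degenerate: zero-variance non-zero difference)\n")
  invisible(x)
}

# Per-participant cell means; errors if a participant x cell combination
# has no trials.
cell_means <- function(trials, value, factors, id = "participant") {
  agg <- stats::aggregate(trials[[value]],
                          by = c(trials[id], trials[factors]), FUN = mean)
  names(agg)[ncol(agg)] <- value
  full <- prod(vapply(c(trials[id], trials[factors]),
                      function(f) length(unique(f)), 1L))
  if (nrow(agg) < full) {
    have <- do.call(paste, agg[c(id, factors)])
    want <- do.call(paste, rev(expand.grid(
      rev(lapply(c(trials[id], trials[factors]), unique)))))
    stop("empty design cell(s): ",
         paste(setdiff(want, have), collapse = "; "))
  }
  agg
}

#' Effect summaries of a simulated run
#'
#' Reproduces the analyses of the simulated experiment: (i) 3 x 2
#' repeated-measures ANOVAs (decimal type a.0c/a.b0/a.bc x
#' tenth-hundredth compatibility) on correct-trial mean steps and on
#' arcsine-transformed error rates, with Bonferroni-corrected pairwise
#' comparisons of the decimal types; (ii) paired tests of the
#' string-length congruity effect on the a.b pairs, for steps and
#' arcsine-transformed error rates. Error-rate tables report raw
#' percentages; their tests run on the transformed values.
#'
#' @param run a [run_experiment()] result.
#' @return list of class \code{"dfc_summary"}: \code{loss_fraction},
#'   \code{rt_cells}, \code{rt_anova}, \code{rt_pairwise},
#'   \code{er_cells}, \code{er_anova}, and \code{congruity} (cell means
#'   and paired tests for RT and ER).
#' @export
summarize_run <- function(run) {
  stopifnot(is.data.frame(run))
  ex <- exclude_errors(run)
  ok <- ex$trials
  crit <- ok[ok$type %in% c("a.0c", "a.b0", "a.bc"), ]
  rt_pp <- cell_means(crit, "steps", c("type", "relation"))
  rt_anova <- rm_anova(rt_pp, "steps", "participant", c("type", "relation"))
  type_pp <- cell_means(crit, "steps", "type")
  wide_t <- stats::reshape(type_pp, idvar = "participant", timevar = "type",
                           direction = "wide")
  combs <- utils::combn(c("a.0c", "a.b0", "a.bc"), 2)
  rt_pairwise <- data.frame(
    a = combs[1, ], b = combs[2, ],
    p = apply(combs, 2, function(cc) {
      pt <- paired_test(wide_t[[paste0("steps.", cc[1])]],
                        wide_t[[paste0("steps.", cc[2])]])
      min(1, pt$p * ncol(combs))  # Bonferroni, family of 3
    }))

  allc <- run[run$type %in% c("a.0c", "a.b0", "a.bc"), ]
  allc$error <- as.numeric(!allc$correct)
  er_pp <- cell_means(allc, "error", c("type", "relation"))
  er_pp$asin_er <- arcsine_transform(er_pp$error)
  er_anova <- rm_anova(er_pp, "asin_er", "participant", c("type", "relation"))

  ab_ok <- ok[ok$type == "a.b", ]
  ab_all <- run[run$type == "a.b", ]
  ab_all$error <- as.numeric(!ab_all$correct)
  rt_ab <- cell_means(ab_ok, "steps", "relation")
  er_ab <- cell_means(ab_all, "error", "relation")
  wide_rt <- stats::reshape(rt_ab, idvar = "participant",
                            timevar = "relation", direction = "wide")
  wide_er <- stats::reshape(er_ab, idvar = "participant",
                            timevar = "relation", direction = "wide")
  congruity <- list(
    rt_means = tapply(ab_ok$steps, ab_ok$relation, mean),
    er_means = 100 * c(congruent = mean(ab_all$error[ab_all$relation == "congruent"]),
                       incongruent = mean(ab_all$error[ab_all$relation == "incongruent"])),
    rt_test = paired_test(wide_rt$steps.incongruent, wide_rt$steps.congruent),
    er_test = paired_test(arcsine_transform(wide_er$error.incongruent),
                          arcsine_transform(wide_er$error.congruent)))

  rt_cells <- stats::aggregate(steps ~ type + relation, rt_pp, mean)
  er_cells <- stats::aggregate(error ~ type + relation, er_pp, mean)
  er_cells$error <- 100 * er_cells$error
  names(er_cells)[names(er_cells) == "error"] <- "error_pct"

  structure(list(loss_fraction = ex$loss_fraction, rt_cells = rt_cells,
                 rt_anova = rt_anova, rt_pairwise = rt_pairwise,
                 er_cells = er_cells, er_anova = er_anova,
                 congruity = congruity),
            class = "dfc_summary")
}

#' @export
print.dfc_summary <- function(x, ...) {
  cat(sprintf("Error exclusion: %.2f%% of trials\n\n", 100 * x$loss_fraction))
  cat("Simulated RT (steps, correct trials), type x compatibility:\n")
  print(x$rt_cells, digits = 4)
  cat("\nRT ANOVA:\n"); print(x$rt_anova)
  cat("\nPairwise type comparisons (Bonferroni):\n")
  print(transform(x$rt_pairwise, p = signif(p, 3)))
  cat("\nError rates (%), type x compatibility:\n")
  print(x$er_cells, digits = 3)
  cat("\nER ANOVA (arcsine-transformed):\n"); print(x$er_anova)
  cat("\nString-length congruity (a.b pairs):\n")
  cat("  RT  :", sprintf("%s = %.2f", names(x$congruity$rt_means),
                         x$congruity$rt_means), "\n   ")
  print(x$congruity$rt_test)
  cat("  ER %:", sprintf("%s = %.2f", names(x$congruity$er_means),
                         x$congruity$er_means), "\n   ")
  print(x$congruity$er_test)
  invisible(x)
}
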