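# Independent oracle: textbook sums-of-squares decomposition for a fully
# balanced one-observation-per-cell within-participant design.
oracle_rm_anova <- function(y, id, A, B) {
  G <- mean(y)
  tbl <- function(...) tapply(y, list(...), mean)
  P <- tbl(id); Am <- tbl(A); Bm <- tbl(B)
  PA <- tbl(id, A); PB <- tbl(id, B); AB <- tbl(A, B)
  n <- length(P); a <- length(Am); b <- length(Bm)
  ssA <- n * b * sum((Am - G)^2)
  ssAS <- b * sum(sweep(sweep(PA, 1, P - G), 2, Am)^2)
  ssB <- n * a * sum((Bm - G)^2)
  ssBS <- a * sum(sweep(sweep(PB, 1, P - G), 2, Bm)^2)
  ssAB <- n * sum((sweep(sweep(AB, 1, Am - G), 2, Bm))^2)
  resid <- y
  for (i in seq_along(y)) {
    ii <- as.character(id[i]); jj <- as.character(A[i]); kk <- as.character(B[i])
    resid[i] <- y[i] - PA[ii, jj] - PB[ii, kk] - AB[jj, kk] +
      P[ii] + Am[jj] + Bm[kk] - G
  }
  ssABS <- sum(resid^2)
  f <- function(ss, df, sse, dfe) {
    Fv <- (ss / df) / (sse / dfe)
    c(F = Fv, p = pf(Fv, df, dfe, lower.tail = FALSE),
      eta = ss / (ss + sse))
  }
  rbind(A = f(ssA, a - 1, ssAS, (a - 1) * (n - 1)),
        B = f(ssB, b - 1, ssBS, (b - 1) * (n - 1)),
        AB = f(ssAB, (a - 1) * (b - 1), ssABS, (a - 1) * (b - 1) * (n - 1)))
}

bench_data <- function(n = 10) {
  set.seed(314)
  g <- expand.grid(participant = factor(1:n),
                   type = factor(c("x", "y", "z")),
                   relation = factor(c("c", "i")))
  g$value <- rnorm(nrow(g)) +
    as.numeric(g$type) * 0.6 + (as.numeric(g$relation) - 1.5) * 0.4 +
    rep(rnorm(n), 6)
  g
}

test_that("arcsine transform matches the closed form and preserves order", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.25), pi / 6)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.2), "proportion")
  expect_error(arcsine_transform(-0.1), "proportion")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  g <- bench_data()
  got <- rm_anova(g, "value", "participant", c("type", "relation"))
  want <- oracle_rm_anova(g$value, g$participant, g$type, g$relation)
  for (i in 1:3) {
    expect_equal(got$F[i], unname(want[i, "F"]), tolerance = 1e-6)
    expect_equal(got$p_uncorrected[i], unname(want[i, "p"]), tolerance = 1e-6)
    expect_equal(got$eta_p_sq[i], unname(want[i, "eta"]), tolerance = 1e-6)
  }
})

test_that("identical condition means give F = 0", {
  set.seed(42)
  g <- expand.grid(participant = factor(1:6), type = factor(c("x", "y", "z")))
  g$value <- rep(rnorm(6), 3) + rnorm(18)
  # remove the condition effect exactly, keeping participant x condition noise
  g$value <- g$value - ave(g$value, g$type) + mean(g$value)
  res <- rm_anova(g, "value", "participant", "type")
  expect_equal(res$F[1], 0, tolerance = 1e-10)
})

test_that("a two-level within factor reproduces the squared paired t", {
  set.seed(21)
  g <- expand.grid(participant = factor(1:12), cond = factor(c("a", "b")))
  g$value <- rnorm(24) + (g$cond == "b") * 0.5
  res <- rm_anova(g, "value", "participant", "cond")
  x <- g$value[g$cond == "a"]; y <- g$value[g$cond == "b"]
  pt <- paired_test(x, y)
  expect_equal(res$F[1], pt$F, tolerance = 1e-8)
  expect_equal(res$p[1], pt$p, tolerance = 1e-8)
})

test_that("sphericity violations trigger the Greenhouse-Geisser correction", {
  set.seed(5)
  n <- 14
  base <- rnorm(n)
  g <- data.frame(
    participant = factor(rep(1:n, 3)),
    cond = factor(rep(c("a", "b", "c"), each = n)),
    value = c(base + rnorm(n, sd = 0.05),
              base + rnorm(n, sd = 0.05) + 1.5,
              rnorm(n, sd = 3)))
  res <- rm_anova(g, "value", "participant", "cond")
  expect_lt(res$mauchly_p[1], 0.05)
  expect_true(res$sphericity_violated[1])
  expect_lt(res$gg_eps[1], 1)
  expect_gt(res$F[1], 1)
  expect_gt(res$p[1], res$p_uncorrected[1])  # corrected p is less extreme
})

test_that("unbalanced designs are rejected", {
  g <- bench_data()[-1, ]
  expect_error(rm_anova(g, "value", "participant", c("type", "relation")),
               "unbalanced")
})

test_that("paired tests report t, F = t^2 and flag degenerate inputs", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  y <- c(1.0, 0.7, 1.1, 1.0, 0.8)
  pt <- paired_test(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(pt$t, t_manual, tolerance = 1e-10)
  expect_equal(pt$F, t_manual^2, tolerance = 1e-10)
  expect_equal(pt$eta_p_sq, t_manual^2 / (t_manual^2 + 4), tolerance = 1e-10)

  same <- paired_test(x, x)
  expect_equal(same$t, 0)
  expect_false(same$degenerate)

  degen <- paired_test(x, x + 1)
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(paired_test(x, y[-1]), "equal length")
})

test_that("run summaries aggregate by participant and reject empty cells", {
  cells <- expand.grid(participant = 1:4,
                       type = c("a.0c", "a.b0", "a.bc"),
                       relation = c("compatible", "incompatible"),
                       rep = 1:3)
  run <- data.frame(
    participant = cells$participant,
    trial = seq_len(nrow(cells)),
    item = paste0("i", seq_len(nrow(cells))),
    type = as.character(cells$type),
    relation = as.character(cells$relation),
    steps = 9 + (cells$type == "a.bc") * 1 + cells$participant * 0.1,
    response = "first", correct = TRUE, conflict = 0)
  ab <- expand.grid(participant = 1:4,
                    relation = c("congruent", "incongruent"), rep = 1:4)
  run_ab <- data.frame(
    participant = ab$participant, trial = 0, item = "x", type = "a.b",
    relation = as.character(ab$relation),
    steps = ifelse(ab$relation == "congruent", 9, 11),
    response = "first",
    correct = !(ab$relation == "incongruent" & ab$rep == 1), conflict = 0)
  s <- summarize_run(rbind(run, run_ab))
  expect_equal(s$loss_fraction, 4 / nrow(rbind(run, run_ab)))
  expect_equal(unname(s$congruity$er_means["incongruent"]), 25)
  expect_equal(unname(s$congruity$er_means["congruent"]), 0)
  expect_gt(s$congruity$rt_means["incongruent"],
            s$congruity$rt_means["congruent"])
  abc <- s$rt_cells$steps[s$rt_cells$type == "a.bc"]
  a0c <- s$rt_cells$steps[s$rt_cells$type == "a.0c"]
  expect_true(all(abc > a0c))

  broken <- rbind(run, run_ab)
  broken <- broken[!(broken$participant == 2 & broken$type == "a.0c" &
                       broken$relation == "compatible"), ]
  expect_error(summarize_run(broken), "a.0c")
})
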