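test_that("conflict is an energy-style co-activation measure", {
  expect_equal(conflict_energy(0, 0.9), 0)
  expect_equal(conflict_energy(0.9, 0), 0)
  expect_equal(conflict_energy(0, 0), 0)
  expect_gt(conflict_energy(0.8, 0.8), conflict_energy(0.5, 0.5))
  expect_error(conflict_energy(-0.1, 0.5))
})

test_that("task couplings decay to baseline without conflict and grow with it", {
  params <- dfc_control()
  w0 <- params$task_activation
  w <- w0 * 2
  for (i in 1:60) w <- adapt_task_weights(w, 0, rep(0.5, 4), params)
  expect_equal(unname(w), unname(w0), tolerance = 1e-6)

  post <- c(0.5, 0.9, 0.5, 0.8)
  hi <- adapt_task_weights(w0, 0.4, post, params)
  lo <- adapt_task_weights(w0, 0.05, post, params)
  expect_gt(hi["tenth"], lo["tenth"])
  expect_gt(hi["tenth"], w0["tenth"])
  expect_true(all(hi >= 0))
})

test_that("one incongruent (high-conflict) trial strengthens couplings more than a congruent one", {
  m <- test_model()
  params <- noise_free(m)
  base <- params$task_activation
  con <- run_trial(m, make_pair("2.7", "2.91"), params, base)
  inc <- run_trial(m, make_pair("7.14", "7.6"), params, base)
  expect_gt(inc$conflict, con$conflict)
  expect_gt(inc$couplings["tenth"], con$couplings["tenth"])
  # interference adaptation: an incongruent trial is resolved at least as
  # fast after an incongruent predecessor as after a congruent one
  after_inc <- run_trial(m, make_pair("6.13", "6.7"), params, inc$couplings)
  after_con <- run_trial(m, make_pair("6.13", "6.7"), params, con$couplings)
  expect_lte(after_inc$steps, after_con$steps)
})

test_that("dynamics are deterministic without noise and frozen at tau = 1", {
  m <- test_model()
  pair <- make_pair("2.04", "2.91")
  params <- noise_free(m)
  set.seed(1); t1 <- run_trial(m, pair, params)
  set.seed(999); t2 <- run_trial(m, pair, params)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$response, t2$response)

  frozen <- params; frozen$tau <- 1
  st <- trial_state()
  st2 <- step_dynamics(st, m, pair, frozen)
  expect_equal(st2$cmp, st$cmp, ignore_attr = TRUE)
  expect_equal(st2$resp, st$resp)
  expect_equal(st2$step, 1L)
})

test_that("stepping past the cap is rejected", {
  m <- test_model()
  st <- trial_state(); st$step <- m$control$max_steps
  expect_error(step_dynamics(st, m, make_pair("2.04", "2.91")), "maximum")
})

test_that("a noise-free trial picks the numerically larger decimal", {
  m <- test_model()
  res <- run_trial(m, make_pair("2.04", "2.91"), noise_free(m))
  expect_equal(res$response, "second")
  expect_true(res$correct)
  expect_lt(res$steps, 30)
  rev <- run_trial(m, make_pair("2.91", "2.04"), noise_free(m))
  expect_equal(rev$response, "first")
})

test_that("symmetric evidence never reaches threshold and caps as an error", {
  m <- test_model()
  res <- run_trial(m, make_pair("4.56", "4.56"), noise_free(m))
  expect_equal(res$steps, m$control$max_steps)
  expect_equal(res$response, "none")
  expect_false(res$correct)
})

test_that("an exact response tie at threshold is broken at random", {
  params <- noise_free(test_model())
  params$theta <- 0.3   # reachable by perfectly symmetric evidence
  ff <- matrix(1, 4, 2) # both sides receive identical net evidence
  sides <- replicate(40, dfcomp:::sim_trial(ff, params$task_activation,
                                            params)$side)
  expect_true(all(sides %in% 1:2))
  expect_gt(length(unique(sides)), 1)
})

test_that("congruent pairs are resolved faster than incongruent pairs under noise", {
  m <- test_model()
  set.seed(8)
  cong <- replicate(150, run_trial(m, make_pair("2.7", "2.91"))$steps)
  incon <- replicate(150, run_trial(m, make_pair("7.14", "7.6"))$steps)
  expect_lt(mean(cong), mean(incon))
})

test_that("untrained weights are rejected by run_trial and run_experiment", {
  m <- test_model()
  bad <- m
  bad$digit$W[] <- 0
  bad$digit$accuracy <- comparator_accuracy(bad$digit)
  expect_error(run_trial(bad, make_pair("2.04", "2.91")), "trained")
  expect_error(run_experiment(bad, mini_stimuli(), 1, 1), "trained")
})

test_that("the number-of-digits comparison outpaces a digit comparison at matched distance", {
  m <- test_model()
  g <- 2  # common gain, so training strength alone drives the comparison
  len_lat <- comparator_latency(m$length, 3, 2, g)
  digit_lat <- mean(sapply(1:8, function(b)
    comparator_latency(m$digit, b + 1, b, g)))
  expect_lt(len_lat, digit_lat)
})

test_that("raising hundredth attention by an order of magnitude re-opens its channel", {
  m <- test_model()
  pair_compat <- make_pair("4.25", "4.69")    # hundredths agree with tenths
  pair_incompat <- make_pair("3.29", "3.67")  # hundredths oppose tenths
  params <- noise_free(m)
  base_diff <- run_trial(m, pair_incompat, params)$steps -
    run_trial(m, pair_compat, params)$steps
  raised <- params
  raised$task_activation["hundredth"] <- 1
  raised$response_weight["hundredth"] <- 1
  raised_diff <- run_trial(m, pair_incompat, raised)$steps -
    run_trial(m, pair_compat, raised)$steps
  expect_gt(raised_diff, base_diff)
})
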