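# Shared fixtures, built once per test run. Training the comparison
# networks takes a few seconds; every test file reuses the same trained
# model and stimulus sets through these memoising accessors.

.dfc_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .dfc_cache)) assign(key, force(expr), .dfc_cache)
  get(key, .dfc_cache)
}

# Canonical fixtures follow the same master-seed derivation as
# scripts/acceptance.R with master seed 1: one seed stream for training,
# one for stimulus generation, one for the simulated experiment.
stage_seeds <- function(master = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, 3L)
}

test_model <- function() memo("model", dfc_model(seed = stage_seeds()[1]))

test_stimuli <- function() memo("stimuli", {
  set.seed(stage_seeds()[2])
  dfc_stimuli()
})

# 10%-scale set: 4 pairs per cell + 12 fillers = 44 items
mini_stimuli <- function() memo("mini", {
  set.seed(1)
  dfc_stimuli(n_per_cell = 4L, n_fillers = 12L, budget = 3000L)
})

# one stimulus row as the list run_trial() expects
make_pair <- function(first, second) {
  p1 <- parse_decimal(first); p2 <- parse_decimal(second)
  list(first = first, second = second,
       unit1 = p1$unit, tenth1 = p1$tenth, hundredth1 = p1$hundredth,
       len1 = p1$n_digits,
       unit2 = p2$unit, tenth2 = p2$tenth, hundredth2 = p2$hundredth,
       len2 = p2$n_digits,
       value1 = p1$value, value2 = p2$value,
       larger = if (p1$value >= p2$value) "first" else "second")
}

noise_free <- function(model) {
  params <- model$control
  params$noise_sd <- 0
  params
}
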