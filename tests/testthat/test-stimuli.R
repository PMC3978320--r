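test_that("canonical example pairs are classified correctly", {
  expect_equal(classify_pair("9.07", "9.39"), "compatible")
  expect_equal(classify_pair("8.10", "8.97"), "compatible")
  expect_equal(classify_pair("1.09", "1.51"), "incompatible")
  expect_equal(classify_pair("3.29", "3.67"), "incompatible")
  expect_equal(classify_pair("6.54", "6.90"), "incompatible")
  expect_equal(classify_pair("2.7", "2.91"), "congruent")
  expect_equal(classify_pair("7.14", "7.6"), "incongruent")
  expect_equal(classify_pair("7.91", "7.98"), "none")  # filler: tenths equal
  expect_equal(classify_pair("2.83", "2.8"), "none")
})

test_that("pair metrics follow the distance and problem-size conventions", {
  m <- pair_metrics("9.07", "9.39")
  expect_equal(unname(m["overall"]), 0.32)
  expect_equal(unname(m["tenth"]), 3)
  expect_equal(unname(m["hundredth"]), 2)
  expect_equal(unname(pair_metrics("2.04", "2.91")["problem_size"]), 4.95)
  expect_equal(unname(pair_metrics("2.4", "2.43")["hundredth"]), 3)
  expect_true(all(pair_metrics("3.45", "3.45")[c("overall", "tenth", "hundredth")] == 0))
})

test_that("malformed decimals are rejected", {
  expect_error(parse_decimal("0.45"))
  expect_error(parse_decimal("12.3"))
  expect_error(parse_decimal("2.456"))
})

test_that("the generated set has the designed structure", {
  s <- test_stimuli()
  expect_s3_class(s, "dfc_stimuli")
  expect_equal(nrow(s), 440L)
  expect_equal(sum(s$type == "filler"), 120L)
  tab <- table(s$type[s$type != "filler"], s$relation[s$type != "filler"])
  expect_true(all(tab[tab > 0] == 40L))
  expect_equal(unname(rowSums(tab)), rep(80L, 4))

  # units identical; fillers share the tenth digit; critical tenths differ
  expect_true(all(s$unit1 == s$unit2))
  crit <- s[s$type != "filler", ]
  expect_true(all(crit$tenth1 != crit$tenth2))
  fil <- s[s$type == "filler", ]
  expect_true(all(fil$tenth1 == fil$tenth2))

  # one member of each critical pair is the all-nonzero three-digit reference
  ref_ok <- with(crit,
    (len1 == 3 & tenth1 > 0 & !is.na(hundredth1) & hundredth1 > 0) |
    (len2 == 3 & tenth2 > 0 & !is.na(hundredth2) & hundredth2 > 0))
  expect_true(all(ref_ok))

  # type-defining member structure
  with(subset(crit, type == "a.0c"), expect_true(all(tenth1 == 0 | tenth2 == 0)))
  with(subset(crit, type == "a.b0"),
       expect_true(all(hundredth1 == 0 | hundredth2 == 0, na.rm = TRUE)))
  with(subset(crit, type == "a.b"), expect_true(all(len1 == 2 | len2 == 2)))
  with(subset(crit, type == "a.bc"),
       expect_true(all(len1 == 3 & len2 == 3 &
                       hundredth1 > 0 & hundredth2 > 0 &
                       hundredth1 != hundredth2)))

  expect_true(all(s$value1 >= 1.04 & s$value1 <= 9.96))
  expect_true(all(s$value2 >= 1.04 & s$value2 <= 9.96))

  # larger position counterbalanced within every cell
  cb <- tapply(s$larger == "first", paste(s$type, s$relation), mean)
  expect_true(all(abs(cb - 0.5) < 1e-9))

  # relation labels agree with the classifier
  lab <- mapply(classify_pair, crit$first, crit$second)
  expect_equal(unname(lab), crit$relation)
})

test_that("cell means match the design targets", {
  s <- test_stimuli()
  crit <- s[s$type != "filler", ]
  ov <- tapply(crit$overall_distance, paste(crit$type, crit$relation), mean)
  expect_true(all(abs(ov - 0.40) <= 0.021))
  t10 <- tapply(crit$tenth_distance, paste(crit$type, crit$relation), mean)
  tg <- matching_targets()
  for (i in seq_len(nrow(tg))) {
    cell <- paste(tg$type[i], tg$relation[i])
    expect_lt(abs(t10[cell] - tg$tenth[i]), tg$tenth_sd[i] + 1e-9)
  }
  expect_length(attr(s, "unmatched"), 0)
})

test_that("generation is reproducible and scales down", {
  set.seed(77); a <- dfc_stimuli(n_per_cell = 3L, n_fillers = 6L, budget = 500L)
  set.seed(77); b <- dfc_stimuli(n_per_cell = 3L, n_fillers = 6L, budget = 500L)
  expect_identical(a, b)
  mini <- mini_stimuli()
  expect_equal(nrow(mini), 44L)
  expect_equal(sum(mini$type == "filler"), 12L)
})

test_that("stimulus sets survive a CSV round trip", {
  mini <- mini_stimuli()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stimuli(mini, path)
  back <- read_stimuli(path)
  expect_equal(back$first, mini$first)
  expect_equal(back$second, mini$second)
  expect_equal(back$overall_distance, mini$overall_distance)
})
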