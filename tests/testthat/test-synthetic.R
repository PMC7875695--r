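test_that("truth construction and corpus generation are deterministic", {
  t1 <- generator_truth(seed = 5)
  t2 <- generator_truth(seed = 5)
  expect_equal(t1$diseases, t2$diseases)
  c1 <- generate_corpus(t1, 300, seed = 8)
  c2 <- generate_corpus(t2, 300, seed = 8)
  expect_identical(c1$corpus, c2$corpus)
  expect_identical(c1$labels, c2$labels)
  c3 <- generate_corpus(t1, 300, seed = 9)
  expect_false(identical(c1$corpus, c3$corpus))
})

test_that("a one-disease world with certain prescribing is degenerate", {
  truth <- degenerate_truth()
  lc <- generate_corpus(truth, 50, seed = 1)
  expect_true(all(vapply(lc$corpus$diagnoses, identical, NA, "D1")))
  expect_true(all(vapply(lc$corpus$medications, identical, NA, "M1")))
  expect_true(all(lc$labels$label == "substantiated"))
})

test_that("error_rate 0 and 1 pin the ground-truth labels", {
  clean <- generate_corpus(generator_truth(error_rate = 0), 200, seed = 2)
  expect_true(all(clean$labels$label == "substantiated"))
  expect_true(all(is.na(clean$labels$injected_medication)))

  dirty <- generate_corpus(generator_truth(error_rate = 1), 200, seed = 3)
  expect_true(all(dirty$labels$label == "unsubstantiated"))
  expect_true(all(!is.na(dirty$labels$injected_medication)))
  expect_true(all(!is.na(dirty$labels$severity)))
  # exactly one flagged medication, present on the prescription but not
  # indicated by any of its diagnoses
  ind <- default_indication_map()
  ok <- vapply(seq_len(200), function(i) {
    inj <- dirty$labels$injected_medication[i]
    dx <- dirty$corpus$diagnoses[[i]]
    inj %in% dirty$corpus$medications[[i]] &&
      !any(ind$medication == inj & ind$disease %in% dx)
  }, NA)
  expect_true(all(ok))
})

test_that("the injected fraction matches the binomial expectation", {
  lc <- generate_corpus(generator_truth(error_rate = 0.1), 20000, seed = 4)
  frac <- mean(lc$labels$label == "unsubstantiated")
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("per-prescription flags exactly identify the injected medications", {
  lc <- generate_corpus(generator_truth(error_rate = 0.3), 500, seed = 6)
  expect_identical(lc$labels$label == "unsubstantiated",
                   !is.na(lc$labels$injected_medication))
  # severity only on injected errors
  expect_identical(is.na(lc$labels$severity),
                   is.na(lc$labels$injected_medication))
})

test_that("disease subset probabilities sum to one in every stratum", {
  for (truth in list(generator_truth(), bernoulli_truth())) {
    sd <- aoprx:::subset_distribution(truth)
    sums <- sd$subsets |>
      dplyr::group_by(sex, age_band) |>
      dplyr::summarise(p = sum(prob), .groups = "drop")
    expect_equal(sums$p, rep(1, nrow(sums)), tolerance = 1e-12)
    expect_equal(sum(sd$strata$prob), 1, tolerance = 1e-12)
  }
})

test_that("analytic lift reproduces the 1/p closed form", {
  # two independent diseases; M1 prescribed iff D1 (prob 1)
  truth <- generator_truth(
    disease_mode = "bernoulli", error_rate = 0,
    diseases = tibble::tibble(
      code = c("D1", "D2"), name = c("a", "b"), weight = c(1, 1),
      prevalence = c(0.1, 0.4), age_coef = 0, female_mult = 1),
    indications = tibble::tibble(
      disease = c("D1", "D2"), medication = c("M1", "M2"), prob = 1),
    comedications = tibble::tibble(trigger = character(),
                                   companion = character(),
                                   prob = double()),
    comorbidities = tibble::tibble(code_a = character(),
                                   code_b = character(),
                                   multiplier = double()))
  expect_equal(analytic_lift(truth, "DM", "D1", "M1"), 1 / 0.1,
               tolerance = 1e-10)
  expect_equal(analytic_lift(truth, "DM", "D2", "M2"), 1 / 0.4,
               tolerance = 1e-10)
  # independent pairs sit exactly at 1
  expect_equal(analytic_lift(truth, "DM", "D1", "M2"), 1, tolerance = 1e-10)
  expect_equal(analytic_lift(truth, "MM", "M1", "M2"), 1, tolerance = 1e-10)
})

test_that("comorbidity pulls the pseudo-association between 1 and 1/p", {
  truth <- generator_truth()  # visit mode, I10-E11.9 comorbidity planted
  pseudo <- analytic_lift(truth, "DM", "I10", "A10AB01")  # insulin vs htn
  direct <- analytic_lift(truth, "DM", "E11.9", "A10AB01")
  expect_gt(pseudo, 1)
  expect_lt(pseudo, direct)
})

test_that("null comorbidity multipliers leave planted-pair structure intact", {
  flat <- generator_truth(
    comorbidities = tibble::tibble(code_a = character(),
                                   code_b = character(),
                                   multiplier = double()))
  # without the comorbidity there is no insulin-hypertension pseudo lift
  expect_lt(analytic_lift(flat, "DM", "I10", "A10AB01"), 1)
})

test_that("mined lifts converge to the analytic oracle in visit mode", {
  truth <- generator_truth()
  lc <- generate_corpus(truth, 30000, seed = 12)
  model <- mine_model(lc$corpus, stratified = FALSE)
  for (pair in list(c("G40.909", "N03AX14"), c("M06.9", "L01BA01"),
                    c("K21.9", "A02BC01"))) {
    mined <- q_lookup(model, "DM", pair[1], pair[2])
    oracle <- analytic_lift(truth, "DM", pair[1], pair[2])
    expect_lt(abs(mined - oracle) / oracle, 0.15,
              label = paste(pair, collapse = "-"))
  }
  mined_mm <- q_lookup(model, "MM", "L01BA01", "B03BB01")
  oracle_mm <- analytic_lift(truth, "MM", "L01BA01", "B03BB01")
  expect_lt(abs(mined_mm - oracle_mm) / oracle_mm, 0.15)
})

test_that("the filler encounter explains its own medication", {
  truth <- generator_truth(error_rate = 0)
  lc <- generate_corpus(truth, 20000, seed = 13)
  model <- mine_model(lc$corpus, stratified = FALSE)
  q <- q_lookup(model, "DM", "Z00.0", "A11CC05")
  expect_gt(q, 1)
  cls <- classify_corpus(lc$corpus, model)
  filler_rx <- vapply(lc$corpus$medications,
                      function(m) identical(m, "A11CC05"), NA)
  expect_true(all(
    cls$prescriptions$verdict[filler_rx] == "substantiated"))
})

test_that("labelled corpora round-trip through the sidecar files", {
  lc <- generate_corpus(generator_truth(error_rate = 0.5), 50, seed = 14)
  cp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_corpus(lc, cp, lp)
  expect_identical(read_corpus(cp), lc$corpus)
  labels <- read_labels(lp)
  expect_equal(labels$label, lc$labels$label)
  expect_equal(labels$injected_medication, lc$labels$injected_medication)
})

test_that("the fixture model round-trips and matches its expectations", {
  fx <- worked_example_fixtures()
  path <- withr::local_tempfile(fileext = ".tsv")
  save_model(fx$model, path)
  expect_identical(load_model(path)$records, fx$model$records)
  cls <- classify_corpus(fx$prescriptions, fx$model)
  expect_equal(cls$prescriptions$verdict, fx$expected$verdict)
})
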