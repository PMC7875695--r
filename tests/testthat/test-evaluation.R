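test_that("enriched sampling is balanced, seeded, and fails on small classes", {
  preds <- tibble::tibble(
    rx_id = sprintf("r%03d", 1:100),
    verdict = rep(c("substantiated", "unsubstantiated"), c(70, 30)))
  ts <- build_enriched_test_set(preds, n_per_class = 20, seed = 9)
  expect_equal(nrow(ts), 40)
  expect_equal(unname(table(ts$predicted)["unsubstantiated"]), 20)
  expect_identical(ts, build_enriched_test_set(preds, 20, seed = 9))
  expect_false(identical(ts, build_enriched_test_set(preds, 20, seed = 10)))
  expect_error(build_enriched_test_set(preds, n_per_class = 31, seed = 1),
               "only 30")
  # exhaustive case: one per class selects both
  two <- tibble::tibble(rx_id = c("a", "b"),
                        verdict = c("substantiated", "unsubstantiated"))
  expect_setequal(build_enriched_test_set(two, 1, seed = 1)$rx_id,
                  c("a", "b"))
})

test_that("a single low-confidence rating excludes the prescription", {
  reviews <- tidyr::expand_grid(rx_id = sprintf("r%03d", 1:10),
                                rater_id = c("R1", "R2")) |>
    dplyr::mutate(label = "substantiated", severity = NA_character_,
                  confidence = 6L)
  reviews$confidence[reviews$rx_id == "r003" &
                       reviews$rater_id == "R2"] <- 3L
  out <- apply_confidence_exclusion(reviews)
  expect_equal(length(out$retained), 9)
  expect_false("r003" %in% out$retained)
  expect_equal(out$excluded$rx_id, "r003")
  # all high confidence: everything retained
  reviews$confidence <- 6L
  expect_equal(length(apply_confidence_exclusion(reviews)$retained), 10)
  # missing rater record is an error
  expect_error(apply_confidence_exclusion(reviews[-1, ]),
               "one record per rater")
})

test_that("adjudication takes agreements and defers splits to the tie-breaker", {
  reviews <- tibble::tibble(
    rx_id = rep(c("a", "b", "c"), each = 2),
    rater_id = rep(c("R1", "R2"), 3),
    label = c("unsubstantiated", "unsubstantiated",
              "substantiated", "unsubstantiated",
              "substantiated", "substantiated"),
    severity = c("serious", "serious", NA, "significant", NA, NA),
    confidence = 6L)
  expect_error(adjudicate(reviews), "no tie_breaker")
  tb <- tibble::tibble(rx_id = "b", label = "substantiated",
                       severity = NA_character_)
  out <- adjudicate(reviews, tie_breaker = tb)
  expect_equal(out$label[out$rx_id == "a"], "unsubstantiated")
  expect_equal(out$severity[out$rx_id == "a"], "serious")
  expect_equal(out$label[out$rx_id == "b"], "substantiated")
  expect_true(is.na(out$severity[out$rx_id == "b"]))
  expect_equal(out$label[out$rx_id == "c"], "substantiated")
})

test_that("confusion counts partition the set with unsubstantiated positive", {
  truths <- tibble::tibble(
    rx_id = sprintf("r%02d", 1:10),
    label = rep(c("unsubstantiated", "substantiated"), c(4, 6)))
  perfect <- tibble::tibble(rx_id = truths$rx_id, verdict = truths$label)
  cm <- confusion_counts(perfect, truths)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 4L, fp = 0L, tn = 6L, fn = 0L))
  all_pos <- dplyr::mutate(perfect, verdict = "unsubstantiated")
  cm2 <- confusion_counts(all_pos, truths)
  expect_equal(cm2$tp, 4L)
  expect_equal(cm2$fp, 6L)
  expect_error(confusion_counts(perfect[-1, ], truths), "different")
})

test_that("metric formulas match hand arithmetic and flag undefined cases", {
  m <- compute_metrics(list(tp = 204, fn = 28, tn = 269, fp = 95))
  expect_equal(m$sensitivity, 204 / 232)
  expect_equal(m$specificity, 269 / 364)
  expect_equal(m$ppv, 204 / 299)
  expect_equal(m$npv, 269 / 297)
  expect_equal(m$accuracy, 473 / 596)
  perfect <- compute_metrics(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_true(all(perfect[c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")] == 1))
  degenerate <- compute_metrics(list(tp = 0, fp = 0, tn = 8, fn = 2))
  expect_true(is.na(degenerate$ppv))
  expect_equal(degenerate$specificity, 1)
})

test_that("threshold sweep at a single alpha matches direct metrics", {
  fx <- worked_example_fixtures()
  truth <- tibble::tibble(rx_id = fx$prescriptions$rx_id,
                          label = fx$expected$verdict)
  sw <- threshold_sweep(fx$model, fx$prescriptions, truth, alphas = 1)
  expect_equal(nrow(sw), 1)
  direct <- compute_metrics(
    confusion_counts(classify_corpus(fx$prescriptions, fx$model), truth),
    alpha = 1)
  expect_equal(sw |> dplyr::select(-model), direct)
  # default grid produces 11 rows per model and a formatted table
  sw11 <- threshold_sweep(list(A = fx$model, B = fx$model),
                          fx$prescriptions, truth)
  expect_equal(nrow(sw11), 22)
  tab <- format_sweep_table(sw11)
  expect_equal(nrow(tab), 11)
  expect_equal(tab$alpha, seq(1.5, 0.5, by = -0.1))
  expect_true(all(c("A_Sen", "B_Accu") %in% names(tab)))
})

test_that("kappa matches hand-computed agreement and is symmetric", {
  # agreement table a=40, b=10, c=10, d=40: p_o = 0.8, p_e = 0.5
  a <- rep(c("S", "S", "U", "U"), c(40, 10, 10, 40))
  b <- rep(c("S", "U", "S", "U"), c(40, 10, 10, 40))
  k <- cohen_kappa(a, b)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_lt(k$ci_low, 0.6)
  expect_gt(k$ci_high, 0.6)
  expect_equal(cohen_kappa(b, a)$kappa, k$kappa)
  # identical vectors with both classes present
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # one constant rater scores zero against any mixed rater
  expect_equal(cohen_kappa(rep("S", 80), a[1:80])$kappa, 0)
  # degenerate marginals are an explicit error
  expect_error(cohen_kappa(rep("S", 5), rep("S", 5)), "undefined")
})

test_that("group comparison reproduces the null and shifted cases", {
  base <- dplyr::bind_rows(lapply(1:60, function(i)
    make_rx(sprintf("r%03d", i), 50, "male",
            paste0("D", 1:3), paste0("M", 1:2))))
  truth <- tibble::tibble(
    rx_id = base$rx_id,
    label = rep(c("substantiated", "unsubstantiated"), 30))
  cg <- compare_groups(base, truth)
  # identical groups: t statistic 0 (zero-variance guard), medians equal
  expect_equal(cg$table$p_value[2], 1)
  expect_equal(cg$table$substantiated[3], cg$table$unsubstantiated[3])

  # medication counts shifted by 2 at n = 200 per group
  shifted <- withr::with_seed(77, dplyr::bind_rows(lapply(1:400, function(i) {
    unsub <- i > 200
    n_med <- sample(1:4, 1) + if (unsub) 2 else 0
    make_rx(sprintf("s%03d", i), sample(30:80, 1),
            sample(c("male", "female"), 1),
            paste0("D", 1:sample(1:4, 1)), paste0("M", 1:n_med))
  })))
  truth2 <- tibble::tibble(
    rx_id = shifted$rx_id,
    label = rep(c("substantiated", "unsubstantiated"), each = 200))
  cg2 <- compare_groups(shifted, truth2)
  expect_lt(cg2$table$p_value[4], 0.05)
})

test_that("medication class tables follow ATC prefixes and severity strata", {
  flagged <- tibble::tibble(
    rx_id = c("a", "a", "b"),
    medication = c("N02AA01", "N02AA05", "N05BA01"))
  tab <- tabulate_medication_classes(flagged)
  expect_equal(tab$medication_class, c("opioid analgesic", "benzodiazepine"))
  expect_equal(tab$n, c(2L, 1L))
  # invariant to input order
  tab2 <- tabulate_medication_classes(flagged[c(3, 1, 2), ])
  expect_equal(tab, tab2)
  # empty input, empty table
  expect_equal(nrow(tabulate_medication_classes(flagged[0, ])), 0)
  # severity strata
  sev <- tibble::tibble(rx_id = c("a", "b"),
                        severity = c("serious", "significant"))
  tab3 <- tabulate_medication_classes(flagged, severities = sev)
  expect_equal(tab3$n[tab3$scope == "serious"], 2L)
  expect_equal(tab3$medication_class[tab3$scope == "significant"],
               "benzodiazepine")
})

test_that("severity proportions are computed over the unsubstantiated set", {
  adj <- tibble::tibble(
    label = rep(c("unsubstantiated", "substantiated"), c(8, 4)),
    severity = c(rep("serious", 2), rep("significant", 6), rep(NA, 4)))
  sp <- severity_proportions(adj)
  expect_equal(sp$pct[sp$severity == "serious"], 25)
  expect_equal(sum(sp$n), 8)
})

test_that("discordance analysis counts O-positive cases cleared by H", {
  mk_cls <- function(verdicts, flagged) {
    structure(list(
      prescriptions = tibble::tibble(rx_id = names(verdicts),
                                     verdict = unname(verdicts)),
      medications = flagged), class = "aop_classification")
  }
  ids <- sprintf("r%02d", 1:10)
  truth <- tibble::tibble(
    rx_id = ids, label = rep(c("unsubstantiated", "substantiated"), c(5, 5)))
  o_verdicts <- setNames(rep("unsubstantiated", 10), ids)
  o_flagged <- tibble::tibble(rx_id = ids, medication = "N02AA01",
                              explained = FALSE)
  # H clears 2 of the 5 truth positives and 1 truth negative
  h_verdicts <- o_verdicts
  h_verdicts[c("r01", "r02", "r06")] <- "substantiated"
  h_cls <- mk_cls(h_verdicts, o_flagged)
  o_cls <- mk_cls(o_verdicts, o_flagged)
  out <- discordance_analysis(o_cls, h_cls, truth)
  expect_equal(out$summary$pct[1], 40)  # 2 / 5
  expect_equal(out$summary$pct[2], 20)  # 1 / 5
  # flipped-case class table agrees with direct tabulation
  direct <- tabulate_medication_classes(
    tibble::tibble(rx_id = c("r01", "r02"), medication = "N02AA01"))
  expect_equal(out$classes$true_positive_to_false_negative, direct)
  # identical classifications have zero discordance
  same <- discordance_analysis(o_cls, o_cls, truth)
  expect_equal(same$summary$n_flipped, c(0L, 0L))
})

test_that("cohort split percentages and sizes are exact", {
  s <- split_summary(667572, 60000)
  expect_equal(s$n_training, 607572)
  expect_equal(s$pct_validation, 100 * 60000 / 667572)
  corpus <- random_corpus(50, seed = 4)
  sp <- cohort_split(corpus, 10, seed = 2)
  expect_equal(nrow(sp$validation), 10)
  expect_equal(nrow(sp$training), 40)
  expect_length(intersect(sp$validation$rx_id, sp$training$rx_id), 0)
  sp2 <- cohort_split(corpus, 10, seed = 2)
  expect_identical(sp$validation$rx_id, sp2$validation$rx_id)
})

test_that("simulated reviews respect the schema", {
  truth <- tibble::tibble(
    rx_id = sprintf("r%03d", 1:50),
    label = rep(c("substantiated", "unsubstantiated"), c(40, 10)),
    severity = c(rep(NA, 40), rep("significant", 10)))
  rv <- simulate_reviews(truth, label_flip = 0.1, seed = 3)
  expect_equal(nrow(rv), 100)
  expect_true(all(is.na(rv$severity[rv$label == "substantiated"])))
  expect_true(all(!is.na(rv$severity[rv$label == "unsubstantiated"])))
  expect_true(all(rv$confidence %in% 1:6))
  expect_identical(rv, simulate_reviews(truth, label_flip = 0.1, seed = 3))
})
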