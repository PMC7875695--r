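#' Split a corpus into validation and training sets
#'
#' Randomly samples `n_validation` prescriptions (without replacement) into
#' a validation set; the remainder is the local training set.
#'
#' @param corpus A prescription corpus tibble.
#' @param n_validation Number of prescriptions to hold out.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with `validation`, `training` (corpus tibbles) and
#'   `summary` (see [split_summary()]).
#' @export
cohort_split <- function(corpus, n_validation, seed) {
  corpus <- as_prescription_corpus(corpus)
  stopifnot(n_validation >= 1, n_validation < nrow(corpus))
  idx <- withr::with_seed(seed, sample.int(nrow(corpus), n_validation))
  list(validation = corpus[sort(idx), ],
       training = corpus[-sort(idx), ],
       summary = split_summary(nrow(corpus), n_validation))
}

#' Summarise a validation/training split
#'
#' @param n_total Total corpus size.
#' @param n_validation Held-out validation size.
#' @return A one-row tibble with `n_total`, `n_validation`, `n_training`,
#'   and the corresponding percentages (`pct_validation`, `pct_training`),
#'   carried at full precision (rounding is left to the report layer).
#' @export
split_summary <- function(n_total, n_validation) {
  tibble(n_total = n_total,
         n_validation = n_validation,
         n_training = n_total - n_validation,
         pct_validation = 100 * n_validation / n_total,
         pct_training = 100 * (n_total - n_validation) / n_total)
}

#' Build an enriched test set
#'
#' Samples, without replacement, the same number of prescriptions from the
#' model-predicted substantiated and unsubstantiated groups of a classified
#' validation set, so that rare unsubstantiated prescriptions are
#' sufficiently represented for review. The output order is shuffled.
#'
#' @param classification An `aop_classification` (from [classify_corpus()]
#'   on the validation set) or a tibble with `rx_id` and `verdict`.
#' @param n_per_class Prescriptions sampled per predicted class
#'   (default 300, i.e. a 600-prescription test set).
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return A tibble with `rx_id` and `predicted` (the model verdict), in
#'   shuffled order.
#' @export
build_enriched_test_set <- function(classification, n_per_class = 300,
                                    seed) {
  preds <- if (inherits(classification, "aop_classification")) {
    classification$prescriptions
  } else {
    as_tibble(classification)
  }
  stopifnot(all(c("rx_id", "verdict") %in% names(preds)))
  classes <- c("substantiated", "unsubstantiated")
  withr::with_seed(seed, {
    picks <- lapply(classes, function(cl) {
      ids <- preds$rx_id[preds$verdict == cl]
      if (length(ids) < n_per_class) {
        stop(sprintf(
          "predicted class '%s' has only %d members (< n_per_class = %d)",
          cl, length(ids), n_per_class), call. = FALSE)
      }
      tibble(rx_id = sample(ids, n_per_class), predicted = cl)
    })
    out <- bind_rows(picks)
    out[sample.int(nrow(out)), ]
  })
}

#' Simulate physician reviews of a labelled test set
#'
#' Emulates the dual-rater chart review: each rater reports the ground-truth
#' substantiation label with a configurable flip rate, a severity grade for
#' prescriptions they call unsubstantiated, and a confidence rating on the
#' 6-point scale.
#'
#' @param truth A tibble with `rx_id`, `label`
#'   ("substantiated"/"unsubstantiated") and optionally `severity`.
#' @param rater_ids Identifiers for the raters (default two).
#' @param label_flip Probability a rater reports the opposite label.
#' @param severity_flip Probability a rater reports a different severity
#'   than the ground truth.
#' @param severity_mix Probabilities of (life_threatening, serious,
#'   significant) used when a severity must be invented (rater says
#'   unsubstantiated but the truth has no severity).
#' @param confidence_probs Probabilities of confidence scores 1..6.
#' @param seed Integer seed.
#' @return A review tibble: `rx_id`, `rater_id`, `label`, `severity`
#'   (`NA` unless `label == "unsubstantiated"`), `confidence`.
#' @export
simulate_reviews <- function(truth, rater_ids = c("R1", "R2"),
                             label_flip = 0.05, severity_flip = 0.1,
                             severity_mix = c(life_threatening = 0,
                                              serious = 27 / 232,
                                              significant = 205 / 232),
                             confidence_probs = c(0.001, 0.001, 0.001,
                                                  0.047, 0.25, 0.7),
                             seed = NULL) {
  truth <- as_tibble(truth)
  stopifnot(all(c("rx_id", "label") %in% names(truth)))
  if (is.null(truth$severity)) truth$severity <- NA_character_
  levels <- severity_levels
  run <- function() {
    bind_rows(lapply(rater_ids, function(rater) {
      n <- nrow(truth)
      flip <- runif(n) < label_flip
      label <- ifelse(flip, other_label(truth$label), truth$label)
      sev <- rep(NA_character_, n)
      unsub <- label == "unsubstantiated"
      has_truth_sev <- unsub & !is.na(truth$severity)
      sev[has_truth_sev] <- truth$severity[has_truth_sev]
      resample <- unsub & (!has_truth_sev | runif(n) < severity_flip)
      if (any(resample)) {
        sev[resample] <- sample(levels, sum(resample), replace = TRUE,
                                prob = severity_mix)
      }
      tibble(rx_id = truth$rx_id, rater_id = rater, label = label,
             severity = sev,
             confidence = sample(1:6, n, replace = TRUE,
                                 prob = confidence_probs))
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

severity_levels <- c("life_threatening", "serious", "significant")

other_label <- function(x) {
  ifelse(x == "substantiated", "unsubstantiated", "substantiated")
}

check_paired_reviews <- function(reviews) {
  reviews <- as_tibble(reviews)
  stopifnot(all(c("rx_id", "rater_id", "label", "confidence") %in%
                  names(reviews)))
  counts <- reviews |> count(.data$rx_id)
  n_raters <- length(unique(reviews$rater_id))
  per_rx <- reviews |> distinct(.data$rx_id, .data$rater_id) |>
    count(.data$rx_id)
  if (any(per_rx$n != n_raters) || any(counts$n != n_raters)) {
    stop("every prescription needs exactly one record per rater",
         call. = FALSE)
  }
  reviews
}

#' Exclude low-confidence reviews
#'
#' A prescription is retained only if *every* rater rated their confidence
#' at or above `min_confidence` (default 4, i.e. confidence >= 50% on the
#' 6-point scale); a single low-confidence rating excludes it.
#'
#' @param reviews A paired review tibble (one record per rater per
#'   prescription; see [simulate_reviews()]).
#' @param min_confidence Minimum acceptable confidence score.
#' @return A list with `retained` (character vector of rx_ids, input
#'   order) and `excluded` (tibble of the sub-threshold records:
#'   `rx_id`, `rater_id`, `confidence`).
#' @export
apply_confidence_exclusion <- function(reviews, min_confidence = 4) {
  reviews <- check_paired_reviews(reviews)
  low <- reviews |>
    filter(.data$confidence < min_confidence) |>
    select("rx_id", "rater_id", "confidence")
  retained <- setdiff(unique(reviews$rx_id), low$rx_id)
  list(retained = retained, excluded = low)
}

#' Adjudicate paired reviews into ground-truth labels
#'
#' When both raters agree, their shared label (and, for unsubstantiated
#' prescriptions, their shared severity) becomes the ground truth. Any
#' disagreement is resolved by the `tie_breaker` labels, which model the
#' senior physician's final decision; a disagreement with no tie-breaker
#' available is an explicit error.
#'
#' @param reviews A paired review tibble from exactly two raters.
#' @param tie_breaker Optional tibble with `rx_id`, `label` and optionally
#'   `severity`, consulted only for disagreements.
#' @return A tibble with `rx_id`, `label`, `severity` (`NA` for
#'   substantiated prescriptions).
#' @export
adjudicate <- function(reviews, tie_breaker = NULL) {
  reviews <- check_paired_reviews(reviews)
  raters <- unique(reviews$rater_id)
  if (length(raters) != 2) {
    stop("adjudication requires exactly two raters", call. = FALSE)
  }
  if (is.null(reviews$severity)) reviews$severity <- NA_character_
  a <- reviews |> filter(.data$rater_id == raters[1]) |>
    select("rx_id", label_a = "label", severity_a = "severity")
  b <- reviews |> filter(.data$rater_id == raters[2]) |>
    select("rx_id", label_b = "label", severity_b = "severity")
  wide <- inner_join(a, b, by = "rx_id")
  tb_lookup <- function(ids, what) {
    if (is.null(tie_breaker)) {
      stop("rater disagreement with no tie_breaker for: ",
           paste(head(ids, 5), collapse = ", "), call. = FALSE)
    }
    tb <- as_tibble(tie_breaker)
    hit <- match(ids, tb$rx_id)
    if (anyNA(hit)) {
      stop("tie_breaker lacks a decision for: ",
           paste(head(ids[is.na(hit)], 5), collapse = ", "), call. = FALSE)
    }
    tb[[what]][hit]
  }
  label <- ifelse(wide$label_a == wide$label_b, wide$label_a,
                  NA_character_)
  if (anyNA(label)) {
    label[is.na(label)] <- tb_lookup(wide$rx_id[is.na(label)], "label")
  }
  severity <- rep(NA_character_, nrow(wide))
  unsub <- label == "unsubstantiated"
  agree_sev <- unsub & !is.na(wide$severity_a) &
    !is.na(wide$severity_b) & wide$severity_a == wide$severity_b
  severity[agree_sev] <- wide$severity_a[agree_sev]
  need_tb <- unsub & !agree_sev
  if (any(need_tb)) {
    severity[need_tb] <- tb_lookup(wide$rx_id[need_tb], "severity")
  }
  tibble(rx_id = wide$rx_id, label = label, severity = severity)
}

#' Severity composition of unsubstantiated prescriptions
#'
#' @param adjudicated A tibble with `label` and `severity` (for example
#'   from [adjudicate()]).
#' @return A tibble with one row per severity level present among
#'   unsubstantiated prescriptions: `severity`, `n`, `pct` (of all
#'   unsubstantiated prescriptions).
#' @export
severity_proportions <- function(adjudicated) {
  unsub <- adjudicated |> filter(.data$label == "unsubstantiated")
  unsub |>
    count(.data$severity, name = "n") |>
    mutate(pct = 100 * .data$n / nrow(unsub)) |>
    arrange(desc(.data$n))
}

#' Confusion counts (positive = unsubstantiated)
#'
#' @param predictions An `aop_classification` or tibble with `rx_id` and
#'   `verdict`.
#' @param truths A tibble with `rx_id` and `label` for the same
#'   prescriptions.
#' @return A list of class `aop_confusion` with integer `tp`, `fp`, `tn`,
#'   `fn` (positive class = unsubstantiated); the four counts partition the
#'   evaluated set.
#' @export
confusion_counts <- function(predictions, truths) {
  preds <- if (inherits(predictions, "aop_classification")) {
    predictions$prescriptions
  } else {
    as_tibble(predictions)
  }
  truths <- as_tibble(truths)
  stopifnot(all(c("rx_id", "verdict") %in% names(preds)),
            all(c("rx_id", "label") %in% names(truths)))
  if (!setequal(preds$rx_id, truths$rx_id)) {
    stop("predictions and truths cover different prescription sets",
         call. = FALSE)
  }
  joined <- inner_join(preds |> select("rx_id", "verdict"),
                       truths |> select("rx_id", "label"), by = "rx_id")
  pos <- "unsubstantiated"
  structure(list(
    tp = sum(joined$verdict == pos & joined$label == pos),
    fp = sum(joined$verdict == pos & joined$label != pos),
    tn = sum(joined$verdict != pos & joined$label != pos),
    fn = sum(joined$verdict != pos & joined$label == pos)
  ), class = "aop_confusion")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV = tp/(tp+fp),
#' NPV = tn/(tn+fn), accuracy = (tp+tn)/n, with unsubstantiated as the
#' positive class. A metric with a zero denominator is reported as `NA`
#' (undefined), never as 0. Values are carried at full precision; rounding
#' to two decimals happens only in [format_sweep_table()].
#'
#' @param cm An `aop_confusion` or a list with `tp`, `fp`, `tn`, `fn`.
#' @param alpha Optional threshold to record alongside the metrics.
#' @return A one-row tibble: `alpha` (if given), `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
compute_metrics <- function(cm, alpha = NULL) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  out <- tibble(
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    accuracy = ratio(cm$tp + cm$tn, n)
  )
  if (!is.null(alpha)) out <- bind_cols(tibble(alpha = alpha), out)
  out
}

#' Sweep the decision threshold across models
#'
#' Re-classifies a truth-labelled test set at every threshold in `alphas`
#' for one or more models and tabulates the confusion metrics. The
#' per-medication evidence is threshold-independent, so it is computed once
#' per model.
#'
#' @param models A single `aop_model` or a named list of them.
#' @param corpus The test-set prescriptions (corpus tibble).
#' @param truth A tibble with `rx_id` and ground-truth `label`.
#' @param alphas Threshold grid (default 0.5 to 1.5 in steps of 0.1).
#' @param params Base [classifier_params()]; its `alpha` is overridden by
#'   the grid.
#' @return A tibble with one row per (model, alpha): confusion counts plus
#'   sensitivity, specificity, ppv, npv, accuracy.
#' @export
threshold_sweep <- function(models, corpus, truth,
                            alphas = seq(0.5, 1.5, by = 0.1),
                            params = classifier_params()) {
  stopifnot(length(alphas) > 0)
  if (inherits(models, "aop_model")) {
    models <- setNames(list(models), models$meta$label)
  }
  corpus <- as_prescription_corpus(corpus)
  n_meds <- setNames(lengths(corpus$medications), corpus$rx_id)
  bind_rows(lapply(names(models), function(name) {
    ev <- medication_evidence(corpus, models[[name]],
                              fallback = params$fallback)
    bind_rows(lapply(alphas, function(a) {
      p <- params
      p$alpha <- a
      flags <- explained_flags(ev, p, n_meds)
      verdicts <- tibble(rx_id = ev$rx_id, explained = flags$explained) |>
        group_by(.data$rx_id) |>
        summarise(verdict = ifelse(all(.data$explained), "substantiated",
                                   "unsubstantiated"), .groups = "drop")
      compute_metrics(confusion_counts(verdicts, truth), alpha = a)
    })) |>
      mutate(model = name, .before = 1)
  }))
}

#' Format a threshold sweep as a performance table
#'
#' Wide layout, one row per threshold (descending), with Sen / Spe / PPV /
#' NPV / Accu columns per model, rounded to two decimals; undefined metrics
#' print as `"NA"`.
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A tibble of formatted strings (first column `alpha`).
#' @export
format_sweep_table <- function(sweep) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  long <- sweep |>
    transmute(model = .data$model, alpha = .data$alpha,
              Sen = fmt(.data$sensitivity), Spe = fmt(.data$specificity),
              PPV = fmt(.data$ppv), NPV = fmt(.data$npv),
              Accu = fmt(.data$accuracy)) |>
    tidyr::pivot_longer(c("Sen", "Spe", "PPV", "NPV", "Accu"),
                        names_to = "metric", values_to = "value") |>
    mutate(column = paste(.data$model, .data$metric, sep = "_")) |>
    select("alpha", "column", "value")
  long |>
    tidyr::pivot_wider(names_from = "column", values_from = "value") |>
    arrange(desc(.data$alpha))
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Unweighted kappa, `(p_o - p_e) / (1 - p_e)`, where `p_e` comes from the
#' product of the marginal proportions; works for binary labels and for the
#' 3-level severity scale alike. The confidence interval uses the standard
#' large-sample agreement-based standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param labels_a,labels_b Equal-length label vectors from the two raters.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `kappa`, `ci_low`, `ci_high`, `p_o`, `p_e`,
#'   `n`. Degenerate marginals (`p_e = 1`) are an explicit error.
#' @export
cohen_kappa <- function(labels_a, labels_b, conf_level = 0.95) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  levels <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = levels)
  b <- factor(labels_b, levels = levels)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (1 - p_e < .Machine$double.eps^0.5) {
    stop("kappa undefined: both raters use a single identical category ",
         "(p_e = 1)", call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(kappa = kappa, ci_low = kappa - z * se, ci_high = kappa + z * se,
         p_o = p_o, p_e = unname(p_e), n = n)
}

#' Compare substantiated and unsubstantiated groups
#'
#' Patient characteristics by ground-truth group: age by two-tailed t test
#' (mean, SD), sex by chi-square (counts), diagnosis and medication counts
#' by Wilcoxon rank-sum (median, IQR).
#'
#' @param corpus The test-set prescriptions.
#' @param truth A tibble with `rx_id` and `label`.
#' @return A list with `table` (formatted comparison, one characteristic
#'   per row with a `p_value` column) and `data` (the per-prescription
#'   characteristics used).
#' @export
compare_groups <- function(corpus, truth) {
  corpus <- as_prescription_corpus(corpus)
  df <- corpus |>
    transmute(rx_id = .data$rx_id, age = .data$age, sex = .data$sex,
              n_diagnoses = lengths(.data$diagnoses),
              n_medications = lengths(.data$medications)) |>
    inner_join(as_tibble(truth) |> select("rx_id", "label"), by = "rx_id")
  g <- split(df, df$label == "unsubstantiated")
  sub <- g[["FALSE"]]
  unsub <- g[["TRUE"]]
  if (is.null(sub) || is.null(unsub)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  safe_t <- function(x, y) {
    if (stats::var(c(x, y)) == 0) return(list(statistic = 0, p.value = 1))
    tt <- t.test(x, y)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  tt <- safe_t(sub$age, unsub$age)
  sex_tab <- table(df$label, df$sex)
  chi <- if (all(dim(sex_tab) >= 2)) {
    suppressWarnings(chisq.test(sex_tab))
  } else {
    list(p.value = NA_real_)  # a single sex level: no contrast to test
  }
  wd <- suppressWarnings(wilcox.test(sub$n_diagnoses, unsub$n_diagnoses))
  wm <- suppressWarnings(wilcox.test(sub$n_medications, unsub$n_medications))
  mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  med_iqr <- function(x) sprintf("%g (%g)", median(x), stats::IQR(x))
  mf <- function(d) sprintf("%d/%d", sum(d$sex == "male"),
                            sum(d$sex == "female"))
  table <- tibble(
    characteristic = c("Sex (male/female)", "Age (years), mean (SD)",
                       "Number of diagnoses, median (IQR)",
                       "Number of medications, median (IQR)"),
    substantiated = c(mf(sub), mean_sd(sub$age), med_iqr(sub$n_diagnoses),
                      med_iqr(sub$n_medications)),
    unsubstantiated = c(mf(unsub), mean_sd(unsub$age),
                        med_iqr(unsub$n_diagnoses),
                        med_iqr(unsub$n_medications)),
    p_value = c(chi$p.value, tt$p.value, wd$p.value, wm$p.value)
  )
  list(table = table, data = df)
}

#' Default ATC prefix to medication class map
#'
#' Maps ATC code prefixes to the medication class names used in
#' unsubstantiated-prescription frequency tables (opioid analgesic,
#' benzodiazepine, SSRI, proton pump inhibitor, ...). Longest matching
#' prefix wins; codes with no matching prefix fall into `"other"`.
#'
#' @return A tibble with `atc_prefix` and `class_name`.
#' @export
default_atc_class_map <- function() {
  tibble::tribble(
    ~atc_prefix, ~class_name,
    "N02A",  "opioid analgesic",
    "N02B",  "nonopioid analgesic",
    "N05BA", "benzodiazepine",
    "N05CD", "benzodiazepine",
    "N05A",  "antipsychotic",
    "N06AB", "SSRI",
    "A02BC", "PPI",
    "R06A",  "antihistamine",
    "B01AA", "anticoagulant",
    "B01AE", "anticoagulant",
    "B01AF", "anticoagulant",
    "B01AC", "antiplatelet",
    "C07",   "beta-blocker",
    "C09A",  "ACEi/ARB",
    "C09C",  "ACEi/ARB",
    "N03A",  "anticonvulsant",
    "C10AA", "statin",
    "A10A",  "insulin",
    "A10B",  "oral antidiabetic",
    "C03",   "diuretic",
    "C08",   "calcium channel blocker",
    "M01A",  "NSAID",
    "P01BA", "antimalarial DMARD",
    "L01BA", "folate-antagonist immunosuppressant",
    "B03BB", "folic acid",
    "A11",   "vitamin"
  )
}

atc_class_of <- function(codes, class_map) {
  prefixes <- class_map$atc_prefix[order(-nchar(class_map$atc_prefix))]
  names_by_prefix <- setNames(class_map$class_name, class_map$atc_prefix)[
    prefixes]
  vapply(codes, function(code) {
    hit <- prefixes[startsWith(code, prefixes)]
    if (length(hit) > 0) names_by_prefix[[hit[1]]] else "other"
  }, "", USE.NAMES = FALSE)
}

#' Tabulate flagged medications by class
#'
#' Counts how often each medication class appears among flagged
#' (problematic) medications, overall and within each severity stratum,
#' sorted by descending count.
#'
#' @param flagged A tibble with `rx_id` and `medication` (one row per
#'   flagged medication occurrence).
#' @param class_map An ATC prefix map (default [default_atc_class_map()]).
#' @param severities Optional tibble with `rx_id` and `severity`; when
#'   given, per-severity strata are tabulated in addition to the total.
#' @return A tibble with `scope` (`"total"` or a severity level),
#'   `medication_class`, `n`, sorted descending within scope.
#' @export
tabulate_medication_classes <- function(flagged,
                                        class_map = default_atc_class_map(),
                                        severities = NULL) {
  flagged <- as_tibble(flagged)
  if (nrow(flagged) == 0) {
    return(tibble(scope = character(), medication_class = character(),
                  n = integer()))
  }
  flagged$medication_class <- atc_class_of(flagged$medication, class_map)
  tab <- function(df, scope) {
    df |>
      count(.data$medication_class, name = "n") |>
      arrange(desc(.data$n), .data$medication_class) |>
      mutate(scope = scope, .before = 1)
  }
  out <- tab(flagged, "total")
  if (!is.null(severities)) {
    flagged <- flagged |>
      inner_join(as_tibble(severities) |> select("rx_id", "severity"),
                 by = "rx_id", relationship = "many-to-many")
    for (lev in intersect(severity_levels, unique(flagged$severity))) {
      out <- bind_rows(out, tab(flagged |> filter(.data$severity == lev),
                                lev))
    }
  }
  out
}

#' Discordance between the original and hybrid models
#'
#' Among truth-positive (unsubstantiated) prescriptions, the fraction that
#' the original model flags (true positive) but the hybrid model clears
#' (false negative); and among truth-negative prescriptions, the fraction
#' the original model flags (false positive) but the hybrid model clears
#' (true negative). For each flipped group the most common flagged
#' medication classes (per the original model's flags) are tabulated.
#'
#' @param results_o,results_h `aop_classification` objects for the same
#'   test set.
#' @param truth A tibble with `rx_id` and `label`.
#' @param class_map An ATC prefix map for the flipped-case class tables.
#' @return A list with `summary` (tibble: `group`, `n_flipped`, `n_group`,
#'   `pct`) and `classes` (named list of class tables for the two flipped
#'   groups).
#' @export
discordance_analysis <- function(results_o, results_h, truth,
                                 class_map = default_atc_class_map()) {
  stopifnot(inherits(results_o, "aop_classification"),
            inherits(results_h, "aop_classification"))
  truth <- as_tibble(truth)
  df <- truth |>
    select("rx_id", "label") |>
    inner_join(results_o$prescriptions |> select("rx_id", o = "verdict"),
               by = "rx_id") |>
    inner_join(results_h$prescriptions |> select("rx_id", h = "verdict"),
               by = "rx_id")
  if (nrow(df) != nrow(truth)) {
    stop("the two classifications must cover the truth-labelled set",
         call. = FALSE)
  }
  flipped <- df$o == "unsubstantiated" & df$h == "substantiated"
  pos <- df$label == "unsubstantiated"
  summarise_group <- function(mask, name) {
    tibble(group = name, n_flipped = sum(flipped & mask),
           n_group = sum(mask),
           pct = ifelse(sum(mask) > 0,
                        100 * sum(flipped & mask) / sum(mask), NA_real_))
  }
  flagged_o <- results_o$medications |>
    filter(!.data$explained) |>
    select("rx_id", "medication")
  classes_for <- function(mask) {
    tabulate_medication_classes(
      flagged_o |> filter(.data$rx_id %in% df$rx_id[mask & flipped]),
      class_map = class_map)
  }
  list(
    summary = bind_rows(
      summarise_group(pos, "true_positive_to_false_negative"),
      summarise_group(!pos, "false_positive_to_true_negative")),
    classes = list(
      true_positive_to_false_negative = classes_for(pos),
      false_positive_to_true_negative = classes_for(!pos))
  )
}
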