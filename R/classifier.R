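#' Classifier parameters
#'
#' @param alpha Positive decision threshold on the Q value. An association
#'   is positive only when `Q > alpha` (strict; `Q == alpha` is negative).
#'   Default 1, the independence point of the lift statistic.
#' @param rule How a medication counts as explained: `"dm_or_mm"` (default;
#'   a relevant disease *and/or* a co-medication) or `"dm_and_mm"` (both a
#'   positive D-M and a positive M-M association are required).
#' @param fallback Q lookup policy when the patient's stratum has no record:
#'   `"pooled"` (default) falls back to the pooled-stratum Q, `"none"`
#'   treats the pair as absent.
#' @param vacuous_mm Under `rule = "dm_and_mm"`, how to treat the M-M clause
#'   on single-medication prescriptions: `TRUE` (default) makes it vacuously
#'   true (otherwise every monotherapy would be flagged), `FALSE` makes it
#'   false.
#' @return A list of class `aop_params`.
#' @export
classifier_params <- function(alpha = 1, rule = c("dm_or_mm", "dm_and_mm"),
                              fallback = c("pooled", "none"),
                              vacuous_mm = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  structure(list(alpha = alpha, rule = match.arg(rule),
                 fallback = match.arg(fallback),
                 vacuous_mm = isTRUE(vacuous_mm)),
            class = "aop_params")
}

#' Best association evidence per medication
#'
#' For every medication on every prescription, finds the highest-Q diagnosis
#' on the same prescription (D-M evidence) and the highest-Q co-medication
#' (M-M evidence), using stratum-specific Q values with the requested
#' fallback. Absent associations yield `NA`. This table is
#' threshold-independent, so a threshold sweep computes it once.
#'
#' @param corpus A prescription corpus tibble.
#' @param model An `aop_model`.
#' @param fallback `"pooled"` or `"none"` (see [classifier_params()]).
#' @return A tibble with one row per (prescription, medication):
#'   `rx_id`, `medication`, `best_dm_code`, `best_dm_q`, `best_mm_code`,
#'   `best_mm_q`.
#' @export
medication_evidence <- function(corpus, model,
                                fallback = c("pooled", "none")) {
  fallback <- match.arg(fallback)
  corpus <- as_prescription_corpus(corpus)
  stopifnot(inherits(model, "aop_model"))
  m_long <- codes_long(corpus, "medications") |> rename(medication = "code")
  if (nrow(corpus) == 0 || nrow(m_long) == 0) {
    return(tibble(rx_id = character(), medication = character(),
                  best_dm_code = character(), best_dm_q = double(),
                  best_mm_code = character(), best_mm_q = double()))
  }
  d_long <- codes_long(corpus, "diagnoses")

  rec <- model$records
  lookup_q <- function(pairs, kind) {
    # pairs: rx_id, sex, age_band, code_a, code_b (+ extra cols kept)
    sub <- rec |> filter(.data$kind == .env$kind)
    strat <- sub |>
      filter(.data$sex != pooled_sex) |>
      select("sex", "age_band", "code_a", "code_b", q_strat = "q")
    pooled <- sub |>
      filter(.data$sex == pooled_sex) |>
      select("code_a", "code_b", q_pooled = "q")
    out <- pairs |>
      left_join(strat, by = c("sex", "age_band", "code_a", "code_b")) |>
      left_join(pooled, by = c("code_a", "code_b"))
    if (fallback == "pooled") {
      out$q <- coalesce(out$q_strat, out$q_pooled)
    } else {
      out$q <- out$q_strat
    }
    out
  }

  dm_pairs <- inner_join(
    d_long |> rename(code_a = "code"),
    m_long |> select("rx_id", "medication"),
    by = "rx_id", relationship = "many-to-many"
  ) |> mutate(code_b = .data$medication)
  dm_best <- lookup_q(dm_pairs, "DM") |>
    filter(!is.na(.data$q)) |>
    arrange(.data$rx_id, .data$medication, desc(.data$q), .data$code_a) |>
    distinct(.data$rx_id, .data$medication, .keep_all = TRUE) |>
    select("rx_id", "medication", best_dm_code = "code_a", best_dm_q = "q")

  mm_pairs <- inner_join(
    m_long |> select("rx_id", "sex", "age_band", "medication"),
    m_long |> select("rx_id", other = "medication"),
    by = "rx_id", relationship = "many-to-many"
  ) |>
    filter(.data$medication != .data$other) |>
    mutate(code_a = pmin(.data$medication, .data$other),
           code_b = pmax(.data$medication, .data$other))
  mm_best <- lookup_q(mm_pairs, "MM") |>
    filter(!is.na(.data$q)) |>
    arrange(.data$rx_id, .data$medication, desc(.data$q), .data$other) |>
    distinct(.data$rx_id, .data$medication, .keep_all = TRUE) |>
    select("rx_id", "medication", best_mm_code = "other", best_mm_q = "q")

  m_long |>
    select("rx_id", "medication") |>
    left_join(dm_best, by = c("rx_id", "medication")) |>
    left_join(mm_best, by = c("rx_id", "medication"))
}

explained_flags <- function(evidence, params, n_meds_by_rx) {
  alpha <- params$alpha
  dm_pos <- !is.na(evidence$best_dm_q) & evidence$best_dm_q > alpha
  mm_pos <- !is.na(evidence$best_mm_q) & evidence$best_mm_q > alpha
  if (params$rule == "dm_or_mm") {
    explained <- dm_pos | mm_pos
  } else {
    single <- n_meds_by_rx[evidence$rx_id] == 1L
    mm_clause <- if (params$vacuous_mm) mm_pos | single else mm_pos
    explained <- dm_pos & mm_clause
  }
  tibble(dm_positive = dm_pos, mm_positive = mm_pos, explained = explained)
}

#' Classify a corpus of prescriptions
#'
#' A medication is *explained* when it has a positive association
#' (`Q > alpha`) with a diagnosis or co-medication on the same prescription,
#' per the configured rule. A prescription is *substantiated* when every one
#' of its medications is explained, otherwise *unsubstantiated* and its
#' unexplained medications are flagged as problematic.
#'
#' @param corpus A prescription corpus tibble.
#' @param model An `aop_model`.
#' @param params An [classifier_params()] object.
#' @return An object of class `aop_classification`: a list with
#'   `prescriptions` (tibble `rx_id`, `verdict`, `n_medications`,
#'   `n_flagged`, in corpus order), `medications` (one row per medication
#'   with its evidence and flags), `params`, and `summary` counts.
#' @export
classify_corpus <- function(corpus, model, params = classifier_params()) {
  stopifnot(inherits(params, "aop_params"))
  corpus <- as_prescription_corpus(corpus)
  ev <- medication_evidence(corpus, model, fallback = params$fallback)
  n_meds <- setNames(lengths(corpus$medications), corpus$rx_id)
  meds <- bind_cols(ev, explained_flags(ev, params, n_meds))
  rx <- meds |>
    group_by(.data$rx_id) |>
    summarise(n_medications = n(),
              n_flagged = sum(!.data$explained),
              .groups = "drop") |>
    mutate(verdict = ifelse(.data$n_flagged == 0,
                            "substantiated", "unsubstantiated"))
  rx <- tibble(rx_id = corpus$rx_id) |>
    left_join(rx, by = "rx_id") |>
    select("rx_id", "verdict", "n_medications", "n_flagged")
  structure(
    list(prescriptions = rx, medications = meds, params = params,
         summary = list(
           n = nrow(rx),
           substantiated = sum(rx$verdict == "substantiated"),
           unsubstantiated = sum(rx$verdict == "unsubstantiated"))),
    class = "aop_classification"
  )
}

#' @export
print.aop_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<aop_classification> %d prescriptions at alpha = %g: %d substantiated, %d unsubstantiated\n",
    s$n, x$params$alpha, s$substantiated, s$unsubstantiated))
  invisible(x)
}

#' Classify a single prescription
#'
#' @param rx A one-row prescription corpus tibble.
#' @inheritParams classify_corpus
#' @return A list with `rx_id`, `verdict`, `flagged` (character vector of
#'   unexplained medications) and `medications` (the per-medication verdict
#'   tibble).
#' @export
classify_prescription <- function(rx, model, params = classifier_params()) {
  rx <- as_prescription_corpus(rx)
  stopifnot(nrow(rx) == 1)
  cls <- classify_corpus(rx, model, params)
  list(rx_id = rx$rx_id,
       verdict = cls$prescriptions$verdict[1],
       flagged = cls$medications$medication[!cls$medications$explained],
       medications = cls$medications)
}

#' Evaluate one medication on a prescription
#'
#' @param rx A one-row prescription corpus tibble.
#' @param med An ATC code; must be on the prescription.
#' @inheritParams classify_corpus
#' @return A one-row tibble: `medication`, `dm_positive`, `best_dm_code`,
#'   `best_dm_q`, `mm_positive`, `best_mm_code`, `best_mm_q`, `explained`.
#' @export
evaluate_medication <- function(rx, med, model,
                                params = classifier_params()) {
  rx <- as_prescription_corpus(rx)
  stopifnot(nrow(rx) == 1)
  if (!med %in% rx$medications[[1]]) {
    stop("medication ", med, " is not on prescription ", rx$rx_id,
         call. = FALSE)
  }
  cls <- classify_prescription(rx, model, params)
  cls$medications |>
    filter(.data$medication == med) |>
    select("medication", "dm_positive", "best_dm_code", "best_dm_q",
           "mm_positive", "best_mm_code", "best_mm_q", "explained")
}

#' Write a classification report
#'
#' Delimited report, one row per prescription: verdict plus the flagged
#' medications with their best supporting pair and Q value.
#'
#' @param classification An `aop_classification`.
#' @param path File path.
#' @param delim Delimiter.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path, delim = "\t") {
  stopifnot(inherits(classification, "aop_classification"))
  flagged <- classification$medications |>
    filter(!.data$explained) |>
    group_by(.data$rx_id) |>
    summarise(flagged_medications = paste(.data$medication, collapse = ";"),
              .groups = "drop")
  out <- classification$prescriptions |>
    left_join(flagged, by = "rx_id") |>
    mutate(flagged_medications = coalesce(.data$flagged_medications, ""))
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}
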