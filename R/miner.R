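#' Count disease-medication and medication-medication co-occurrences
#'
#' Tallies, per stratum (sex x 5-year age band) and always also for the
#' pooled stratum, how many prescriptions contain each diagnosis code, each
#' medication code, and each observed D-M and M-M code pair. Pairs that
#' never co-occur are absent from the tables. M-M pairs are stored in
#' canonical lexicographic order, so counts are symmetric in the two codes.
#'
#' @param corpus A prescription corpus tibble (see [prescription-corpus]).
#' @param stratified If `TRUE` (default) counts are computed per stratum in
#'   addition to the pooled stratum; if `FALSE` only pooled counts are kept.
#' @return An object of class `aop_counts`: a list of tibbles `totals`
#'   (`sex`, `age_band`, `n_total`), `diag_counts` and `med_counts`
#'   (`sex`, `age_band`, `code`, `n`), and `dm` / `mm`
#'   (`sex`, `age_band`, `code_a`, `code_b`, `n_joint`).
#' @export
count_cooccurrence <- function(corpus, stratified = TRUE) {
  corpus <- as_prescription_corpus(corpus)
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)

  d_long <- codes_long(corpus, "diagnoses")
  m_long <- codes_long(corpus, "medications")

  count_marg <- function(long) {
    strat <- if (stratified) {
      count(long, .data$sex, .data$age_band, .data$code, name = "n")
    }
    pooled <- count(long, .data$code, name = "n") |>
      mutate(sex = pooled_sex, age_band = pooled_band, .before = 1)
    bind_rows(strat, pooled)
  }

  dm_pairs <- inner_join(
    d_long |> rename(code_a = "code"),
    m_long |> select("rx_id", code_b = "code"),
    by = "rx_id", relationship = "many-to-many"
  )
  mm_pairs <- inner_join(
    m_long |> rename(code_a = "code"),
    m_long |> select("rx_id", code_b = "code"),
    by = "rx_id", relationship = "many-to-many"
  ) |>
    filter(.data$code_a < .data$code_b)

  count_joint <- function(pairs) {
    strat <- if (stratified) {
      count(pairs, .data$sex, .data$age_band, .data$code_a, .data$code_b,
            name = "n_joint")
    }
    pooled <- count(pairs, .data$code_a, .data$code_b, name = "n_joint") |>
      mutate(sex = pooled_sex, age_band = pooled_band, .before = 1)
    bind_rows(strat, pooled)
  }

  strat_totals <- if (stratified) {
    corpus |>
      mutate(age_band = age_band(.data$age)) |>
      count(.data$sex, .data$age_band, name = "n_total")
  }
  totals <- bind_rows(
    strat_totals,
    tibble(sex = pooled_sex, age_band = pooled_band, n_total = nrow(corpus))
  )

  structure(
    list(totals = totals,
         diag_counts = count_marg(d_long),
         med_counts = count_marg(m_long),
         dm = count_joint(dm_pairs),
         mm = count_joint(mm_pairs),
         stratified = stratified),
    class = "aop_counts"
  )
}

codes_long <- function(corpus, col) {
  k <- lengths(corpus[[col]])
  tibble(
    rx_id = rep.int(corpus$rx_id, k),
    sex = rep.int(corpus$sex, k),
    age_band = rep.int(age_band(corpus$age), k),
    code = unlist(corpus[[col]], use.names = FALSE)
  )
}

# The association statistic ("Q value"): lift of the pair over prescriptions,
# Q = P(a, b) / (P(a) P(b)) = n_joint * n_total / (n_a * n_b).
# Kept behind this one function so an alternative definition can be swapped in.
q_statistic <- function(n_joint, n_a, n_b, n_total) {
  (n_joint * as.numeric(n_total)) / (as.numeric(n_a) * as.numeric(n_b))
}

#' Compute Q values and build an association model
#'
#' Turns co-occurrence counts into an association model. The Q value of a
#' pair is its lift over prescriptions, `Q = P(a,b) / (P(a) P(b))`, computed
#' within each stratum; `Q = 1` is the independence point, which is why the
#' default decision threshold is `alpha = 1`. Records whose joint count
#' falls below `min_support` are omitted.
#'
#' @param counts An `aop_counts` object from [count_cooccurrence()].
#' @param label Provenance label stored in the model metadata (for example
#'   `"O"`, `"L"`, `"H"`).
#' @param min_support Minimum `n_joint` for a record to be emitted
#'   (default 1, i.e. every observed pair).
#' @return An object of class `aop_model`: a list with `records` (tibble
#'   with columns `kind` ("DM"/"MM"), `code_a`, `code_b`, `sex`, `age_band`,
#'   `n_joint`, `n_a`, `n_b`, `n_total`, `q`) and `meta`.
#' @export
compute_q <- function(counts, label = "model", min_support = 1) {
  stopifnot(inherits(counts, "aop_counts"))
  join_marg <- function(joint, marg_a, marg_b) {
    joint |>
      inner_join(marg_a |> rename(code_a = "code", n_a = "n"),
                 by = c("sex", "age_band", "code_a")) |>
      inner_join(marg_b |> rename(code_b = "code", n_b = "n"),
                 by = c("sex", "age_band", "code_b")) |>
      inner_join(counts$totals, by = c("sex", "age_band"))
  }
  dm <- join_marg(counts$dm, counts$diag_counts, counts$med_counts) |>
    mutate(kind = "DM", .before = 1)
  mm <- join_marg(counts$mm, counts$med_counts, counts$med_counts) |>
    mutate(kind = "MM", .before = 1)
  records <- bind_rows(dm, mm) |>
    filter(.data$n_joint >= min_support) |>
    mutate(q = q_statistic(.data$n_joint, .data$n_a, .data$n_b,
                           .data$n_total)) |>
    select("kind", "code_a", "code_b", "sex", "age_band",
           "n_joint", "n_a", "n_b", "n_total", "q") |>
    arrange(.data$kind, .data$code_a, .data$code_b, .data$sex,
            .data$age_band)
  new_aop_model(records, meta = list(
    label = label,
    n_prescriptions = counts$totals$n_total[
      counts$totals$sex == pooled_sex],
    stratified = isTRUE(counts$stratified),
    min_support = as.numeric(min_support),
    pruned = FALSE
  ))
}

new_aop_model <- function(records, meta) {
  structure(list(records = as_tibble(records), meta = meta),
            class = "aop_model")
}

#' @export
print.aop_model <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<aop_model '%s'>  %d records (%d DM, %d MM); trained on %d prescriptions%s\n",
    m$label, nrow(x$records), sum(x$records$kind == "DM"),
    sum(x$records$kind == "MM"), m$n_prescriptions,
    if (isTRUE(m$stratified)) ", stratified by sex and 5-year age band"
    else ", pooled only"))
  invisible(x)
}

#' Mine an association model from a corpus
#'
#' Convenience wrapper: [count_cooccurrence()] followed by [compute_q()].
#'
#' @inheritParams count_cooccurrence
#' @inheritParams compute_q
#' @return An `aop_model`.
#' @export
mine_model <- function(corpus, label = "model", stratified = TRUE,
                       min_support = 1) {
  compute_q(count_cooccurrence(corpus, stratified = stratified),
            label = label, min_support = min_support)
}

#' Look up a Q value
#'
#' Returns the stratum-specific Q value for a pair, or `NA` when no record
#' exists. Under `fallback = "pooled"` an absent stratum record falls back
#' to the pooled-stratum record; under `fallback = "none"` it stays absent.
#' Absent associations are treated as negative evidence by the classifier.
#' M-M pairs may be given in either order.
#'
#' @param model An `aop_model`.
#' @param kind `"DM"` or `"MM"`.
#' @param code_a,code_b Codes of the pair (diagnosis then medication for
#'   `"DM"`).
#' @param sex,age_band Stratum of the patient; ignored (pooled lookup) when
#'   `sex = "all"`.
#' @param fallback `"pooled"` or `"none"`.
#' @return A numeric scalar Q value, or `NA_real_` if absent.
#' @export
q_lookup <- function(model, kind, code_a, code_b, sex = pooled_sex,
                     age_band = pooled_band,
                     fallback = c("pooled", "none")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(model, "aop_model"), kind %in% c("DM", "MM"))
  if (kind == "MM" && code_a > code_b) {
    tmp <- code_a; code_a <- code_b; code_b <- tmp
  }
  rec <- model$records
  pick <- function(s, b) {
    hit <- rec$kind == kind & rec$code_a == code_a & rec$code_b == code_b &
      rec$sex == s & rec$age_band == b
    if (any(hit)) rec$q[which(hit)[1]] else NA_real_
  }
  q <- pick(sex, age_band)
  if (is.na(q) && fallback == "pooled" && sex != pooled_sex) {
    q <- pick(pooled_sex, pooled_band)
  }
  q
}

#' Keep only the strongest diagnosis per medication
#'
#' Comorbidity can induce pseudo-associations: insulin acquires a high Q
#' with hypertension merely because hypertension and type 2 diabetes are
#' common comorbidities. This optional pruning keeps, within each stratum
#' and for each medication, only the single D-M record with the highest Q
#' (ties broken towards the lexicographically smaller diagnosis code) and
#' discards the rest. M-M records are untouched. Off by default; the
#' classifier's per-prescription maximum achieves the equivalent existential
#' test at classification time.
#'
#' @param model An `aop_model`.
#' @return The pruned `aop_model` (metadata records `pruned = TRUE`).
#' @export
prune_global_top1 <- function(model) {
  stopifnot(inherits(model, "aop_model"))
  rec <- model$records
  dm <- rec |>
    filter(.data$kind == "DM") |>
    arrange(.data$sex, .data$age_band, .data$code_b,
            desc(.data$q), .data$code_a) |>
    distinct(.data$sex, .data$age_band, .data$code_b, .keep_all = TRUE)
  records <- bind_rows(dm, rec |> filter(.data$kind == "MM")) |>
    arrange(.data$kind, .data$code_a, .data$code_b, .data$sex,
            .data$age_band)
  meta <- model$meta
  meta$pruned <- TRUE
  new_aop_model(records, meta)
}
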