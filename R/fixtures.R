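#' Worked-example fixtures
#'
#' A small hand-set association model and two reviewer-style example
#' prescriptions that exercise the classifier end to end:
#' \itemize{
#'   \item `rx_substantiated`: a 74-year-old woman with aortic stenosis,
#'     hypertension, Raynaud's disease and hyperlipidemia on aspirin,
#'     atorvastatin, furosemide and losartan — every medication has a
#'     positive D-M association, so the prescription is substantiated.
#'   \item `rx_unsubstantiated`: a 76-year-old man seen for gait
#'     disturbance and epilepsy management, on seven medications of which
#'     only levetiracetam is explained by a listed diagnosis; the other six
#'     (simvastatin, methotrexate, omeprazole, warfarin,
#'     hydroxychloroquine, folic acid) are flagged as problematic.
#' }
#' The model is a synthetic stand-in with pooled-stratum Q values chosen by
#' hand so that classification at `alpha = 1` reproduces those reviewer
#' verdicts; it also contains one below-threshold decoy record.
#'
#' @return A list with `model` (an `aop_model`), `prescriptions` (a 2-row
#'   corpus tibble) and `expected` (tibble `rx_id`, `verdict`, `flagged`
#'   list column).
#' @export
worked_example_fixtures <- function() {
  q_rec <- function(kind, code_a, code_b, n_joint, n_a, n_b, n_total) {
    tibble(kind = kind, code_a = code_a, code_b = code_b,
           sex = pooled_sex, age_band = pooled_band,
           n_joint = as.integer(n_joint), n_a = as.integer(n_a),
           n_b = as.integer(n_b), n_total = as.integer(n_total),
           q = q_statistic(n_joint, n_a, n_b, n_total))
  }
  n <- 100000L
  records <- bind_rows(
    # supports for the substantiated example (all q > 1)
    q_rec("DM", "I35.0", "B01AC06", 700, 2000, 10000, n),   # q = 3.5
    q_rec("DM", "E78.5", "C10AA05", 7200, 12000, 10000, n), # q = 6.0
    q_rec("DM", "I10", "C03CA01", 5600, 25000, 8000, n),    # q = 2.8
    q_rec("DM", "I10", "C09CA01", 16500, 25000, 12000, n),  # q = 5.5
    # the only positive support in the unsubstantiated example
    q_rec("DM", "G40.309", "N03AX14", 960, 1200, 10000, n), # q = 8.0
    # below-threshold decoy: seen together, but negatively associated
    q_rec("DM", "R26.9", "C10AA01", 120, 3000, 10000, n)    # q = 0.4
  ) |>
    arrange(.data$kind, .data$code_a, .data$code_b)
  model <- new_aop_model(records, meta = list(
    label = "fixture", n_prescriptions = n, stratified = FALSE,
    min_support = 1, pruned = FALSE))
  prescriptions <- tibble(
    rx_id = c("rx-sub", "rx-unsub"),
    patient_id = c("pt-1", "pt-2"),
    age = c(74L, 76L),
    sex = c("female", "male"),
    diagnoses = list(
      c("I35.0", "I10", "I73.0", "E78.5"),
      c("R26.9", "G40.309")),
    medications = list(
      c("B01AC06", "C10AA05", "C03CA01", "C09CA01"),
      c("C10AA01", "L01BA01", "N03AX14", "A02BC01", "B01AA03",
        "P01BA02", "B03BB01"))
  )
  expected <- tibble(
    rx_id = prescriptions$rx_id,
    verdict = c("substantiated", "unsubstantiated"),
    flagged = list(character(0),
                   sort(c("C10AA01", "L01BA01", "A02BC01", "B01AA03",
                          "P01BA02", "B03BB01")))
  )
  list(model = model,
       prescriptions = as_prescription_corpus(prescriptions),
       expected = expected)
}
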