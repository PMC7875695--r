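# Small in-code fixtures and independent brute-force oracles.

make_rx <- function(rx_id, age, sex, dx, meds, patient_id = rx_id) {
  tibble::tibble(rx_id = rx_id, patient_id = patient_id,
                 age = as.integer(age), sex = sex,
                 diagnoses = list(dx), medications = list(meds))
}

# The 4-prescription reference corpus: D and M each appear in 2 of 4
# prescriptions and co-occur once, so lift(D, M) = (1/4)/((2/4)(2/4)) = 1.
four_rx_corpus <- function() {
  dplyr::bind_rows(
    make_rx("r1", 40, "male", c("D", "Dx"), c("M", "Mx")),
    make_rx("r2", 41, "male", c("D", "Dx"), "Mx"),
    make_rx("r3", 42, "male", "Dx", c("M", "Mx")),
    make_rx("r4", 43, "male", "Dx", "Mx")
  )
}

random_corpus <- function(n, seed, n_dx = 4, n_med = 5, ages = 20:49) {
  withr::with_seed(seed, {
    d_pool <- paste0("D", seq_len(n_dx))
    m_pool <- paste0("M", seq_len(n_med))
    tibble::tibble(
      rx_id = sprintf("r%03d", seq_len(n)),
      patient_id = sprintf("p%03d", seq_len(n)),
      age = sample(ages, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      diagnoses = lapply(seq_len(n), function(i)
        sample(d_pool, sample(1:3, 1))),
      medications = lapply(seq_len(n), function(i)
        sample(m_pool, sample(1:3, 1)))
    )
  })
}

# Brute-force oracle: double loop over prescriptions and code pairs,
# independent of the join-based implementation.
brute_model_records <- function(corpus, min_support = 1) {
  bands <- aoprx::age_band(corpus$age)
  strata <- unique(data.frame(sex = corpus$sex, age_band = bands))
  strata <- rbind(strata, data.frame(sex = "all", age_band = -1L))
  all_d <- sort(unique(unlist(corpus$diagnoses)))
  all_m <- sort(unique(unlist(corpus$medications)))
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    idx <- if (strata$sex[s] == "all") seq_len(nrow(corpus)) else
      which(corpus$sex == strata$sex[s] & bands == strata$age_band[s])
    n_total <- length(idx)
    has_d <- sapply(all_d, function(d)
      sapply(idx, function(i) d %in% corpus$diagnoses[[i]]))
    has_m <- sapply(all_m, function(m)
      sapply(idx, function(i) m %in% corpus$medications[[i]]))
    has_d <- matrix(has_d, nrow = n_total)
    has_m <- matrix(has_m, nrow = n_total)
    for (a in seq_along(all_d)) for (b in seq_along(all_m)) {
      nj <- sum(has_d[, a] & has_m[, b])
      if (nj >= min_support && nj > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          kind = "DM", code_a = all_d[a], code_b = all_m[b],
          sex = strata$sex[s], age_band = strata$age_band[s],
          n_joint = nj, n_a = sum(has_d[, a]), n_b = sum(has_m[, b]),
          n_total = n_total)
      }
    }
    if (length(all_m) > 1) {
      for (a in seq_len(length(all_m) - 1)) {
        for (b in (a + 1):length(all_m)) {
          nj <- sum(has_m[, a] & has_m[, b])
          if (nj >= min_support && nj > 0) {
            rows[[length(rows) + 1]] <- data.frame(
              kind = "MM", code_a = all_m[a], code_b = all_m[b],
              sex = strata$sex[s], age_band = strata$age_band[s],
              n_joint = nj, n_a = sum(has_m[, a]), n_b = sum(has_m[, b]),
              n_total = n_total)
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q <- out$n_joint * as.numeric(out$n_total) /
    (as.numeric(out$n_a) * as.numeric(out$n_b))
  out$n_joint <- as.integer(out$n_joint)
  out$n_a <- as.integer(out$n_a)
  out$n_b <- as.integer(out$n_b)
  out$n_total <- as.integer(out$n_total)
  out$age_band <- as.integer(out$age_band)
  out <- out[order(out$kind, out$code_a, out$code_b, out$sex,
                   out$age_band), ]
  tibble::as_tibble(out)
}

# A truth with independent diseases, used where exact independence or the
# 1/p closed form is asserted.
bernoulli_truth <- function(...) {
  aoprx::generator_truth(
    disease_mode = "bernoulli",
    comorbidities = tibble::tibble(code_a = character(),
                                   code_b = character(),
                                   multiplier = double()),
    ...)
}

# Minimal one-disease / one-medication world.
degenerate_truth <- function(error_rate = 0) {
  aoprx::generator_truth(
    error_rate = error_rate,
    diseases = tibble::tibble(code = "D1", name = "only disease",
                              weight = 1, prevalence = 0.5,
                              age_coef = 0, female_mult = 1),
    indications = tibble::tibble(disease = "D1", medication = "M1",
                                 prob = 1),
    comedications = tibble::tibble(trigger = character(),
                                   companion = character(),
                                   prob = double()),
    comorbidities = tibble::tibble(code_a = character(),
                                   code_b = character(),
                                   multiplier = double()),
    k_pmf = c("1" = 1))
}
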