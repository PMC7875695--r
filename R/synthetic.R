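#' Default synthetic disease catalog
#'
#' Ten chronic and acute outpatient conditions with ICD-10-CM codes.
#' `weight` is the relative visit-sampling weight used by the `"visit"`
#' disease mode; `prevalence` is the per-prescription marginal used by the
#' `"bernoulli"` mode; `age_coef` tilts the weight linearly across 5-year
#' age bands (band 10, ages 50-54, is the pivot) and `female_mult`
#' multiplies the weight for female patients.
#'
#' @return A tibble with `code`, `name`, `weight`, `prevalence`,
#'   `age_coef`, `female_mult`.
#' @export
default_disease_catalog <- function() {
  tibble::tribble(
    ~code,     ~name,                     ~weight, ~age_coef, ~female_mult,
    "I10",     "essential hypertension",     1.00,       0.8,          1.0,
    "E11.9",   "type 2 diabetes mellitus",   0.55,       0.6,          1.0,
    "E78.5",   "hyperlipidemia",             0.85,       0.5,          1.0,
    "J06.9",   "acute upper respiratory infection",
                                             0.60,      -0.5,          1.0,
    "M17.9",   "osteoarthritis of knee",     0.45,       0.9,          1.2,
    "F32.9",   "major depressive disorder",  0.40,      -0.2,          1.4,
    "G40.909", "epilepsy, unspecified",      0.10,       0.0,          1.0,
    "M06.9",   "rheumatoid arthritis",       0.15,       0.2,          2.0,
    "K21.9",   "gastro-esophageal reflux",   0.50,       0.2,          1.0,
    "I25.10",  "atherosclerotic heart disease",
                                             0.35,       1.0,          0.7
  ) |>
    mutate(prevalence = 0.25 * .data$weight)
}

#' Default indication map
#'
#' Probability that each indicated medication is prescribed, given that the
#' disease is on the prescription; each draw is independent, so a
#' medication indicated by several present diseases is prescribed with the
#' complement-product probability.
#'
#' @return A tibble with `disease`, `medication`, `prob`.
#' @export
default_indication_map <- function() {
  tibble::tribble(
    ~disease,  ~medication, ~prob,
    "I10",     "C03CA01",   0.20,  # furosemide
    "I10",     "C09CA01",   0.35,  # losartan
    "I10",     "C07AB02",   0.25,  # metoprolol
    "I10",     "C08CA01",   0.25,  # amlodipine
    "E11.9",   "A10BA02",   0.65,  # metformin
    "E11.9",   "A10AB01",   0.20,  # insulin
    "E78.5",   "C10AA05",   0.45,  # atorvastatin
    "E78.5",   "C10AA01",   0.20,  # simvastatin
    "J06.9",   "N02BE01",   0.40,  # paracetamol
    "J06.9",   "R06AE07",   0.30,  # cetirizine
    "M17.9",   "M01AE01",   0.40,  # ibuprofen
    "M17.9",   "N02BE01",   0.25,
    "M17.9",   "N02AA05",   0.10,  # oxycodone
    "F32.9",   "N06AB03",   0.40,  # fluoxetine
    "F32.9",   "N06AB06",   0.30,  # sertraline
    "F32.9",   "N05BA01",   0.10,  # diazepam
    "G40.909", "N03AX14",   0.75,  # levetiracetam
    "M06.9",   "L01BA01",   0.55,  # methotrexate
    "M06.9",   "P01BA02",   0.30,  # hydroxychloroquine
    "K21.9",   "A02BC01",   0.60,  # omeprazole
    "I25.10",  "B01AC06",   0.55,  # aspirin
    "I25.10",  "C07AB02",   0.30
  )
}

#' Default co-medication rules
#'
#' Companion medications added with probability `prob` when the trigger
#' medication was drawn by indication (the planted M-M structure, e.g.
#' folic acid supplementation alongside methotrexate).
#'
#' @return A tibble with `trigger`, `companion`, `prob`.
#' @export
default_comedication_rules <- function() {
  tibble::tribble(
    ~trigger,  ~companion, ~prob,
    "L01BA01", "B03BB01",  0.85
  )
}

#' Default comorbidity structure
#'
#' Pairwise multipliers applied to a disease's sampling weight when its
#' comorbid partner has already been drawn for the visit. The
#' hypertension / type 2 diabetes pair is the planted source of
#' pseudo-associations (insulin acquiring lift with hypertension).
#'
#' @return A tibble with `code_a`, `code_b`, `multiplier`.
#' @export
default_comorbidities <- function() {
  tibble::tribble(
    ~code_a,  ~code_b,   ~multiplier,
    "I10",    "E11.9",   2.5,
    "I10",    "I25.10",  2.0,
    "E78.5",  "I25.10",  1.8
  )
}

#' Ground truth for the synthetic prescription generator
#'
#' Defines a synthetic outpatient world: demographics, a disease catalog
#' with per-stratum sampling weights, an indication map, comorbidity and
#' co-medication structure, and a controlled error-injection process that
#' adds, with probability `error_rate`, one medication indicated by none of
#' the visit's diagnoses. Two disease-sampling modes are available:
#' \describe{
#'   \item{`"visit"` (default)}{the number of diagnoses is drawn from
#'     `k_pmf` and diseases are sampled without replacement with
#'     comorbidity-adjusted weights, mimicking themed clinic visits
#'     (diseases are negatively correlated, as in real per-visit coding).}
#'   \item{`"bernoulli"`}{each disease enters independently with its
#'     (stratum-adjusted) `prevalence`; pairs of diseases are then exactly
#'     independent, which is what the lift-calibration oracle needs.}
#' }
#' In both modes a prescription whose indicated medication draws all come
#' up empty receives a health-maintenance filler (a `Z00.0` encounter
#' diagnosis plus a vitamin-supplement medication) rather than being
#' redrawn, so disease and medication draws stay exactly independent
#' across unrelated pairs.
#'
#' @param preset Demographic preset: `"local"` (age mean 53.4, SD 19.8,
#'   36% male — a US academic-center profile) or `"original"` (age mean
#'   46.6, SD 23.3, 45% male — a Taiwan national-claims profile). Ages are
#'   truncated to [18, 100).
#' @param error_rate Probability that a prescription receives one injected,
#'   unindicated medication (ground-truth unsubstantiated).
#' @param severity_mix Probabilities of (life_threatening, serious,
#'   significant) for injected errors; must sum to 1. The default mirrors
#'   the observed review mix (0, 27/232, 205/232).
#' @param disease_mode `"visit"` or `"bernoulli"` (see above).
#' @param diseases,indications,comedications,comorbidities Optional
#'   replacement tables (see the `default_*` functions for schemas).
#' @param k_pmf Named numeric: probability of 1, 2, ... diagnoses per
#'   visit (`"visit"` mode).
#' @param demographics Optional list overriding `age_mean`, `age_sd`,
#'   `age_min`, `age_max`, `p_male`.
#' @param seed Stored for provenance; truth construction is deterministic.
#' @return An object of class `aop_truth`.
#' @export
generator_truth <- function(preset = c("local", "original"),
                            error_rate = 0.1,
                            severity_mix = c(life_threatening = 0,
                                             serious = 27 / 232,
                                             significant = 205 / 232),
                            disease_mode = c("visit", "bernoulli"),
                            diseases = default_disease_catalog(),
                            indications = default_indication_map(),
                            comedications = default_comedication_rules(),
                            comorbidities = default_comorbidities(),
                            k_pmf = c("1" = 0.30, "2" = 0.30,
                                      "3" = 0.25, "4" = 0.15),
                            demographics = list(),
                            seed = NULL) {
  preset <- match.arg(preset)
  disease_mode <- match.arg(disease_mode)
  stopifnot(nrow(diseases) >= 1,
            all(indications$disease %in% diseases$code),
            all(indications$prob >= 0 & indications$prob <= 1),
            abs(sum(severity_mix) - 1) < 1e-8,
            error_rate >= 0, error_rate <= 1)
  if (disease_mode == "visit" &&
      max(as.integer(names(k_pmf))) > nrow(diseases)) {
    stop("k_pmf allows more diagnoses than the catalog has diseases",
         call. = FALSE)
  }
  demo_default <- switch(preset,
    local = list(age_mean = 53.4, age_sd = 19.8, age_min = 18,
                 age_max = 100, p_male = 0.36),
    original = list(age_mean = 46.6, age_sd = 23.3, age_min = 18,
                    age_max = 100, p_male = 0.45))
  demo <- modifyList(demo_default, demographics)
  filler <- list(disease = "Z00.0", medication = "A11CC05")
  meds <- sort(unique(c(indications$medication, comedications$companion,
                        comedications$trigger, filler$medication)))
  truth <- list(
    preset = preset,
    disease_mode = disease_mode,
    diseases = as_tibble(diseases),
    indications = as_tibble(indications),
    comedications = as_tibble(comedications),
    comorbidities = as_tibble(comorbidities),
    medications = meds,
    k_pmf = k_pmf / sum(k_pmf),
    error_rate = error_rate,
    severity_mix = severity_mix,
    demographics = demo,
    filler = filler,
    seed = seed,
    cache = new.env(parent = emptyenv())
  )
  if (disease_mode == "bernoulli" && nrow(diseases) > 14) {
    stop("bernoulli mode enumerates 2^n disease subsets; use <= 14 diseases",
         call. = FALSE)
  }
  structure(truth, class = "aop_truth")
}

#' @export
print.aop_truth <- function(x, ...) {
  cat(sprintf(
    "<aop_truth '%s' preset, %s disease mode> %d diseases, %d medications, error rate %.3g\n",
    x$preset, x$disease_mode, nrow(x$diseases), length(x$medications),
    x$error_rate))
  invisible(x)
}

# ---- stratum machinery -----------------------------------------------------

truth_strata <- function(truth) {
  demo <- truth$demographics
  bands <- (demo$age_min %/% 5L):((demo$age_max - 1L) %/% 5L)
  z <- function(a) pnorm((a - demo$age_mean) / demo$age_sd)
  lo <- pmax(bands * 5, demo$age_min)
  hi <- pmin(bands * 5 + 5, demo$age_max)
  band_prob <- (z(hi) - z(lo)) / (z(demo$age_max) - z(demo$age_min))
  tidyr::expand_grid(sex = c("male", "female"), age_band = bands) |>
    mutate(prob = ifelse(.data$sex == "male", demo$p_male,
                         1 - demo$p_male) *
             band_prob[match(.data$age_band, bands)])
}

disease_weights_for_stratum <- function(truth, sex, band) {
  d <- truth$diseases
  base <- if (truth$disease_mode == "visit") d$weight else d$prevalence
  age_mult <- pmax(0.05, 1 + d$age_coef * (band - 10) / 10)
  sex_mult <- if (sex == "female") d$female_mult else 1
  w <- base * age_mult * sex_mult
  if (truth$disease_mode == "bernoulli") w <- pmin(w, 0.95)
  w
}

comorbidity_matrix <- function(truth) {
  codes <- truth$diseases$code
  M <- matrix(1, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (i in seq_len(nrow(truth$comorbidities))) {
    a <- truth$comorbidities$code_a[i]
    b <- truth$comorbidities$code_b[i]
    m <- truth$comorbidities$multiplier[i]
    M[a, b] <- m
    M[b, a] <- m
  }
  M
}

enum_visit_subsets <- function(w, M, k_pmf) {
  n <- length(w)
  kmax <- min(max(as.integer(names(k_pmf))), n)
  acc <- new.env(parent = emptyenv())
  recurse <- function(drawn, mult, p) {
    k <- length(drawn)
    if (k > 0) {
      pk <- k_pmf[as.character(k)]
      if (!is.na(pk) && pk > 0) {
        key <- paste(sort(drawn), collapse = ",")
        prev <- acc[[key]]
        acc[[key]] <- (if (is.null(prev)) 0 else prev) + p * pk
      }
    }
    if (k < kmax) {
      avail <- setdiff(seq_len(n), drawn)
      v <- w[avail] * mult[avail]
      tot <- sum(v)
      if (tot <= 0) return(invisible())
      for (i in seq_along(avail)) {
        d <- avail[i]
        recurse(c(drawn, d), mult * M[d, ], p * v[i] / tot)
      }
    }
  }
  recurse(integer(0), rep(1, n), 1)
  keys <- ls(acc)
  tibble(subset = keys,
         prob = vapply(keys, function(k) acc[[k]], 0, USE.NAMES = FALSE))
}

enum_bernoulli_subsets <- function(p, filler_key) {
  n <- length(p)
  B <- as.matrix(expand.grid(rep(list(0:1), n)))
  lp <- ifelse(p > 0, log(p), -745)
  l1p <- ifelse(p < 1, log1p(-p), -745)
  prob <- exp(drop(B %*% lp + (1 - B) %*% l1p))
  keys <- apply(B, 1, function(row) {
    idx <- which(row == 1)
    if (length(idx) == 0) filler_key else paste(idx, collapse = ",")
  })
  tibble(subset = keys, prob = prob) |>
    group_by(.data$subset) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
}

# Per-stratum exact disease-subset distribution. Subset keys are
# comma-joined sorted disease indices ("F" denotes the filler diagnosis).
subset_distribution <- function(truth) {
  cached <- truth$cache$subset_distribution
  if (!is.null(cached)) return(cached)
  strata <- truth_strata(truth)
  M <- comorbidity_matrix(truth)
  per <- lapply(seq_len(nrow(strata)), function(i) {
    w <- disease_weights_for_stratum(truth, strata$sex[i],
                                     strata$age_band[i])
    tab <- if (truth$disease_mode == "visit") {
      enum_visit_subsets(w, M, truth$k_pmf)
    } else {
      if (any(M != 1)) {
        stop("bernoulli disease mode assumes independent diseases; ",
             "comorbidity multipliers must all be 1", call. = FALSE)
      }
      enum_bernoulli_subsets(w, "F")
    }
    tab$sex <- strata$sex[i]
    tab$age_band <- strata$age_band[i]
    tab$stratum_prob <- strata$prob[i]
    tab
  })
  out <- list(strata = strata, subsets = bind_rows(per))
  truth$cache$subset_distribution <- out
  out
}

decode_subset <- function(truth, key) {
  if (key == "F") return(character(0))
  truth$diseases$code[as.integer(strsplit(key, ",", fixed = TRUE)[[1]])]
}

# Closed-form medication model given a disease subset:
#  r_base  — P(med drawn by indication), 1 - prod(1 - p) over indications in S
#  p_ic    — r_base extended by co-medication paths (trigger base-drawn,
#            then companion with prob pc)
#  err     — candidate set for error injection: no indication in S, not a
#            companion of an indicated trigger, never the filler medication
#            (disjoint from legitimately drawable medications)
#  p0      — P(no indicated medication at all); such prescriptions receive
#            the health-maintenance filler (Z00.0 diagnosis + filler
#            medication) instead of being redrawn, so disease and
#            medication draws stay exactly independent across pairs.
subset_med_model <- function(truth, key) {
  cache_key <- paste0("med:", key)
  cached <- truth$cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  S <- decode_subset(truth, key)
  meds <- truth$medications
  r_base <- setNames(rep(0, length(meds)), meds)
  ind <- truth$indications[truth$indications$disease %in% S, ]
  if (nrow(ind) > 0) {
    fail <- tapply(1 - ind$prob, ind$medication, prod)
    r_base[names(fail)] <- 1 - fail
  }
  p_ic <- r_base
  com <- truth$comedications
  companion_possible <- character(0)
  if (nrow(com) > 0) {
    active <- com[r_base[com$trigger] > 0, , drop = FALSE]
    if (nrow(active) > 0) {
      companion_possible <- unique(active$companion)
      for (i in seq_len(nrow(active))) {
        m <- active$companion[i]
        p_ic[m] <- 1 - (1 - p_ic[m]) *
          (1 - r_base[active$trigger[i]] * active$prob[i])
      }
    }
  }
  err <- meds[r_base == 0 & !meds %in% companion_possible &
                meds != truth$filler$medication]
  eps <- if (length(err) > 0) truth$error_rate else 0
  p0 <- prod(1 - r_base)
  out <- list(r_base = r_base, p_ic = p_ic, err = err, eps = eps, p0 = p0,
              active_com = if (nrow(com) > 0)
                com[r_base[com$trigger] > 0, , drop = FALSE] else com)
  truth$cache[[cache_key]] <- out
  out
}

# Marginal P(med present | subset). The error channel is disjoint from the
# indicated channel; the filler medication appears exactly when no
# indicated medication was drawn.
subset_med_prob <- function(truth, mm, med) {
  if (med == truth$filler$medication) return(mm$p0)
  p <- unname(mm$p_ic[med])
  if (med %in% mm$err) p <- p + mm$eps / length(mm$err)
  p
}

#' Exact expected lift under the generator
#'
#' Computes the population lift `P(a,b) / (P(a) P(b))` of a
#' disease-medication or medication-medication pair implied by a generator
#' truth, by exact enumeration of the disease-subset distribution (per
#' stratum, marginalised over the demographic mix) combined with
#' closed-form conditional medication probabilities, including the
#' "at least one medication" rejection normalisation and the
#' error-injection contribution. This is the oracle that mined Q values are
#' checked against: for a medication prescribed only when disease D is
#' present, it reduces to `1 / P(D)` as the indication probability's
#' contribution cancels.
#'
#' @param truth An `aop_truth`.
#' @param kind `"DM"` or `"MM"`.
#' @param code_a,code_b The pair (diagnosis then medication for `"DM"`;
#'   two medications for `"MM"`, order irrelevant).
#' @return The expected lift (a positive scalar).
#' @export
analytic_lift <- function(truth, kind = c("DM", "MM"), code_a, code_b) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "aop_truth"))
  sd <- subset_distribution(truth)
  tab <- sd$subsets
  w <- tab$prob * tab$stratum_prob
  keys <- unique(tab$subset)
  mms <- setNames(lapply(keys, function(k) subset_med_model(truth, k)), keys)
  filler_med <- truth$filler$medication
  if (kind == "DM") {
    if (!code_a %in% c(truth$diseases$code, truth$filler$disease)) {
      stop("unknown diagnosis code: ", code_a, call. = FALSE)
    }
    if (!code_b %in% truth$medications) {
      stop("unknown medication code: ", code_b, call. = FALSE)
    }
    p_m_given <- vapply(tab$subset, function(k)
      subset_med_prob(truth, mms[[k]], code_b), 0)
    p_m <- sum(w * p_m_given)
    if (code_a == truth$filler$disease) {
      # the filler diagnosis is present exactly when no indicated
      # medication was drawn
      p_d_given <- vapply(tab$subset, function(k) mms[[k]]$p0, 0)
      joint_given <- vapply(tab$subset, function(k) {
        mm <- mms[[k]]
        if (code_b == filler_med) mm$p0
        else if (code_b %in% mm$err) mm$p0 * mm$eps / length(mm$err)
        else 0
      }, 0)
      return(sum(w * joint_given) / (sum(w * p_d_given) * p_m))
    }
    has_d <- vapply(tab$subset, function(k)
      code_a %in% decode_subset(truth, k), NA)
    p_d <- sum(w[has_d])
    p_dm <- sum((w * p_m_given)[has_d])
    return(p_dm / (p_d * p_m))
  }
  if (!all(c(code_a, code_b) %in% truth$medications)) {
    stop("unknown medication code(s)", call. = FALSE)
  }
  joint_given <- vapply(tab$subset, function(k) {
    mm <- mms[[k]]
    err_p <- function(m) if (m %in% mm$err) mm$eps / length(mm$err) else 0
    if (code_a == filler_med || code_b == filler_med) {
      # filler co-occurs with a real medication only via error injection
      other <- if (code_a == filler_med) code_b else code_a
      return(mm$p0 * err_p(other))
    }
    p1_ic <- unname(mm$p_ic[code_a])
    p2_ic <- unname(mm$p_ic[code_b])
    com <- mm$active_com
    comed_joint <- function(trigger, companion) {
      # P(trigger and companion both present through the indicated channel)
      rule <- com[com$trigger == trigger & com$companion == companion, ,
                  drop = FALSE]
      com2 <- com[com$companion == companion & com$trigger != trigger, ,
                  drop = FALSE]
      other <- if (nrow(com2) > 0) {
        prod(1 - mm$r_base[com2$trigger] * com2$prob)
      } else 1
      unname(mm$r_base[trigger]) *
        (1 - (1 - unname(mm$r_base[companion])) *
           (1 - rule$prob[1]) * other)
    }
    joint_ic <- if (any(com$trigger == code_a & com$companion == code_b)) {
      comed_joint(code_a, code_b)
    } else if (any(com$trigger == code_b & com$companion == code_a)) {
      comed_joint(code_b, code_a)
    } else {
      p1_ic * p2_ic
    }
    joint_ic + p1_ic * err_p(code_b) + err_p(code_a) * p2_ic
  }, 0)
  p1 <- sum(w * vapply(tab$subset, function(k)
    subset_med_prob(truth, mms[[k]], code_a), 0))
  p2 <- sum(w * vapply(tab$subset, function(k)
    subset_med_prob(truth, mms[[k]], code_b), 0))
  sum(w * joint_given) / (p1 * p2)
}

# ---- corpus sampling -------------------------------------------------------

#' Generate a labelled synthetic corpus
#'
#' Draws `n` prescriptions from a generator truth: demographics, a
#' diagnosis set (per the disease mode), indicated medications, companion
#' medications, and — with probability `error_rate` — one injected
#' medication indicated by none of the visit's diagnoses, with a severity
#' grade drawn from `severity_mix`. Prescriptions whose indicated draws
#' come up empty receive the health-maintenance filler instead, so every
#' prescription satisfies the corpus invariants. The per-prescription
#' ground truth records exactly which medication was injected: a
#' prescription is unsubstantiated if and only if it carries an injected
#' medication.
#'
#' @param truth An `aop_truth`.
#' @param n Number of prescriptions (>= 1).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return An object of class `aop_labeled_corpus`: a list with `corpus`
#'   (a prescription corpus tibble) and `labels` (tibble `rx_id`, `label`,
#'   `injected_medication`, `severity`).
#' @export
generate_corpus <- function(truth, n, seed) {
  stopifnot(inherits(truth, "aop_truth"), n >= 1)
  withr::with_seed(seed, generate_corpus_impl(truth, n))
}

generate_corpus_impl <- function(truth, n) {
  demo <- truth$demographics
  sex <- ifelse(runif(n) < demo$p_male, "male", "female")
  zlo <- pnorm((demo$age_min - demo$age_mean) / demo$age_sd)
  zhi <- pnorm((demo$age_max - demo$age_mean) / demo$age_sd)
  age_cont <- demo$age_mean + demo$age_sd *
    qnorm(runif(n, zlo, zhi))
  age <- pmin(pmax(floor(age_cont), demo$age_min), demo$age_max - 1L)
  band <- age %/% 5L

  sd_tab <- subset_distribution(truth)
  stratum_key <- paste(sex, band)
  subset_key <- character(n)
  tab <- sd_tab$subsets
  tab_key <- paste(tab$sex, tab$age_band)
  for (k in unique(stratum_key)) {
    idx <- which(stratum_key == k)
    rows <- which(tab_key == k)
    pick <- rows[sample.int(length(rows), length(idx), replace = TRUE,
                            prob = tab$prob[rows])]
    subset_key[idx] <- tab$subset[pick]
  }

  keys <- unique(subset_key)
  models <- setNames(lapply(keys, function(k) subset_med_model(truth, k)),
                     keys)
  base_tabs <- lapply(models, function(mm) {
    tibble(medication = names(mm$r_base)[mm$r_base > 0],
           prob = unname(mm$r_base[mm$r_base > 0]))
  })
  eps_by_key <- vapply(models, function(mm) mm$eps, 0)
  err_by_key <- lapply(models, function(mm) mm$err)
  # indicated medications
  nb <- vapply(base_tabs[subset_key], nrow, 0L)
  rx_rep <- rep.int(seq_len(n), nb)
  bt <- bind_rows(base_tabs[subset_key])
  drawn <- runif(nrow(bt)) < bt$prob
  base_long <- tibble(rx = rx_rep[drawn], medication = bt$medication[drawn])
  # companion medications off base-drawn triggers
  com <- truth$comedications
  if (nrow(com) > 0 && nrow(base_long) > 0) {
    cand <- inner_join(base_long, com, by = c(medication = "trigger"),
                       relationship = "many-to-many")
    fired <- runif(nrow(cand)) < cand$prob
    base_long <- bind_rows(base_long,
                           tibble(rx = cand$rx[fired],
                                  medication = cand$companion[fired]))
  }
  med_sets <- rep(list(character(0)), n)
  f <- factor(base_long$rx, levels = seq_len(n))
  sets <- split(base_long$medication, f)
  nonempty <- lengths(sets) > 0
  med_sets[nonempty] <- lapply(sets[nonempty],
                               function(m) sort(unique(m)))
  # prescriptions with no indicated medication get the health-maintenance
  # filler (Z00.0 encounter plus filler medication)
  filler_rx <- !nonempty
  med_sets[filler_rx] <- list(truth$filler$medication)
  # error injection, independent of the indicated draw
  injected <- rep(NA_character_, n)
  err_flag <- runif(n) < eps_by_key[subset_key]
  which_err <- which(err_flag)
  if (length(which_err) > 0) {
    lens <- lengths(err_by_key[subset_key[which_err]])
    pick <- ceiling(runif(length(which_err)) * lens)
    injected[which_err] <- mapply(function(k, i) err_by_key[[k]][i],
                                  subset_key[which_err], pick)
    med_sets[which_err] <- mapply(function(m, e) sort(unique(c(m, e))),
                                  med_sets[which_err], injected[which_err],
                                  SIMPLIFY = FALSE)
  }

  diagnoses <- lapply(subset_key, function(k)
    sort(decode_subset(truth, k)))
  diagnoses[filler_rx] <- lapply(diagnoses[filler_rx], function(d)
    sort(c(d, truth$filler$disease)))
  rx_id <- sprintf("rx%07d", seq_len(n))
  corpus <- tibble(
    rx_id = rx_id,
    patient_id = sprintf("pt%07d", seq_len(n)),
    age = as.integer(age),
    sex = sex,
    diagnoses = diagnoses,
    medications = med_sets
  )
  severity <- rep(NA_character_, n)
  has_inj <- !is.na(injected)
  if (any(has_inj)) {
    severity[has_inj] <- sample(severity_levels, sum(has_inj),
                                replace = TRUE, prob = truth$severity_mix)
  }
  labels <- tibble(
    rx_id = rx_id,
    label = ifelse(has_inj, "unsubstantiated", "substantiated"),
    injected_medication = injected,
    severity = severity
  )
  structure(list(corpus = corpus, labels = labels),
            class = "aop_labeled_corpus")
}

#' @export
print.aop_labeled_corpus <- function(x, ...) {
  cat(sprintf(
    "<aop_labeled_corpus> %d prescriptions, %d (%.1f%%) unsubstantiated\n",
    nrow(x$corpus), sum(x$labels$label == "unsubstantiated"),
    100 * mean(x$labels$label == "unsubstantiated")))
  invisible(x)
}

#' Write a labelled corpus to disk
#'
#' Emits the standard corpus file plus a labels sidecar
#' (`rx_id`, `label`, `injected_medication`, `severity`).
#'
#' @param labeled An `aop_labeled_corpus`.
#' @param corpus_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_corpus <- function(labeled, corpus_path, labels_path) {
  stopifnot(inherits(labeled, "aop_labeled_corpus"))
  write_corpus(labeled$corpus, corpus_path)
  readr::write_delim(labeled$labels, labels_path, delim = "\t",
                     progress = FALSE, na = "")
  invisible(c(corpus_path, labels_path))
}

#' Read a labels sidecar file
#'
#' @param path Path written by [write_labeled_corpus()].
#' @return A tibble with `rx_id`, `label`, `injected_medication`,
#'   `severity`.
#' @export
read_labels <- function(path) {
  readr::read_delim(
    path, delim = "\t", na = "",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
}
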