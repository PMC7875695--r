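#' Prescription corpora
#'
#' A prescription corpus is a tibble with one row per clinic-visit
#' prescription and columns:
#' \describe{
#'   \item{rx_id}{character, unique prescription identifier}
#'   \item{patient_id}{character, opaque patient identifier}
#'   \item{age}{integer years, >= 0}
#'   \item{sex}{\code{"male"} or \code{"female"}}
#'   \item{diagnoses}{list column of ICD-10-CM code sets (>= 1 code)}
#'   \item{medications}{list column of ATC code sets (>= 1 code)}
#' }
#' Codes within a prescription form a set: duplicates are collapsed and the
#' stored order is sorted, so file round-trips are exact.
#'
#' The on-disk dialect is tab-delimited text with that header; the two code
#' columns hold the set members joined by a secondary delimiter
#' (\code{";"} by default).
#'
#' @name prescription-corpus
NULL

corpus_columns <- c("rx_id", "patient_id", "age", "sex",
                    "diagnoses", "medications")

#' Assemble and validate a prescription corpus
#'
#' Normalises the two code columns to sorted, de-duplicated character sets
#' and checks the corpus invariants (non-empty code sets, non-negative age,
#' known sex levels, unique rx_id).
#'
#' @param df A data frame with the columns listed in
#'   [prescription-corpus]. `diagnoses`/`medications` may be list columns
#'   or secondary-delimited strings.
#' @param code_sep Secondary delimiter used when code columns are strings.
#' @param on_error `"abort"` stops on the first invalid row; `"skip"` drops
#'   invalid rows, attaches them as the `"rejected"` attribute and reports
#'   how many were dropped.
#' @return A validated corpus tibble. With `on_error = "skip"` the rejected
#'   rows (plus a `problem` column) are attached as `attr(x, "rejected")`.
#' @export
as_prescription_corpus <- function(df, code_sep = ";",
                                   on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  missing <- setdiff(corpus_columns, names(df))
  if (length(missing) > 0) {
    stop("corpus is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df)[corpus_columns]
  df$rx_id <- as.character(df$rx_id)
  df$patient_id <- as.character(df$patient_id)
  df$age <- as.integer(df$age)
  df$sex <- as.character(df$sex)
  df$diagnoses <- normalize_code_sets(df$diagnoses, code_sep)
  df$medications <- normalize_code_sets(df$medications, code_sep)

  problem <- rep(NA_character_, nrow(df))
  bad <- function(cond, msg) ifelse(cond & is.na(problem), msg, problem)
  problem <- bad(is.na(df$age) | df$age < 0, "age missing or negative")
  problem <- bad(!df$sex %in% c("male", "female"), "unknown sex level")
  problem <- bad(lengths(df$diagnoses) == 0, "empty diagnosis set")
  problem <- bad(lengths(df$medications) == 0, "empty medication set")

  if (anyNA(df$rx_id) || anyDuplicated(df$rx_id[is.na(problem)]) > 0) {
    stop("rx_id must be present and unique", call. = FALSE)
  }
  if (any(!is.na(problem))) {
    if (on_error == "abort") {
      i <- which(!is.na(problem))[1]
      stop(sprintf("invalid prescription row %d (%s): %s",
                   i, df$rx_id[i], problem[i]), call. = FALSE)
    }
    rejected <- df[!is.na(problem), ]
    rejected$problem <- problem[!is.na(problem)]
    df <- df[is.na(problem), ]
    attr(df, "rejected") <- rejected
    message(nrow(rejected), " invalid prescription row(s) skipped")
  }
  df
}

normalize_code_sets <- function(x, code_sep) {
  if (length(x) == 0) return(list())
  if (!is.list(x)) {
    x <- strsplit(ifelse(is.na(x), "", as.character(x)), code_sep,
                  fixed = TRUE)
  }
  lapply(x, function(codes) {
    codes <- trimws(as.character(codes))
    sort(unique(codes[nzchar(codes)]))
  })
}

#' Read / write a prescription corpus file
#'
#' Delimited text, one row per prescription, with the documented header
#' (`rx_id`, `patient_id`, `age`, `sex`, `diagnoses`, `medications`); code
#' sets are stored as strings joined by `code_sep`. `write_corpus()` followed
#' by `read_corpus()` reproduces the corpus exactly (code sets are kept
#' sorted and de-duplicated).
#'
#' @param path File path.
#' @param delim Column delimiter (default tab).
#' @param code_sep Secondary delimiter inside the code set columns.
#' @param on_error Passed to [as_prescription_corpus()]: `"skip"` counts and
#'   reports malformed rows, `"abort"` stops.
#' @return `read_corpus()`: a corpus tibble (empty files yield an empty
#'   corpus); `write_corpus()`: `path`, invisibly.
#' @export
read_corpus <- function(path, delim = "\t", code_sep = ";",
                        on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  df <- readr::read_delim(
    path, delim = delim, na = character(),
    col_types = readr::cols(
      rx_id = readr::col_character(),
      patient_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      diagnoses = readr::col_character(),
      medications = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  as_prescription_corpus(df, code_sep = code_sep, on_error = on_error)
}

#' @rdname read_corpus
#' @param corpus A prescription corpus tibble.
#' @export
write_corpus <- function(corpus, path, delim = "\t", code_sep = ";") {
  corpus <- as_prescription_corpus(corpus, code_sep = code_sep)
  out <- corpus
  out$diagnoses <- vapply(corpus$diagnoses, paste, "", collapse = code_sep)
  out$medications <- vapply(corpus$medications, paste, "", collapse = code_sep)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Map medication codes onto ATC
#'
#' Applies a many-to-one code-mapping table (for example EPIC or HCPCS
#' source codes to ATC targets) to every medication code in a corpus.
#' Unmapped codes are left in place and reported with their frequencies,
#' never silently dropped.
#'
#' @param corpus A prescription corpus tibble.
#' @param map A code map table with columns `source_system`, `source_code`,
#'   `atc_code` (see [read_code_map()]).
#' @return A list with `corpus` (medication codes substituted, sets
#'   re-normalised) and `unmapped`, a tibble of `source_code` / `n` counting
#'   medication occurrences that had no mapping row; codes that already
#'   appear on the ATC side of the table are treated as mapped identities.
#' @export
map_codes <- function(corpus, map) {
  corpus <- as_prescription_corpus(corpus)
  stopifnot(all(c("source_code", "atc_code") %in% names(map)))
  lookup <- setNames(as.character(map$atc_code), as.character(map$source_code))
  all_codes <- unlist(corpus$medications)
  # codes already on the ATC side of the table count as mapped (identity)
  hit <- all_codes %in% names(lookup) | all_codes %in% lookup
  unmapped <- tibble(source_code = all_codes[!hit]) |>
    count(.data$source_code, name = "n") |>
    arrange(desc(.data$n), .data$source_code)
  corpus$medications <- lapply(corpus$medications, function(meds) {
    mapped <- ifelse(meds %in% names(lookup), lookup[meds], meds)
    sort(unique(unname(mapped)))
  })
  list(corpus = corpus, unmapped = unmapped)
}

#' Read a code-mapping table
#'
#' Three-column delimited text: `source_system` (EPIC, HCPCS, RxNorm,
#' other), `source_code`, `atc_code`. The mapping must be many-to-one onto
#' ATC: a source code mapping to two different targets is an error.
#'
#' @param path File path.
#' @param delim Column delimiter.
#' @return A tibble with the three columns.
#' @export
read_code_map <- function(path, delim = "\t") {
  map <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  stopifnot(all(c("source_system", "source_code", "atc_code") %in% names(map)))
  dup <- map |>
    distinct(.data$source_code, .data$atc_code) |>
    count(.data$source_code) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("source codes map to multiple ATC targets: ",
         paste(dup$source_code, collapse = ", "), call. = FALSE)
  }
  map
}

#' Demographic strata
#'
#' Models are stratified by sex and 5-year age band. Bands are half-open
#' intervals [5k, 5k + 5), indexed k = floor(age / 5), so every age belongs
#' to exactly one band. The pooled (all-ages, both-sexes) stratum is encoded
#' as `sex = "all"`, `age_band = -1`.
#'
#' @param age Integer vector of ages in years (>= 0).
#' @param sex Character vector, `"male"` or `"female"`, recycled to the
#'   length of `age`.
#' @return `age_band()`: integer band indices. `stratum_of()`: a tibble with
#'   `sex` and `age_band`.
#' @examples
#' age_band(c(0, 74, 75))   # 0, 14, 15
#' stratum_of(74, "female")
#' @export
age_band <- function(age) {
  age <- as.integer(age)
  if (anyNA(age) || any(age < 0)) stop("age must be >= 0", call. = FALSE)
  age %/% 5L
}

#' @rdname age_band
#' @export
stratum_of <- function(age, sex) {
  if (!all(sex %in% c("male", "female"))) {
    stop('sex must be "male" or "female"', call. = FALSE)
  }
  tibble(sex = rep_len(as.character(sex), length(age)),
         age_band = age_band(age))
}

pooled_sex <- "all"
pooled_band <- -1L
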