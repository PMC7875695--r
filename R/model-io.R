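#' Save / load an association model
#'
#' Models are serialized as versioned plain text: a commented metadata
#' header (`#aop_model` magic, format version, provenance label, training
#' corpus size, mining options) followed by one tab-separated row per
#' association record. Q values are written with 17 significant digits so a
#' save/load round trip is bit-exact, metadata included. Merged models
#' additionally carry a `source` provenance column (`"O"`/`"L"`).
#'
#' @param model An `aop_model`.
#' @param path File path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the
#'   `aop_model`. Files whose magic or version is wrong, or whose record
#'   table is truncated or malformed, raise an explicit error.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aop_model"))
  m <- model$meta
  header <- c(
    "#aop_model",
    "#format_version: 1",
    paste0("#label: ", m$label),
    paste0("#n_prescriptions: ", m$n_prescriptions),
    paste0("#stratified: ", m$stratified),
    paste0("#min_support: ", format_exact(m$min_support)),
    paste0("#pruned: ", m$pruned)
  )
  if (!is.null(m$merged_from)) {
    header <- c(header, paste0("#merged_from: ",
                               paste(m$merged_from, collapse = ",")))
  }
  rec <- model$records
  rec$q <- format_exact(rec$q)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(rec), collapse = "\t"), con)
  if (nrow(rec) > 0) {
    writeLines(do.call(paste, c(unname(as.list(rec)), sep = "\t")), con)
  }
  invisible(path)
}

format_exact <- function(x) sprintf("%.17g", x)

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "#aop_model") {
    stop("not an association model file (missing #aop_model magic): ", path,
         call. = FALSE)
  }
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get <- function(key, required = TRUE) {
    row <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (length(row) == 0) {
      if (required) stop("corrupt model file: missing header '", key, "'",
                         call. = FALSE)
      return(NULL)
    }
    sub(paste0("^#", key, ": "), "", row[1])
  }
  if (get("format_version") != "1") {
    stop("unsupported model format version: ", get("format_version"),
         call. = FALSE)
  }
  if (length(body) == 0) stop("corrupt model file: no record table",
                              call. = FALSE)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("kind", "code_a", "code_b", "sex", "age_band",
            "n_joint", "n_a", "n_b", "n_total", "q")
  if (!all(need %in% cols)) {
    stop("corrupt model file: record header lacks required columns",
         call. = FALSE)
  }
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  if (length(fields) > 0 && any(lengths(fields) != length(cols))) {
    stop("corrupt model file: truncated or ragged record row", call. = FALSE)
  }
  rec <- as_tibble(setNames(
    lapply(seq_along(cols), function(j)
      vapply(fields, `[[`, "", j)),
    cols
  ))
  for (col in c("age_band", "n_joint", "n_a", "n_b", "n_total")) {
    rec[[col]] <- as.integer(rec[[col]])
  }
  rec$q <- as.numeric(rec$q)
  if (anyNA(rec$q) || anyNA(rec$n_joint)) {
    stop("corrupt model file: non-numeric record fields", call. = FALSE)
  }
  meta <- list(
    label = get("label"),
    n_prescriptions = as.integer(get("n_prescriptions")),
    stratified = as.logical(get("stratified")),
    min_support = as.numeric(get("min_support")),
    pruned = as.logical(get("pruned"))
  )
  merged <- get("merged_from", required = FALSE)
  if (!is.null(merged)) {
    meta$merged_from <- strsplit(merged, ",", fixed = TRUE)[[1]]
  }
  new_aop_model(rec, meta)
}
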