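#' Merge policy for federated model combination
#'
#' The merge is one-shot and fully deterministic: for a (stratum, pair)
#' present in both models, the record with the larger co-occurrence
#' frequency (`n_joint` in its own training corpus) wins; `tie_break`
#' decides equal counts. Pairs present in exactly one model are included
#' (`unshared = "union"`, default) or dropped (`"intersection"`).
#'
#' @param tie_break `"O"` (default; the first, typically larger corpus) or
#'   `"L"`.
#' @param unshared `"union"` or `"intersection"`.
#' @return A list of class `aop_merge_policy`.
#' @export
merge_policy <- function(tie_break = c("O", "L"),
                         unshared = c("union", "intersection")) {
  structure(list(tie_break = match.arg(tie_break),
                 unshared = match.arg(unshared)),
            class = "aop_merge_policy")
}

#' Combine two association models into a hybrid model
#'
#' Implements the one-shot federated combination of an original model (O)
#' and a locally trained model (L): every record of the hybrid model is
#' copied unchanged from one of the two sources, choosing for shared
#' (stratum, pair) keys the source with the higher co-occurrence frequency.
#' A `source` column records the provenance (`"O"` or `"L"`) of every
#' record.
#'
#' @param o_model,l_model `aop_model` objects mined with the same
#'   stratification scheme and Q definition.
#' @param policy A [merge_policy()].
#' @param label Provenance label for the hybrid model (default `"H"`).
#' @return An `aop_model` whose records carry an extra `source` column;
#'   `meta$merged_from` names the two source models.
#' @export
merge_models <- function(o_model, l_model, policy = merge_policy(),
                         label = "H") {
  stopifnot(inherits(o_model, "aop_model"), inherits(l_model, "aop_model"),
            inherits(policy, "aop_merge_policy"))
  if (!identical(isTRUE(o_model$meta$stratified),
                 isTRUE(l_model$meta$stratified))) {
    stop("models use incompatible stratification schemes", call. = FALSE)
  }
  key <- c("kind", "code_a", "code_b", "sex", "age_band")
  o <- o_model$records |> mutate(.row_o = seq_len(n()))
  l <- l_model$records |> mutate(.row_l = seq_len(n()))
  joined <- full_join(o |> select(all_of(key), "n_joint", ".row_o"),
                      l |> select(all_of(key), "n_joint", ".row_l"),
                      by = key, suffix = c("_o", "_l"))
  in_o <- !is.na(joined$.row_o)
  in_l <- !is.na(joined$.row_l)
  shared <- in_o & in_l
  take_o <- (shared & (joined$n_joint_o > joined$n_joint_l |
                         (joined$n_joint_o == joined$n_joint_l &
                            policy$tie_break == "O"))) |
    (in_o & !in_l & policy$unshared == "union")
  take_l <- (shared & !take_o) |
    (in_l & !in_o & policy$unshared == "union")
  drop_source <- function(rec) rec[setdiff(names(rec), "source")]
  from_o <- drop_source(o_model$records)[joined$.row_o[take_o], ] |>
    mutate(source = "O")
  from_l <- drop_source(l_model$records)[joined$.row_l[take_l], ] |>
    mutate(source = "L")
  records <- bind_rows(from_o, from_l) |>
    arrange(.data$kind, .data$code_a, .data$code_b, .data$sex,
            .data$age_band)
  new_aop_model(records, meta = list(
    label = label,
    n_prescriptions = max(o_model$meta$n_prescriptions,
                          l_model$meta$n_prescriptions),
    stratified = isTRUE(o_model$meta$stratified),
    min_support = max(o_model$meta$min_support, l_model$meta$min_support),
    pruned = isTRUE(o_model$meta$pruned) && isTRUE(l_model$meta$pruned),
    merged_from = c(o_model$meta$label, l_model$meta$label)
  ))
}
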