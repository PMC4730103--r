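#' Consensus enrichment across independent studies
#'
#' Pools EWCE evidence for the same contrast measured in several
#' independent cohorts: the per-study bootstrap matrices are summed
#' element-wise (replicate j of every study contributes to consensus
#' replicate j) and the per-study target statistics are summed, then
#' p-values, fold enrichment and z-scores are computed from the sums
#' exactly as for a single study. All studies must share the same group
#' set and replicate count; studies run at different depths are refused
#' rather than resampled.
#'
#' @param targets List of named numeric vectors: each study's per-group
#'   target totals ([summed_specificity()]).
#' @param nulls List of `bootstrap_null` objects, same length and order as
#'   `targets`.
#' @param correction Multiple-testing correction across groups.
#' @param p_method See [bootstrap_test()].
#' @return An `ewce_result` tibble for the consensus.
#' @export
merge_bootstrap <- function(targets, nulls,
                            correction = c("bonferroni", "BH", "none"),
                            p_method = c("plus_one", "raw")) {
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  if (length(targets) != length(nulls) || length(nulls) == 0) {
    abort("`targets` and `nulls` must be non-empty lists of equal length.")
  }
  if (!all(vapply(nulls, inherits, logical(1), "bootstrap_null"))) {
    abort("Every element of `nulls` must be a bootstrap_null object.")
  }

  groups <- nulls[[1]]$groups
  reps <- nulls[[1]]$n_replicates
  for (i in seq_along(nulls)) {
    if (!identical(sort(nulls[[i]]$groups), sort(groups))) {
      abort(sprintf(
        "Study %d has a different group set (%s) than study 1 (%s).",
        i, paste(nulls[[i]]$groups, collapse = ", "), paste(groups, collapse = ", ")
      ))
    }
    if (nulls[[i]]$n_replicates != reps) {
      abort(sprintf(
        "Study %d has %d replicates but study 1 has %d; replicate counts must match.",
        i, nulls[[i]]$n_replicates, reps
      ))
    }
    if (!setequal(names(targets[[i]]), groups)) {
      abort(sprintf("Target totals of study %d do not cover the shared group set.", i))
    }
  }

  sum_values <- Reduce(`+`, lapply(nulls, function(nl) nl$values[, groups, drop = FALSE]))
  sum_target <- Reduce(`+`, lapply(targets, function(tg) tg[groups]))
  n_total <- sum(vapply(nulls, function(nl) nl$list_length, numeric(1)))

  consensus <- new_bootstrap_null(
    sum_values,
    list_length = n_total,
    mode = paste0("merged-", nulls[[1]]$mode),
    seed = nulls[[1]]$seed
  )
  res <- bootstrap_test(sum_target, consensus, correction = correction,
                        p_method = p_method)
  attr(res, "n_studies") <- length(nulls)
  res
}
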