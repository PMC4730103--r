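#' Select the most differentially expressed genes from a ranked table
#'
#' Takes the `k` probes with the most extreme t-statistics in one direction
#' (largest positive for `"up"`, largest negative for `"down"`), then
#' collapses duplicate gene symbols keeping each gene's most extreme probe.
#' The returned list can therefore be shorter than `k`; its actual length
#' is what the matching null lists must use.
#'
#' @param de_table Data frame with columns `probe`, `gene`, `t` (one row
#'   per probe; a gene may appear under several probes).
#' @param k Number of probes to take from the extreme of the ranking
#'   (default 250).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of unique gene symbols, ordered from most to
#'   least extreme. Ties at the selection boundary are broken by input
#'   order (noted when they occur).
#' @export
select_extreme_genes <- function(de_table, k = 250, direction = c("up", "down")) {
  direction <- match.arg(direction)
  de_table <- as.data.frame(de_table)
  need <- c("probe", "gene", "t")
  if (!all(need %in% names(de_table))) abort("`de_table` must have columns probe, gene, t.")
  if (nrow(de_table) < k) abort(sprintf("Need at least k = %d probes, got %d.", k, nrow(de_table)))
  if (any(!is.finite(de_table$t))) abort("All t-statistics must be finite.")
  assert_unique_symbols(as.character(de_table$probe), "probe ids")

  score <- if (direction == "up") de_table$t else -de_table$t
  ord <- order(score, decreasing = TRUE)   # stable: ties keep input order
  boundary <- sort(score, decreasing = TRUE)[k]
  if (sum(score == boundary) > 1 && k < nrow(de_table)) {
    inform(sprintf("t-statistic tie at the top-%d boundary; broken by input order.", k))
  }
  top <- de_table[ord[seq_len(k)], ]
  genes <- normalize_symbols(top$gene)
  unique(genes)
}

#' EWCE on a differential-expression ranking (transcriptome mode)
#'
#' Tests the most up- and most down-regulated gene sets of a disease
#' transcriptome study for cell-type enrichment. The background is
#' restricted to genes both detected in the study and present in the
#' specificity matrix, so the null — random gene lists from that
#' background — is equivalent to re-ranking the detected genes at random.
#' Benjamini-Hochberg correction is applied across both directions and all
#' groups as one family.
#'
#' @inheritParams ewce_test
#' @param de_table Data frame with columns `probe`, `gene`, `t`.
#' @param k Probes per direction (default 250).
#' @param min_genes Minimum unique genes a direction must yield (default
#'   10); fewer is refused.
#' @return An `ewce_result` tibble with a leading `direction` column
#'   (`"up"`, `"down"`), one row per direction x group.
#' @export
ewce_transcriptome <- function(de_table, spec, k = 250, reps = 1e5, seed = NULL,
                               controlled = FALSE, grid = NULL,
                               correction = c("BH", "bonferroni", "none"),
                               p_method = c("plus_one", "raw"),
                               min_genes = 10, keep_null = FALSE) {
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  detected <- unique(normalize_symbols(de_table$gene))

  dirs <- c("up", "down")
  parts <- vector("list", 2)
  names(parts) <- dirs
  nulls <- list()
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    sel <- select_extreme_genes(de_table, k = k, direction = d)
    genes_used <- intersect(sel, spec$gene)
    if (length(genes_used) < min_genes) {
      abort(sprintf(
        "Direction '%s' yields only %d usable gene(s) (minimum %d).",
        d, length(genes_used), min_genes
      ))
    }
    background <- build_background(spec, genes_used, detected_in_study = detected)
    # Both directions reuse the same seed: the null depends only on the
    # background and the list length, so negating every t swaps the up and
    # down results exactly.
    res <- ewce_test(spec, genes_used, background = background, reps = reps,
                     seed = seed, controlled = controlled, grid = grid,
                     correction = "none", p_method = p_method,
                     keep_null = keep_null)
    if (keep_null) nulls[[d]] <- attr(res, "null")
    res <- tidy(res)
    parts[[d]] <- tibble::add_column(res, direction = d, .before = 1)
  }
  out <- dplyr::bind_rows(parts)
  out$p_adj <- if (correction == "none") out$p else correct_pvalues(out$p, correction)
  out <- new_ewce_result(out, correction = correction, p_method = p_method)
  if (keep_null) attr(out, "null") <- nulls
  out
}
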