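#' Summed specificity of a gene list
#'
#' The test statistic: for a gene list X and group c,
#' \eqn{\gamma(X, c) = \sum_{g \in X} e_{g,c}}. Unknown genes are an error —
#' filtering a list against the specificity matrix is the caller's explicit
#' job so that exclusions stay auditable.
#'
#' @param spec Specificity tibble ([specificity()]).
#' @param genes Character vector of gene symbols, all present in `spec`.
#' @return Named numeric vector of per-group totals.
#' @export
summed_specificity <- function(spec, genes) {
  genes <- normalize_symbols(genes)
  m <- group_matrix(spec)
  idx <- match(genes, rownames(m))
  if (anyNA(idx)) {
    abort(sprintf(
      "Gene(s) not in the specificity matrix: %s. Filter the list first.",
      paste(genes[is.na(idx)], collapse = ", ")
    ))
  }
  colSums(m[idx, , drop = FALSE])
}

new_bootstrap_null <- function(values, list_length, mode, seed, lists = NULL) {
  structure(
    list(
      values = values,
      n_replicates = nrow(values),
      list_length = list_length,
      groups = colnames(values),
      mode = mode,
      seed = seed,
      lists = lists
    ),
    class = "bootstrap_null"
  )
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat(sprintf(
    "<bootstrap null> %d replicates x %d groups (lists of %d genes, %s sampling, seed %s)\n",
    x$n_replicates, length(x$groups), x$list_length, x$mode,
    x$seed %||% "unset"
  ))
  invisible(x)
}

# Sum specificity rows over an index matrix (replicates x positions),
# returning a replicates x groups matrix of gamma values.
gamma_from_index_matrix <- function(sm, idx) {
  reps <- nrow(idx)
  values <- matrix(0, nrow = reps, ncol = ncol(sm), dimnames = list(NULL, colnames(sm)))
  for (g in seq_len(ncol(sm))) {
    v <- sm[, g][idx]
    dim(v) <- dim(idx)
    values[, g] <- rowSums(v)
  }
  values
}

#' Uncontrolled bootstrap null: random gene lists from the background
#'
#' Draws `reps` random gene lists of length `n` from the background set,
#' each without replacement and uniformly, and records the summed
#' specificity of every list in every group. This replicate-by-group matrix
#' is the estimated null distribution of the test statistic, and the
#' reusable exchange object for merging studies.
#'
#' @param spec Specificity tibble.
#' @param background Character vector of background genes (all present in
#'   `spec`); see [build_background()].
#' @param n List length (the target list's length).
#' @param reps Number of bootstrap replicates (default 100000).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @param keep_lists Keep the sampled gene lists (a replicates x n
#'   character matrix) for auditing. Off by default: at full scale the
#'   matrix is large and only the gamma values are needed.
#' @return A `bootstrap_null` object.
#' @export
sample_random_lists <- function(spec, background, n, reps = 1e5, seed = NULL,
                                keep_lists = FALSE) {
  m <- group_matrix(spec)
  bg_idx <- match(background, rownames(m))
  if (anyNA(bg_idx)) {
    abort(sprintf(
      "Background gene(s) missing from the specificity matrix: %s.",
      paste(background[is.na(bg_idx)][1:min(5, sum(is.na(bg_idx)))], collapse = ", ")
    ))
  }
  nb <- length(bg_idx)
  if (n > nb) abort(sprintf("List length n = %d exceeds the background size (%d).", n, nb))
  if (n < 1 || reps < 1) abort("`n` and `reps` must be positive.")
  sm <- m[bg_idx, , drop = FALSE]

  idx <- with_seed(seed, {
    if (n == nb) {
      matrix(rep(seq_len(nb), each = reps), nrow = reps)
    } else {
      draws <- vapply(seq_len(reps), function(j) sample.int(nb, n), integer(n))
      if (n == 1L) matrix(draws, ncol = 1L) else t(draws)
    }
  })
  values <- gamma_from_index_matrix(sm, idx)
  lists <- if (keep_lists) {
    l <- rownames(sm)[idx]
    dim(l) <- dim(idx)
    l
  }
  new_bootstrap_null(values, n, "uncontrolled", seed, lists)
}

#' Controlled bootstrap null: property-matched gene sampling
#'
#' Like [sample_random_lists()], but position i of every random list is
#' drawn from the transcript-length x GC-content decile-grid cell of target
#' gene i, so the null lists share the target list's gene-property profile.
#' Within one replicate all genes are distinct whenever the grid cells can
#' supply enough distinct members; a cell asked for more genes than it
#' holds falls back to sampling with replacement for those positions (noted
#' once per run).
#'
#' @inheritParams sample_random_lists
#' @param target Character vector: the target gene list (defines one grid
#'   cell per position). All target genes must be in `spec` and in `grid`.
#' @param grid A [build_decile_grid()] result.
#' @return A `bootstrap_null` object with `mode = "controlled"`.
#' @export
sample_controlled_lists <- function(spec, target, grid, reps = 1e5, seed = NULL,
                                    keep_lists = FALSE) {
  stopifnot(inherits(grid, "decile_grid"))
  target <- normalize_symbols(target)
  m <- group_matrix(spec)
  if (!all(target %in% rownames(m))) {
    abort("All target genes must be present in the specificity matrix.")
  }
  cells <- grid_cell_of(grid, target)$cell
  n <- length(target)

  # Membership of each needed cell, as row indices into the spec matrix.
  mem_idx <- lapply(grid$members, function(g) {
    i <- match(g, rownames(m))
    i[!is.na(i)]
  })
  empty <- cells[lengths(mem_idx[cells]) == 0]
  if (length(empty) > 0) {
    abort(sprintf(
      "Grid cell(s) with no sampleable members for target gene(s): %s.",
      paste(target[cells %in% empty], collapse = ", ")
    ))
  }

  idx <- matrix(0L, nrow = reps, ncol = n)
  with_seed(seed, {
    fell_back <- FALSE
    for (cell in unique(cells)) {
      pos <- which(cells == cell)
      mem <- mem_idx[[cell]]
      t_cell <- length(pos)
      if (t_cell == 1L) {
        idx[, pos] <- mem[sample.int(length(mem), reps, replace = TRUE)]
      } else if (length(mem) >= t_cell) {
        # Distinct genes per replicate within a cell; cells are disjoint, so
        # this guarantees whole-replicate uniqueness.
        draws <- vapply(seq_len(reps),
                        function(j) mem[sample.int(length(mem), t_cell)],
                        integer(t_cell))
        idx[, pos] <- t(draws)
      } else {
        fell_back <- TRUE
        for (p in pos) idx[, p] <- mem[sample.int(length(mem), reps, replace = TRUE)]
      }
    }
    if (fell_back) {
      warn("Some grid cells hold fewer genes than target positions assigned to them; duplicates allowed there.")
    }
  })
  values <- gamma_from_index_matrix(m, idx)
  lists <- if (keep_lists) {
    l <- rownames(m)[idx]
    dim(l) <- dim(idx)
    l
  }
  new_bootstrap_null(values, n, "controlled", seed, lists)
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()] fixing the two corrections used in
#' practice here: Bonferroni (default for susceptibility-gene-list scans)
#' and Benjamini-Hochberg (used when many list x group x direction tests
#' form one family, as in transcriptome mode). The family is whatever is
#' passed in one call.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method `"bonferroni"` or `"BH"`.
#' @return Adjusted p-values, same length and order.
#' @export
correct_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1].")
  p.adjust(p, method = method)
}

#' Bootstrap enrichment test from a target statistic and a null matrix
#'
#' Compares the target list's summed specificity against the bootstrap
#' null, per group: the p-value is the fraction of null lists with summed
#' specificity at least as large as the target's (ties count against the
#' target), fold enrichment is target over null mean, and the z-score is
#' the number of null standard deviations the target sits above the null
#' mean.
#'
#' By default p-values use the add-one correction (k + 1) / (reps + 1),
#' which never reports an exact zero from a finite bootstrap;
#' `p_method = "raw"` gives the plain fraction k / reps, where a zero means
#' "below 1/reps".
#'
#' @param target_gamma Named numeric vector of per-group totals
#'   ([summed_specificity()]); names must match the null's groups.
#' @param null A `bootstrap_null` object.
#' @param correction Multiple-testing correction across the groups of this
#'   call ("bonferroni", "BH", or "none").
#' @param p_method `"plus_one"` (default) or `"raw"`.
#' @return An `ewce_result` tibble with one row per group: `group`,
#'   `n_genes_used`, `gamma`, `p`, `p_adj`, `fold`, `z`, `n_reps`, `seed`,
#'   `mode`. The z-score is `NA` when the null has zero spread.
#' @export
bootstrap_test <- function(target_gamma, null,
                           correction = c("bonferroni", "BH", "none"),
                           p_method = c("plus_one", "raw")) {
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  stopifnot(inherits(null, "bootstrap_null"))
  if (!setequal(names(target_gamma), null$groups) ||
      is.null(names(target_gamma))) {
    abort("Group names of `target_gamma` and the null matrix must be identical.")
  }
  target_gamma <- target_gamma[null$groups]
  values <- null$values
  reps <- null$n_replicates

  exceed <- colSums(values >= rep(target_gamma, each = reps))
  p <- switch(p_method,
    plus_one = (exceed + 1) / (reps + 1),
    raw = exceed / reps
  )
  null_mean <- colMeans(values)
  null_sd <- apply(values, 2, sd)
  fold <- target_gamma / null_mean
  z <- ifelse(null_sd > 0, (target_gamma - null_mean) / null_sd, NA_real_)
  # raw-mode p can be exactly 0; adjust directly rather than through the
  # stricter correct_pvalues() validation
  p_adj <- if (correction == "none") p else p.adjust(p, method = correction)

  out <- tibble::tibble(
    group = null$groups,
    n_genes_used = null$list_length,
    gamma = unname(target_gamma),
    p = unname(p),
    p_adj = unname(p_adj),
    fold = unname(fold),
    z = unname(z),
    n_reps = reps,
    seed = null$seed %||% NA_integer_,
    mode = null$mode
  )
  new_ewce_result(out, correction = correction, p_method = p_method)
}

#' Expression-weighted cell-type enrichment test
#'
#' One-call interface: filters the target list against the specificity
#' matrix, builds the background, draws the bootstrap null (uncontrolled,
#' or decile-grid controlled when `controlled = TRUE`), and tests every
#' group.
#'
#' @param spec Specificity tibble ([specificity()] or
#'   [specificity_from_dataset()]).
#' @param target Character vector of target gene symbols (already in the
#'   reference species; see [map_orthologs()] for cross-species lists).
#' @param background Optional background gene set; defaults to every gene
#'   in the specificity matrix ([build_background()]).
#' @param reps Bootstrap replicates (default 100000).
#' @param seed Integer seed for the bootstrap.
#' @param controlled Match null genes to the target's transcript-length and
#'   GC-content deciles (requires `grid`).
#' @param grid A [build_decile_grid()] result (controlled mode only).
#' @param correction Multiple-testing correction across groups.
#' @param p_method See [bootstrap_test()].
#' @param keep_null Attach the bootstrap null object to the result (needed
#'   for [merge_bootstrap()] and for saving with [write_null()]).
#' @return An `ewce_result` tibble (see [bootstrap_test()]), with
#'   attributes `genes_used` and `genes_excluded`.
#' @export
#' @examples
#' sim <- simulate_sct(n_genes = 200, n_subtypes = 4, cells_per_subtype = 12,
#'                     marker_effect = 8, seed = 1)
#' spec <- specificity_from_dataset(sim$dataset)
#' targ <- simulate_gene_list(sim$markers, group = "subtype1", n = 15,
#'                            purity = 1, seed = 2)
#' ewce_test(spec, targ, reps = 500, seed = 3)
ewce_test <- function(spec, target, background = NULL, reps = 1e5, seed = NULL,
                      controlled = FALSE, grid = NULL,
                      correction = c("bonferroni", "BH", "none"),
                      p_method = c("plus_one", "raw"),
                      keep_null = FALSE) {
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  target <- unique(normalize_symbols(target))
  genes_used <- intersect(target, spec$gene)
  genes_excluded <- setdiff(target, genes_used)
  if (length(genes_excluded) > 0) {
    inform(sprintf(
      "%d target gene(s) not in the specificity matrix were excluded from the test.",
      length(genes_excluded)
    ))
  }
  if (length(genes_used) == 0) abort("No target gene is present in the specificity matrix.")
  background <- background %||% build_background(spec, genes_used)

  if (controlled) {
    if (is.null(grid)) abort("Controlled sampling needs a decile grid (`grid`).")
    no_cell <- setdiff(genes_used, grid$assignment$gene)
    if (length(no_cell) > 0) {
      warn(sprintf(
        "%d target gene(s) lack grid properties and are excluded from the controlled test.",
        length(no_cell)
      ))
      genes_used <- setdiff(genes_used, no_cell)
      genes_excluded <- c(genes_excluded, no_cell)
      if (length(genes_used) == 0) abort("No target gene has grid properties.")
    }
    null <- sample_controlled_lists(spec, genes_used, grid, reps = reps, seed = seed)
  } else {
    null <- sample_random_lists(spec, background, n = length(genes_used),
                                reps = reps, seed = seed)
  }
  gam <- summed_specificity(spec, genes_used)
  res <- bootstrap_test(gam, null, correction = correction, p_method = p_method)
  attr(res, "genes_used") <- genes_used
  attr(res, "genes_excluded") <- genes_excluded
  if (keep_null) attr(res, "null") <- null
  res
}
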