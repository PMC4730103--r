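#' Assemble an annotated single-cell expression dataset
#'
#' Bundles a genes-by-cells expression matrix with its two-level cell
#' annotation (cell -> sub-cell type -> cell type) and validates the
#' structural invariants everything downstream relies on: non-negative
#' expression, unique gene symbols, exactly one sub-cell-type label per
#' cell, exactly one cell-type parent per sub-cell type, and at least one
#' cell per sub-cell type.
#'
#' @param expression Numeric matrix (genes in rows, cells in columns) with
#'   gene symbols as row names and cell ids as column names, or a data frame
#'   whose first column holds gene symbols and remaining columns hold
#'   per-cell expression. Values are non-negative expression measurements
#'   (e.g. UMI counts); no library-size normalisation is applied.
#' @param annotations Data frame with columns `cell_id`, `subtype`,
#'   `celltype`, one row per cell of `expression`.
#'
#' @return An object of class `sc_dataset`: a list with elements
#'   `expression` (numeric matrix), `cell_ids`, `subtype_of_cell` (named
#'   character vector, cell id -> sub-cell type) and `celltype_of_subtype`
#'   (named character vector, sub-cell type -> cell type).
#' @export
#' @examples
#' m <- matrix(rpois(20, 5), nrow = 4,
#'             dimnames = list(paste0("G", 1:4), paste0("c", 1:5)))
#' ann <- data.frame(cell_id = paste0("c", 1:5),
#'                   subtype = c("a1", "a1", "a2", "b1", "b1"),
#'                   celltype = c("A", "A", "A", "B", "B"))
#' ds <- sc_dataset(m, ann)
sc_dataset <- function(expression, annotations) {
  if (is.data.frame(expression)) {
    genes <- normalize_symbols(expression[[1]])
    vals <- as.matrix(expression[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- genes
    expression <- vals
  }
  if (inherits(expression, "Matrix")) expression <- as.matrix(expression)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort("`expression` must be a numeric matrix or a data frame with a gene-symbol first column.")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    abort("`expression` needs gene symbols as row names and cell ids as column names.")
  }
  rownames(expression) <- normalize_symbols(rownames(expression))
  assert_unique_symbols(rownames(expression))
  assert_unique_symbols(colnames(expression), "cell ids")
  if (anyNA(expression)) abort("`expression` contains missing values.")
  if (any(expression < 0)) abort("`expression` contains negative values; expression must be non-negative.")

  annotations <- as.data.frame(annotations)
  need <- c("cell_id", "subtype", "celltype")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` must have columns cell_id, subtype, celltype.")
  }
  annotations$cell_id <- as.character(annotations$cell_id)
  assert_unique_symbols(annotations$cell_id, "cell ids in annotations")
  missing_cells <- setdiff(colnames(expression), annotations$cell_id)
  if (length(missing_cells) > 0) {
    abort(sprintf("Cells without annotation: %s.", paste(head(missing_cells, 5), collapse = ", ")))
  }
  unknown <- setdiff(annotations$cell_id, colnames(expression))
  if (length(unknown) > 0) {
    abort(sprintf("Annotation rows reference unknown cells: %s.", paste(head(unknown, 5), collapse = ", ")))
  }
  annotations <- annotations[match(colnames(expression), annotations$cell_id), ]
  if (anyNA(annotations$subtype) || anyNA(annotations$celltype)) {
    abort("Every cell needs a subtype and a celltype label.")
  }

  map <- unique(annotations[, c("subtype", "celltype")])
  conflict <- unique(map$subtype[duplicated(map$subtype)])
  if (length(conflict) > 0) {
    abort(sprintf(
      "Sub-cell type(s) mapped to more than one cell type: %s.",
      paste(conflict, collapse = ", ")
    ))
  }
  celltype_of_subtype <- stats::setNames(as.character(map$celltype), map$subtype)
  subtype_of_cell <- stats::setNames(as.character(annotations$subtype), annotations$cell_id)

  structure(
    list(
      expression = expression,
      cell_ids = colnames(expression),
      subtype_of_cell = subtype_of_cell,
      celltype_of_subtype = celltype_of_subtype
    ),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf(
    "<sc_dataset> %d genes x %d cells; %d sub-cell types in %d cell types\n",
    nrow(x$expression), ncol(x$expression),
    length(x$celltype_of_subtype), length(unique(x$celltype_of_subtype))
  ))
  invisible(x)
}

# Coerce a wide gene-by-group tibble (gene column + numeric group columns)
# to a plain matrix with genes as row names.
group_matrix <- function(df) {
  df <- as.data.frame(df)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  m
}

as_group_tibble <- function(m) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  tibble::add_column(out, gene = rownames(m), .before = 1)
}

#' Mean expression per sub-cell type
#'
#' Averages each gene's expression over the cells of every sub-cell type:
#' the per-group mean \eqn{\sum_{i: l_i = c} r_{g,i} / N_c}, where
#' \eqn{r_{g,i}} is the expression of gene g in cell i and \eqn{N_c} the
#' number of cells annotated as sub-cell type c.
#'
#' @param dataset An [sc_dataset()].
#' @return A tibble with a `gene` column and one numeric column per
#'   sub-cell type, carrying attributes `n_cells` (cells per sub-cell type)
#'   and `celltype_of_subtype`.
#' @export
subtype_means <- function(dataset) {
  stopifnot(inherits(dataset, "sc_dataset"))
  f <- factor(dataset$subtype_of_cell, levels = unique(dataset$subtype_of_cell))
  n_cells <- table(f)
  if (any(n_cells == 0)) {
    abort(sprintf(
      "Sub-cell type(s) with zero cells: %s.",
      paste(names(n_cells)[n_cells == 0], collapse = ", ")
    ))
  }
  sums <- t(rowsum(t(dataset$expression), group = f))
  means <- sweep(sums, 2, as.numeric(n_cells), "/")
  out <- as_group_tibble(means)
  attr(out, "n_cells") <- stats::setNames(as.integer(n_cells), levels(f))
  attr(out, "celltype_of_subtype") <- dataset$celltype_of_subtype
  out
}

#' Drop genes with uniformly low expression
#'
#' A gene is retained only if its mean expression strictly exceeds
#' `threshold` in at least one sub-cell type. Because specificity is a
#' proportion and independent of a gene's overall expression level, a few
#' stray reads would otherwise make a barely-detected gene look like a
#' perfect cell-type marker.
#'
#' @param means Tibble from [subtype_means()].
#' @param threshold Expression-units cutoff; a gene whose maximum sub-cell
#'   type mean is `<= threshold` is dropped. Default 0.2.
#' @return Filtered tibble of the same shape; dropped symbols are recorded
#'   in the `dropped_genes` attribute.
#' @export
drop_low_expression_genes <- function(means, threshold = 0.2) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  m <- group_matrix(means)
  keep <- apply(m, 1, max) > threshold
  if (!any(keep)) {
    abort(sprintf("All genes fall at or below the expression threshold (%g); nothing left to analyse.", threshold))
  }
  out <- means[keep, , drop = FALSE]
  attr(out, "n_cells") <- attr(means, "n_cells")
  attr(out, "celltype_of_subtype") <- attr(means, "celltype_of_subtype")
  attr(out, "dropped_genes") <- means$gene[!keep]
  out
}

#' Sub-cell-type specificity matrix
#'
#' Converts per-sub-cell-type mean expression into specificity: the
#' fraction of a gene's summed mean expression attributable to each
#' sub-cell type,
#' \deqn{e_{g,c} = \frac{\bar r_{g,c}}{\sum_r \bar r_{g,r}}.}
#' Each gene's row sums to 1, so specificity is independent of the gene's
#' overall expression level. Apply [drop_low_expression_genes()] first;
#' the filter guarantees every retained gene has a positive denominator.
#'
#' @param means Tibble from [subtype_means()], already filtered.
#' @return A specificity tibble (`gene` column plus one column per
#'   sub-cell type, entries in \[0, 1\]) with attributes `level = "subtype"`,
#'   `celltype_of_subtype` and `dropped_genes`.
#' @export
specificity <- function(means) {
  m <- group_matrix(means)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(sprintf(
      "Gene(s) with all-zero means reached specificity computation (%s); run drop_low_expression_genes() first.",
      paste(head(rownames(m)[tot <= 0], 5), collapse = ", ")
    ))
  }
  out <- as_group_tibble(m / tot)
  attr(out, "level") <- "subtype"
  attr(out, "celltype_of_subtype") <- attr(means, "celltype_of_subtype")
  attr(out, "dropped_genes") <- attr(means, "dropped_genes") %||% character()
  class(out) <- c("ewce_specificity", class(out))
  out
}

#' Aggregate sub-cell-type specificity to cell types
#'
#' Sums sub-cell-type specificity columns within each cell type:
#' \eqn{p_{g,e} = \sum_{c: m_c = e} e_{g,c}}. Row sums are conserved, so the
#' cell-type matrix is again row-stochastic.
#'
#' @param spec Specificity tibble at `level = "subtype"`.
#' @param celltype_of_subtype Named character vector mapping each sub-cell
#'   type to its cell type; defaults to the mapping carried by `spec`.
#' @return Specificity tibble with `level = "celltype"`.
#' @export
aggregate_specificity <- function(spec, celltype_of_subtype = NULL) {
  if (!identical(attr(spec, "level"), "subtype")) {
    abort("`spec` must be a subtype-level specificity matrix.")
  }
  map <- celltype_of_subtype %||% attr(spec, "celltype_of_subtype")
  m <- group_matrix(spec)
  missing <- setdiff(colnames(m), names(map))
  if (length(missing) > 0) {
    abort(sprintf("Sub-cell type(s) missing from the cell-type map: %s.", paste(missing, collapse = ", ")))
  }
  f <- factor(map[colnames(m)], levels = unique(map[colnames(m)]))
  agg <- t(rowsum(t(m), group = f))
  out <- as_group_tibble(agg)
  attr(out, "level") <- "celltype"
  attr(out, "dropped_genes") <- attr(spec, "dropped_genes")
  class(out) <- c("ewce_specificity", class(out))
  out
}

#' One-step specificity construction
#'
#' Convenience wrapper chaining [subtype_means()],
#' [drop_low_expression_genes()] and [specificity()], optionally followed
#' by [aggregate_specificity()].
#'
#' @inheritParams subtype_means
#' @inheritParams drop_low_expression_genes
#' @param level `"subtype"` (default) or `"celltype"`.
#' @return A specificity tibble at the requested level.
#' @export
specificity_from_dataset <- function(dataset, threshold = 0.2, level = c("subtype", "celltype")) {
  level <- match.arg(level)
  spec <- specificity(drop_low_expression_genes(subtype_means(dataset), threshold))
  if (level == "celltype") spec <- aggregate_specificity(spec) else spec
}

#' @export
print.ewce_specificity <- function(x, ...) {
  cat(sprintf(
    "<specificity matrix> %d genes x %d groups (level: %s, %d genes dropped by expression filter)\n",
    nrow(x), ncol(x) - 1L, attr(x, "level") %||% "?",
    length(attr(x, "dropped_genes") %||% character())
  ))
  NextMethod()
}
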