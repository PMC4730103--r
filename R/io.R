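read_table_guess <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, comment = "#", trim_ws = TRUE,
                    show_col_types = FALSE, progress = FALSE)
}

#' Read a genes-by-cells expression matrix
#'
#' Reads either a delimited table (first column gene symbols, remaining
#' columns one per cell) or a MatrixMarket triplet (`format = "mtx"`, with
#' sidecar files listing gene symbols and cell ids, one per line).
#'
#' @param path Path to the TSV/CSV table or the `.mtx` file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_file,cells_file Required for `"mtx"`: row and column name
#'   files.
#' @return Numeric matrix with gene row names and cell column names.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file)) {
      abort("MatrixMarket input needs `genes_file` and `cells_file`.")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- normalize_symbols(readr::read_lines(genes_file))
    cells <- normalize_symbols(readr::read_lines(cells_file))
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort("Gene/cell id files do not match the MatrixMarket dimensions.")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- read_table_guess(path, delim = if (format == "csv") "," else "\t")
    genes <- normalize_symbols(df[[1]])
    vals <- df[, -1, drop = FALSE]
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric expression values in cell column(s): %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
  }
  assert_unique_symbols(rownames(m))
  assert_unique_symbols(colnames(m), "cell ids")
  storage.mode(m) <- "double"
  m
}

#' Read a cell annotation table
#'
#' @param path TSV with columns `cell_id`, `subtype`, `celltype`.
#' @return Tibble with those three character columns.
#' @export
read_annotations <- function(path) {
  df <- read_table_guess(path)
  need <- c("cell_id", "subtype", "celltype")
  if (!all(need %in% names(df))) {
    abort("Annotation table must have columns cell_id, subtype, celltype.")
  }
  dplyr::mutate(df[need], dplyr::across(dplyr::everything(), as.character))
}

#' Read an expression matrix and annotations into a dataset
#'
#' @param expression_path,annotation_path File paths.
#' @param ... Passed to [read_expression()].
#' @return An [sc_dataset()].
#' @export
read_sc_dataset <- function(expression_path, annotation_path, ...) {
  sc_dataset(read_expression(expression_path, ...), read_annotations(annotation_path))
}

#' Read a gene list
#'
#' Plain text, one symbol per line; `#` starts a comment; blank lines
#' ignored.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- sub("#.*$", "", x)
  x <- normalize_symbols(x)
  x[nzchar(x)]
}

#' Read an ortholog table
#'
#' @param path TSV whose first two columns are source-species and
#'   reference-species symbols (e.g. `human_symbol`, `mouse_symbol`).
#' @return Tibble of the two symbol columns (unfiltered; see
#'   [orthologs_one_to_one()]).
#' @export
read_ortholog_table <- function(path) {
  df <- read_table_guess(path)
  if (ncol(df) < 2) abort("Ortholog table needs at least two columns.")
  df[, 1:2]
}

#' Read a gene-property table
#'
#' Columns `gene`, `transcript_length_bp`, `gc_fraction`. GC given as a
#' percentage (values above 1) is auto-detected and rescaled to a
#' fraction, with a message.
#'
#' @param path File path.
#' @return Tibble of properties, GC as a fraction.
#' @export
read_gene_properties <- function(path) {
  df <- read_table_guess(path)
  need <- c("gene", "transcript_length_bp", "gc_fraction")
  if (!all(need %in% names(df))) {
    abort("Property table must have columns gene, transcript_length_bp, gc_fraction.")
  }
  gc <- df$gc_fraction
  if (any(gc > 1.5, na.rm = TRUE)) {
    inform("GC content looks like a percentage; rescaling to a fraction.")
    df$gc_fraction <- gc / 100
  }
  df[need]
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `probe`, `gene`, `t`.
#' @return Tibble of the three columns.
#' @export
read_de_table <- function(path) {
  df <- read_table_guess(path)
  need <- c("probe", "gene", "t")
  if (!all(need %in% names(df))) abort("DE table must have columns probe, gene, t.")
  df[need]
}

#' Write a specificity matrix
#'
#' Writes the gene-by-group table as TSV and, optionally, the
#' filter-dropped gene symbols as a sidecar text file.
#'
#' @param spec Specificity tibble.
#' @param path Output TSV path.
#' @param dropped_path Optional path for the dropped-gene sidecar.
#' @export
write_specificity <- function(spec, path, dropped_path = NULL) {
  readr::write_lines(sprintf("# specificity matrix; level: %s",
                             attr(spec, "level") %||% "unknown"), path)
  readr::write_tsv(tibble::as_tibble(as.data.frame(spec)), path, append = TRUE,
                   col_names = TRUE)
  if (!is.null(dropped_path)) {
    readr::write_lines(attr(spec, "dropped_genes") %||% character(), dropped_path)
  }
  invisible(path)
}

#' Read a specificity matrix written by [write_specificity()]
#'
#' @param path TSV path.
#' @param level Level flag to attach (`"subtype"` or `"celltype"`); read
#'   from the file header when present.
#' @return Specificity tibble.
#' @export
read_specificity <- function(path, level = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  if (is.null(level) && grepl("^# specificity matrix; level:", first)) {
    level <- trimws(sub("^# specificity matrix; level:", "", first))
  }
  df <- read_table_guess(path)
  names(df)[1] <- "gene"
  df$gene <- normalize_symbols(df$gene)
  assert_unique_symbols(df$gene)
  out <- tibble::as_tibble(df)
  attr(out, "level") <- level
  attr(out, "dropped_genes") <- character()
  class(out) <- c("ewce_specificity", class(out))
  out
}

#' Write an enrichment result table
#'
#' Deterministic output: fixed column order, rows sorted by (direction,
#' group), run metadata embedded as `#` header comments. Two runs with the
#' same seed produce byte-identical files.
#'
#' @param result An `ewce_result`.
#' @param path Output TSV path.
#' @export
write_results <- function(result, path) {
  df <- tidy(result)
  if (!"direction" %in% names(df)) df <- tibble::add_column(df, direction = "-", .before = 1)
  df <- dplyr::arrange(df, .data$direction, .data$group)
  cols <- c("direction", "group", "n_genes_used", "gamma", "p", "p_adj",
            "fold", "z", "n_reps", "seed", "mode")
  df <- df[intersect(cols, names(df))]
  header <- c(
    "# ewcer enrichment results",
    sprintf("# correction: %s", attr(result, "correction") %||% "none"),
    sprintf("# p_method: %s", attr(result, "p_method") %||% "plus_one")
  )
  readr::write_lines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an enrichment result table written by [write_results()]
#'
#' @param path TSV path.
#' @return Tibble of the result rows.
#' @export
read_results <- function(path) {
  read_table_guess(path)
}

#' Save a bootstrap null matrix
#'
#' TSV exchange format for [merge_bootstrap()]: metadata (replicates, list
#' length, mode, seed) as `#` header comments, then the replicate-by-group
#' gamma matrix.
#'
#' @param null A `bootstrap_null`.
#' @param path Output path.
#' @export
write_null <- function(null, path) {
  stopifnot(inherits(null, "bootstrap_null"))
  header <- c(
    "# ewcer bootstrap null matrix",
    sprintf("# n_replicates: %d", null$n_replicates),
    sprintf("# list_length: %d", null$list_length),
    sprintf("# mode: %s", null$mode),
    sprintf("# seed: %s", null$seed %||% "NA")
  )
  readr::write_lines(header, path)
  readr::write_tsv(tibble::as_tibble(as.data.frame(null$values)), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a bootstrap null matrix written by [write_null()]
#'
#' @param path File path.
#' @return A `bootstrap_null` object.
#' @export
read_null <- function(path) {
  meta <- readr::read_lines(path, n_max = 5)
  get_field <- function(key) {
    line <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(line) == 0) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", line[1]))
  }
  df <- read_table_guess(path)
  values <- as.matrix(df)
  seed <- get_field("seed")
  new_bootstrap_null(
    values,
    list_length = as.integer(get_field("list_length")),
    mode = get_field("mode"),
    seed = if (seed %in% c("NA", NA)) NULL else as.integer(seed)
  )
}

#' Validate a run configuration
#'
#' Reads a YAML or JSON configuration (or takes a named list) and fills in
#' the standard defaults: 100000 bootstrap replicates, expression filter
#' 0.2, 250 genes per transcriptome-mode direction, 10 bins per
#' decile-grid axis. Unknown keys are rejected.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return Named list of validated parameters.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    reps = 100000L,
    expression_threshold = 0.2,
    k = 250L,
    n_bins = 10L,
    correction = "bonferroni",
    level = "subtype",
    seed = NULL
  )
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config)
    } else {
      yaml::read_yaml(config)
    }
    config <- config %||% list()
  }
  if (!is.list(config)) abort("`config` must be a file path or a named list.")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.numeric(out$reps) || out$reps < 1) abort("`reps` must be a positive integer.")
  if (out$expression_threshold < 0) abort("`expression_threshold` must be >= 0.")
  if (!is.numeric(out$k) || out$k < 1) abort("`k` must be a positive integer.")
  if (!is.numeric(out$n_bins) || out$n_bins < 1) abort("`n_bins` must be a positive integer.")
  if (!out$correction %in% c("bonferroni", "BH", "none")) {
    abort("`correction` must be one of bonferroni, BH, none.")
  }
  if (!out$level %in% c("subtype", "celltype")) abort("`level` must be subtype or celltype.")
  out$reps <- as.integer(out$reps)
  out$k <- as.integer(out$k)
  out$n_bins <- as.integer(out$n_bins)
  out
}
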