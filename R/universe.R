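#' Filter an ortholog table to strict one-to-one pairs
#'
#' Cross-species symbol mapping must be unambiguous before specificity
#' values can be attached to mapped genes: a source symbol hitting two
#' reference symbols (or vice versa) would double-count expression. Every
#' pair involved in a many-to-many relation is removed and reported.
#'
#' @param table Data frame with two columns, source-species symbol then
#'   reference-species symbol (e.g. `human_symbol`, `mouse_symbol`).
#' @return A tibble with columns `source`, `reference` containing only 1:1
#'   pairs; dropped pairs are kept in the `dropped_pairs` attribute.
#' @export
orthologs_one_to_one <- function(table) {
  table <- as.data.frame(table)
  if (ncol(table) < 2) abort("Ortholog table needs two columns: source symbol, reference symbol.")
  tab <- tibble::tibble(
    source = normalize_symbols(table[[1]]),
    reference = normalize_symbols(table[[2]])
  )
  tab <- dplyr::distinct(tab)
  if (any(tab$source == "" | tab$reference == "")) abort("Ortholog table contains empty symbols.")
  multi_src <- unique(tab$source[duplicated(tab$source)])
  multi_ref <- unique(tab$reference[duplicated(tab$reference)])
  bad <- tab$source %in% multi_src | tab$reference %in% multi_ref
  out <- tab[!bad, , drop = FALSE]
  attr(out, "dropped_pairs") <- tab[bad, , drop = FALSE]
  if (any(bad)) {
    inform(sprintf("Dropped %d ortholog pair(s) involved in many-to-many relations.", sum(bad)))
  }
  out
}

#' Map gene symbols through an ortholog table
#'
#' Translates a gene list from the source species to the reference species
#' of the specificity matrix (by default, human disease lists onto a mouse
#' single-cell reference). The table is reduced to strict 1:1 pairs first;
#' symbols without a surviving pair are reported, never silently dropped.
#'
#' @param symbols Character vector of source-species symbols.
#' @param table Two-column ortholog table (see [orthologs_one_to_one()]).
#' @return A list with `mapped` (reference-species symbols, input order,
#'   duplicates removed after mapping) and `unmapped` (input symbols with
#'   no usable ortholog).
#' @export
map_orthologs <- function(symbols, table) {
  symbols <- normalize_symbols(symbols)
  tab <- if (identical(names(table), c("source", "reference"))) table else orthologs_one_to_one(table)
  idx <- match(symbols, tab$source)
  mapped <- tab$reference[idx[!is.na(idx)]]
  list(
    mapped = unique(mapped),
    unmapped = symbols[is.na(idx)]
  )
}

#' Build the background gene set for bootstrapping
#'
#' The background (gene universe) is the pool null lists are sampled from:
#' all genes retained in the specificity matrix, optionally intersected
#' with the genes detected in a disease transcriptome study (transcriptome
#' mode). Target genes absent from the specificity matrix cannot be tested
#' and are reported as excluded.
#'
#' @param spec Specificity tibble ([specificity()]).
#' @param target Character vector of (already ortholog-mapped) target
#'   genes.
#' @param detected_in_study Optional character vector restricting the
#'   universe to genes detected in the disease study.
#' @return Character vector of background genes with attribute
#'   `excluded_target` (target symbols not in the specificity matrix).
#' @export
build_background <- function(spec, target, detected_in_study = NULL) {
  genes <- spec$gene
  target <- normalize_symbols(target)
  excluded <- setdiff(target, genes)
  target_in <- intersect(target, genes)
  bg <- if (is.null(detected_in_study)) genes else intersect(genes, normalize_symbols(detected_in_study))
  bg <- union(bg, target_in)
  bg <- genes[genes %in% bg]   # keep specificity-matrix order
  if (length(bg) < length(target_in)) {
    abort("Background smaller than the target list; check the study restriction.")
  }
  if (length(excluded) > 0) {
    inform(sprintf(
      "%d target gene(s) absent from the specificity matrix were excluded: %s%s",
      length(excluded), paste(head(excluded, 5), collapse = ", "),
      if (length(excluded) > 5) ", ..." else ""
    ))
  }
  attr(bg, "excluded_target") <- excluded
  bg
}

# Decile index of x against interior boundaries, right-closed bins:
# values equal to a boundary fall in the lower bin.
decile_index <- function(x, boundaries) {
  findInterval(x, boundaries, left.open = TRUE) + 1L
}

#' Build the transcript-length x GC-content decile grid
#'
#' Gene lists from genetic studies are biased toward long, GC-atypical
#' genes, which inflates naive enrichment tests. The controlled bootstrap
#' removes this bias by sampling each null gene from the same
#' transcript-length decile and GC-content decile as the corresponding
#' target gene. This function computes the empirical decile boundaries over
#' the background set and assigns every background gene to a grid cell.
#'
#' @param background Character vector of background genes
#'   ([build_background()]).
#' @param properties Data frame with columns `gene`,
#'   `transcript_length_bp` (> 0; mean over a gene's transcripts) and
#'   `gc_fraction` (in \[0, 1\]).
#' @param n_bins Bins per axis (default 10, i.e. deciles).
#' @return A `decile_grid` object: assignment tibble (`gene`,
#'   `length_bin`, `gc_bin`, `cell`), per-cell membership list, axis
#'   boundaries, and the background genes lacking properties
#'   (`missing_properties`).
#' @export
build_decile_grid <- function(background, properties, n_bins = 10) {
  props <- as.data.frame(properties)
  need <- c("gene", "transcript_length_bp", "gc_fraction")
  if (!all(need %in% names(props))) {
    abort("`properties` must have columns gene, transcript_length_bp, gc_fraction.")
  }
  props$gene <- normalize_symbols(props$gene)
  assert_unique_symbols(props$gene, "genes in the property table")
  if (any(props$transcript_length_bp <= 0, na.rm = TRUE)) abort("Transcript lengths must be positive.")
  if (any(props$gc_fraction < 0 | props$gc_fraction > 1, na.rm = TRUE)) {
    abort("GC content must be a fraction in [0, 1].")
  }

  idx <- match(background, props$gene)
  missing <- background[is.na(idx) |
                          is.na(props$transcript_length_bp[idx]) |
                          is.na(props$gc_fraction[idx])]
  if (length(missing) > 0) {
    warn(sprintf(
      "%d background gene(s) lack length/GC properties and are excluded from controlled sampling.",
      length(missing)
    ))
  }
  usable <- setdiff(background, missing)
  if (length(usable) == 0) abort("No background gene has usable length/GC properties.")
  len <- props$transcript_length_bp[match(usable, props$gene)]
  gc <- props$gc_fraction[match(usable, props$gene)]

  probs <- seq_len(n_bins - 1) / n_bins
  len_b <- unique(quantile(len, probs, names = FALSE, type = 7))
  gc_b <- unique(quantile(gc, probs, names = FALSE, type = 7))
  len_b <- len_b[len_b < max(len)]
  gc_b <- gc_b[gc_b < max(gc)]
  if (length(len_b) < n_bins - 1 || length(gc_b) < n_bins - 1) {
    warn("Tied length/GC values collapsed some grid bins; using fewer bins on that axis.")
  }

  assignment <- tibble::tibble(
    gene = usable,
    length_bin = decile_index(len, len_b),
    gc_bin = decile_index(gc, gc_b)
  )
  assignment$cell <- paste(assignment$length_bin, assignment$gc_bin, sep = ":")
  members <- split(assignment$gene, assignment$cell)

  structure(
    list(
      assignment = assignment,
      members = members,
      length_boundaries = len_b,
      gc_boundaries = gc_b,
      n_bins = c(length = length(len_b) + 1L, gc = length(gc_b) + 1L),
      missing_properties = missing
    ),
    class = "decile_grid"
  )
}

#' @export
print.decile_grid <- function(x, ...) {
  cat(sprintf(
    "<decile grid> %d genes over %d x %d length/GC bins (%d occupied cells; %d genes without properties)\n",
    nrow(x$assignment), x$n_bins["length"], x$n_bins["gc"],
    length(x$members), length(x$missing_properties)
  ))
  invisible(x)
}

#' Look up a gene's grid cell
#'
#' @param grid A [build_decile_grid()] result.
#' @param gene Gene symbol(s).
#' @return Tibble with `gene`, `length_bin`, `gc_bin`, `cell`.
#' @export
grid_cell_of <- function(grid, gene) {
  stopifnot(inherits(grid, "decile_grid"))
  idx <- match(normalize_symbols(gene), grid$assignment$gene)
  if (anyNA(idx)) {
    abort(sprintf("Gene(s) not in the decile grid: %s.", paste(gene[is.na(idx)], collapse = ", ")))
  }
  grid$assignment[idx, , drop = FALSE]
}
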