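#' Simulate an annotated single-cell reference with planted markers
#'
#' Generates a genes-by-cells count matrix with known cell-type marker
#' structure: each sub-cell type owns a disjoint set of marker genes whose
#' mean expression is elevated `marker_effect`-fold in that sub-cell type
#' and baseline elsewhere. Counts are drawn per cell from a negative
#' binomial (default, mimicking UMI overdispersion) or Poisson noise
#' model. With `marker_effect = 1` all genes are exchangeable, giving a
#' fully null reference.
#'
#' @param n_genes Number of genes (symbols `G0001`, ...).
#' @param n_subtypes Number of sub-cell types (`subtype1`, ...).
#' @param cells_per_subtype Cells per sub-cell type (scalar or vector).
#' @param celltype_of_subtype Named character vector mapping sub-cell types
#'   to cell types; default: each sub-cell type is its own cell type.
#' @param marker_fraction Fraction of all genes planted as markers of each
#'   sub-cell type (disjoint sets; `n_subtypes * marker_fraction` must not
#'   exceed 1).
#' @param marker_effect Fold elevation of a marker's mean expression in
#'   its own sub-cell type (1 = no signal).
#' @param baseline_mean Baseline mean count per cell.
#' @param noise `"nb"` (negative binomial) or `"poisson"`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.5.
#' @param seed Integer seed.
#' @return A list: `dataset` (an [sc_dataset()]), `markers` (named list,
#'   sub-cell type -> planted marker symbols), `genes` (all symbols).
#' @export
simulate_sct <- function(n_genes = 1000, n_subtypes = 5, cells_per_subtype = 20,
                         celltype_of_subtype = NULL,
                         marker_fraction = 0.1, marker_effect = 1,
                         baseline_mean = 1, noise = c("nb", "poisson"),
                         dispersion = 0.5, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_genes >= 1, n_subtypes >= 1, all(cells_per_subtype >= 1),
            marker_fraction >= 0, marker_effect > 0, baseline_mean > 0,
            dispersion > 0)
  n_markers <- round(marker_fraction * n_genes)
  if (n_markers * n_subtypes > n_genes) {
    abort("Marker allocation infeasible: n_subtypes * marker_fraction exceeds 1.")
  }
  subtypes <- paste0("subtype", seq_len(n_subtypes))
  cells_per_subtype <- rep_len(cells_per_subtype, n_subtypes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  map <- celltype_of_subtype %||%
    stats::setNames(paste0("celltype", seq_len(n_subtypes)), subtypes)

  with_seed(seed, {
    marker_pool <- sample(genes, n_markers * n_subtypes)
    markers <- split(marker_pool, rep(subtypes, each = n_markers))[subtypes]
    if (n_markers == 0) markers <- stats::setNames(rep(list(character()), n_subtypes), subtypes)

    subtype_of_cell <- rep(subtypes, times = cells_per_subtype)
    n_cells <- length(subtype_of_cell)
    mu <- matrix(baseline_mean, nrow = n_genes, ncol = n_cells,
                 dimnames = list(genes, NULL))
    for (s in subtypes) {
      mu[markers[[s]], subtype_of_cell == s] <- baseline_mean * marker_effect
    }
    counts <- switch(noise,
      poisson = rpois(length(mu), mu),
      nb = rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    )
    counts <- matrix(as.double(counts), nrow = n_genes,
                     dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
    ann <- data.frame(
      cell_id = colnames(counts),
      subtype = subtype_of_cell,
      celltype = unname(map[subtype_of_cell])
    )
    list(dataset = sc_dataset(counts, ann), markers = markers, genes = genes)
  })
}

#' Simulate a target gene list with known marker content
#'
#' Draws `ceiling(purity * n)` genes from a sub-cell type's planted
#' markers and the remainder uniformly from genes that are markers of no
#' sub-cell type.
#'
#' @param truth A [simulate_sct()] result (or any list with `markers` and
#'   `genes`).
#' @param group Sub-cell type whose markers seed the list.
#' @param n List length.
#' @param purity Fraction of the list drawn from the group's markers
#'   (default 1).
#' @param seed Integer seed.
#' @return Character vector of `n` gene symbols.
#' @export
simulate_gene_list <- function(truth, group, n, purity = 1, seed = NULL) {
  stopifnot(purity >= 0, purity <= 1, n >= 1)
  markers <- truth$markers[[group]]
  if (is.null(markers)) abort(sprintf("No planted markers recorded for group '%s'.", group))
  nonmarkers <- setdiff(truth$genes, unlist(truth$markers))
  n_m <- ceiling(purity * n)
  if (n_m > length(markers)) abort("Not enough planted markers for the requested purity and length.")
  if (n - n_m > length(nonmarkers)) abort("Not enough non-marker genes for the requested list.")
  with_seed(seed, {
    c(sample(markers, n_m), sample(nonmarkers, n - n_m))
  })
}

#' Simulate a differential-expression table with a planted cell-type shift
#'
#' Per-probe t-statistics are standard normal, shifted by `effect` for the
#' planted markers of one sub-cell type. Multiple probes per gene (each
#' with its own noise draw) exercise the duplicate-probe collapsing of
#' [select_extreme_genes()].
#'
#' @inheritParams simulate_gene_list
#' @param effect Mean t-statistic shift for the group's markers (0 = fully
#'   null table).
#' @param n_probes_per_gene Probes per gene (default 1).
#' @param seed Integer seed.
#' @return Tibble with columns `probe`, `gene`, `t`.
#' @export
simulate_de_table <- function(truth, group, effect = 0, n_probes_per_gene = 1,
                              seed = NULL) {
  stopifnot(n_probes_per_gene >= 1)
  genes <- truth$genes
  markers <- truth$markers[[group]] %||% character()
  gene_col <- rep(genes, each = n_probes_per_gene)
  probe <- sprintf("%s_p%d", gene_col, rep(seq_len(n_probes_per_gene), length(genes)))
  shift <- ifelse(gene_col %in% markers, effect, 0)
  with_seed(seed, {
    tibble::tibble(probe = probe, gene = gene_col,
                   t = rnorm(length(probe)) + shift)
  })
}

#' Simulate transcript-length and GC-content gene properties
#'
#' Transcript lengths are log-normal (median ~2.5 kb) and GC content is
#' beta-distributed around 0.46, matching the broad shape of mammalian
#' annotation. With `correlation > 0`, the planted markers of a chosen
#' group are pushed toward the upper tail of the length distribution by
#' skewing their length percentile (`u^(1/(1 + 4 * correlation))`). This
#' creates the confound the controlled bootstrap exists to remove: gene
#' lists selected with a length bias then over-sample that group's markers.
#'
#' @param genes Character vector of gene symbols.
#' @param markers Symbols whose lengths are skewed upward (typically one
#'   group's planted markers).
#' @param correlation Strength of the marker-length association in
#'   \[0, 1\]; 0 = properties independent of marker status.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `transcript_length_bp`,
#'   `gc_fraction`.
#' @export
simulate_gene_properties <- function(genes, markers = character(),
                                     correlation = 0, seed = NULL) {
  stopifnot(correlation >= 0, correlation <= 1)
  with_seed(seed, {
    u <- runif(length(genes))
    skew <- genes %in% markers
    u[skew] <- u[skew]^(1 / (1 + 4 * correlation))
    tibble::tibble(
      gene = genes,
      transcript_length_bp = stats::qlnorm(u, meanlog = log(2500), sdlog = 0.9),
      gc_fraction = rbeta(length(genes), 20, 23)
    )
  })
}

#' Simulate a length-biased gene list
#'
#' Draws a gene list whose inclusion probability grows with the gene's
#' transcript-length decile (probability proportional to
#' `decile^strength`), emulating the length bias of gene discovery in
#' genetic studies. Because the bias operates on the decile index alone,
#' inclusion is uniform within each grid cell: the decile-grid controlled
#' bootstrap is exactly calibrated for such lists, while the uncontrolled
#' bootstrap is not whenever specificity co-varies with length.
#'
#' @param background Character vector of candidate genes.
#' @param grid [build_decile_grid()] over (at least) `background`.
#' @param n List length.
#' @param strength Exponent on the length-decile index (0 = unbiased).
#' @param seed Integer seed.
#' @return Character vector of `n` distinct gene symbols.
#' @export
simulate_biased_list <- function(background, grid, n, strength = 3, seed = NULL) {
  cells <- grid_cell_of(grid, background)
  w <- as.numeric(cells$length_bin)^strength
  with_seed(seed, sample(background, n, prob = w))
}
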