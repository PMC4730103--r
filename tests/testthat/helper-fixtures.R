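# Shared fixture builders. Everything is generated in code; no data files.

# Wrap a gene-by-group matrix (rows need not be normalized) as a specificity
# tibble of the kind specificity() returns.
make_spec <- function(m, level = "subtype", normalize = TRUE) {
  if (normalize) m <- m / rowSums(m)
  df <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  df <- tibble::add_column(df, gene = rownames(m), .before = 1)
  attr(df, "level") <- level
  attr(df, "dropped_genes") <- character()
  class(df) <- c("ewce_specificity", class(df))
  df
}

# Hand-built 6-gene, 3-group specificity matrix used by the enumeration
# oracle tests. Values chosen to give distinct pair sums.
tiny_spec <- function() {
  m <- matrix(
    c(0.70, 0.20, 0.10,
      0.10, 0.80, 0.10,
      0.05, 0.15, 0.80,
      0.40, 0.40, 0.20,
      0.25, 0.25, 0.50,
      0.33, 0.33, 0.34),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:6), c("A", "B", "C"))
  )
  make_spec(m, normalize = FALSE)
}

# Exhaustive enumeration oracle: exact p for every group when lists of size n
# are drawn uniformly without replacement from `background`. p is the
# probability that a random list's summed specificity >= the target's.
enumerate_exact_p <- function(spec, background, target) {
  m <- as.matrix(as.data.frame(spec)[, -1])
  rownames(m) <- spec$gene
  n <- length(target)
  combos <- utils::combn(background, n)
  gamma_t <- colSums(m[target, , drop = FALSE])
  hits <- integer(ncol(m))
  for (j in seq_len(ncol(combos))) {
    g <- colSums(m[combos[, j], , drop = FALSE])
    hits <- hits + as.integer(g >= gamma_t - 1e-12)
  }
  stats::setNames(hits / ncol(combos), colnames(m))
}

# Small annotated dataset with exact integer counts for hand-checked means.
toy_dataset <- function() {
  counts <- matrix(
    c(2, 4, 0, 1, 3, 5, 7, 0, 6, 1, 2, 9,
      0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
      1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Ga", "Gzero", "Gb"), paste0("c", 1:12))
  )
  ann <- data.frame(
    cell_id = paste0("c", 1:12),
    subtype = rep(c("s1", "s2", "s3"), each = 4),
    celltype = rep(c("T1", "T1", "T2"), each = 4)
  )
  list(counts = counts, ann = ann)
}
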