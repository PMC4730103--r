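test_that("subtype means equal a brute-force per-cell average", {
  toy <- toy_dataset()
  ds <- sc_dataset(toy$counts, toy$ann)
  means <- subtype_means(ds)
  m <- as.matrix(as.data.frame(means)[, -1])
  rownames(m) <- means$gene

  # independent oracle: explicit loop over cells
  for (g in rownames(toy$counts)) {
    for (s in unique(toy$ann$subtype)) {
      cells <- toy$ann$cell_id[toy$ann$subtype == s]
      expect_equal(m[g, s], mean(toy$counts[g, cells]))
    }
  }
  expect_equal(unname(m["Ga", "s1"]), mean(c(2, 4, 0, 1)))
  expect_true(all(m["Gzero", ] == 0))
  expect_equal(attr(means, "n_cells"), c(s1 = 4L, s2 = 4L, s3 = 4L))
})

test_that("a sub-cell type with zero cells is rejected by dataset validation", {
  toy <- toy_dataset()
  ann <- toy$ann
  ann$subtype[1] <- NA
  expect_error(sc_dataset(toy$counts, ann), "subtype")
})

test_that("low-expression filter keeps only genes strictly above the threshold", {
  m <- matrix(c(0.2, 0.1,    # max exactly 0.2 -> dropped
                0.21, 0.0,   # strictly above -> kept
                0.0, 0.0,    # all zero -> dropped
                5.0, 1.0),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  means <- tibble::add_column(tibble::as_tibble(as.data.frame(m)),
                              gene = rownames(m), .before = 1)
  out <- drop_low_expression_genes(means, threshold = 0.2)
  expect_setequal(out$gene, c("g2", "g4"))
  expect_setequal(attr(out, "dropped_genes"), c("g1", "g3"))
  expect_error(drop_low_expression_genes(means, threshold = 10), "threshold")
})

test_that("specificity rows are proportions of the summed subtype means", {
  m <- matrix(c(1, 0, 0, 0,    # exclusive marker
                2, 2, 2, 2,    # uniform
                1, 3, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gU", "gM"), paste0("s", 1:4)))
  means <- tibble::add_column(tibble::as_tibble(as.data.frame(m)),
                              gene = rownames(m), .before = 1)
  spec <- specificity(means)
  sm <- as.matrix(as.data.frame(spec)[, -1])
  expect_equal(unname(sm[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(sm[2, ]), rep(0.25, 4))
  expect_equal(unname(sm[3, 1:2]), c(0.25, 0.75))
  expect_equal(unname(rowSums(sm)), rep(1, 3), tolerance = 1e-12)
})

test_that("specificity errors on an all-zero gene instead of dividing by zero", {
  m <- matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  means <- tibble::add_column(tibble::as_tibble(as.data.frame(m)),
                              gene = rownames(m), .before = 1)
  expect_error(specificity(means), "drop_low_expression_genes")
})

test_that("cell-type aggregation sums subtype specificities within each parent", {
  m <- matrix(c(0.2, 0.3, 0.5,
                0.1, 0.1, 0.8), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  spec <- make_spec(m, normalize = FALSE)
  agg <- aggregate_specificity(spec, c(s1 = "T1", s2 = "T1", s3 = "T2"))
  am <- as.matrix(as.data.frame(agg)[, -1])
  expect_equal(unname(am[1, ]), c(0.5, 0.5))
  expect_equal(unname(am[2, ]), c(0.2, 0.8))

  # identity partition: output equals input
  id <- aggregate_specificity(spec, c(s1 = "s1", s2 = "s2", s3 = "s3"))
  expect_equal(as.data.frame(id), as.data.frame(spec), ignore_attr = TRUE)

  # missing subtype in the map is named in the error
  expect_error(aggregate_specificity(spec, c(s1 = "T1", s2 = "T1")), "s3")
})

test_that("random subtype-to-celltype partition matches a group-by oracle", {
  set.seed(42)
  m <- matrix(runif(10 * 6), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  spec <- make_spec(m)
  map <- setNames(sample(c("X", "Y", "Z"), 6, replace = TRUE), paste0("s", 1:6))
  agg <- aggregate_specificity(spec, map)
  am <- as.matrix(as.data.frame(agg)[, -1])
  sm <- as.matrix(as.data.frame(spec)[, -1])
  for (ct in unique(map)) {
    oracle <- rowSums(sm[, names(map)[map == ct], drop = FALSE])
    expect_equal(unname(am[, ct]), unname(oracle))
  }
  # aggregation conserves each gene's total
  expect_equal(rowSums(am), rowSums(sm))
})

test_that("specificity is invariant to per-gene scaling and cell order", {
  toy <- toy_dataset()
  counts <- toy$counts[c("Ga", "Gb"), ]
  ds <- sc_dataset(counts, toy$ann)
  spec1 <- specificity(subtype_means(ds))

  scaled <- counts
  scaled["Ga", ] <- scaled["Ga", ] * 7.3
  spec2 <- specificity(subtype_means(sc_dataset(scaled, toy$ann)))
  expect_equal(as.data.frame(spec1), as.data.frame(spec2), tolerance = 1e-12)

  perm <- sample(ncol(counts))
  spec3 <- specificity(subtype_means(
    sc_dataset(counts[, perm], toy$ann[perm, ])
  ))
  expect_equal(as.data.frame(spec1), as.data.frame(spec3))
})

test_that("dataset validation rejects malformed input", {
  toy <- toy_dataset()
  dup <- toy$counts
  rownames(dup) <- c("Ga", "Ga", "Gb")
  expect_error(sc_dataset(dup, toy$ann), "Duplicate")

  neg <- toy$counts
  neg[1, 1] <- -1
  expect_error(sc_dataset(neg, toy$ann), "negative")

  two_parents <- toy$ann
  two_parents$celltype[1] <- "T9"
  expect_error(sc_dataset(toy$counts, two_parents), "more than one cell type")

  expect_error(sc_dataset(toy$counts, toy$ann[-1, ]), "without annotation")
})

test_that("specificity_from_dataset chains the steps at both levels", {
  toy <- toy_dataset()
  ds <- sc_dataset(toy$counts, toy$ann)
  sub <- specificity_from_dataset(ds)
  ct <- specificity_from_dataset(ds, level = "celltype")
  expect_identical(attr(sub, "level"), "subtype")
  expect_identical(attr(ct, "level"), "celltype")
  expect_false("Gzero" %in% sub$gene)
  expect_equal(names(ct), c("gene", "T1", "T2"))
  expect_equal(unname(rowSums(as.matrix(as.data.frame(ct)[, -1]))),
               rep(1, nrow(ct)), tolerance = 1e-9)
})
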