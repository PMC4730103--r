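test_that("summed specificity accumulates rows exactly and audits unknowns", {
  spec <- tiny_spec()
  g <- summed_specificity(spec, "g1")
  expect_equal(unname(g), c(0.70, 0.20, 0.10))

  g <- summed_specificity(spec, c("g1", "g2"))
  expect_equal(unname(g), c(0.80, 1.00, 0.20))

  # independent accumulation oracle on a random selection
  sel <- c("g5", "g2", "g4", "g6", "g1")
  m <- as.matrix(as.data.frame(spec)[, -1]); rownames(m) <- spec$gene
  oracle <- c(0, 0, 0)
  for (gn in sel) oracle <- oracle + m[gn, ]
  expect_equal(summed_specificity(spec, sel), oracle)

  expect_error(summed_specificity(spec, c("g1", "gX")), "gX")
})

test_that("uncontrolled sampling is uniform, without replacement, and seeded", {
  spec <- tiny_spec()
  bg <- spec$gene

  # forced sample: n = |background| makes every replicate the whole background
  null <- sample_random_lists(spec, bg, n = 6, reps = 50, seed = 1)
  expect_true(all(apply(null$values, 2, function(x) all(x == x[1]))))
  expect_equal(unname(null$values[1, ]), unname(summed_specificity(spec, bg)))

  # n = 1 from a 2-gene background: each gene in about half the replicates
  null <- sample_random_lists(spec[1:2, ], c("g1", "g2"), n = 1, reps = 4000,
                              seed = 2, keep_lists = TRUE)
  frac_g1 <- mean(null$lists[, 1] == "g1")
  expect_gt(frac_g1, 0.5 - 3 * sqrt(0.25 / 4000))
  expect_lt(frac_g1, 0.5 + 3 * sqrt(0.25 / 4000))

  # replicates hold n distinct genes
  null <- sample_random_lists(spec, bg, n = 3, reps = 200, seed = 3, keep_lists = TRUE)
  expect_true(all(apply(null$lists, 1, function(x) length(unique(x)) == 3)))

  # deterministic given the seed; different seeds differ
  a <- sample_random_lists(spec, bg, n = 2, reps = 100, seed = 9)
  b <- sample_random_lists(spec, bg, n = 2, reps = 100, seed = 9)
  c <- sample_random_lists(spec, bg, n = 2, reps = 100, seed = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))

  expect_error(sample_random_lists(spec, bg, n = 7, reps = 10), "exceeds")
})

test_that("pair frequencies over C(6,2) are uniform at chi-square tolerance", {
  spec <- tiny_spec()
  null <- sample_random_lists(spec, spec$gene, n = 2, reps = 15000, seed = 4,
                              keep_lists = TRUE)
  pairs <- apply(null$lists, 1, function(x) paste(sort(x), collapse = "-"))
  counts <- table(pairs)
  expect_length(counts, 15)
  chisq <- sum((counts - 1000)^2 / 1000)
  expect_lt(chisq, qchisq(0.999, df = 14))
})

test_that("controlled sampling draws each position from the target gene's cell", {
  spec <- tiny_spec()
  genes <- spec$gene

  # every target gene alone in its cell: replicates are forced to the target
  props <- tibble::tibble(gene = genes,
                          transcript_length_bp = c(100, 200, 300, 400, 500, 600),
                          gc_fraction = seq(0.3, 0.55, by = 0.05))
  grid <- build_decile_grid(genes, props)
  expect_true(all(lengths(grid$members) == 1))
  null <- sample_controlled_lists(spec, c("g1", "g4"), grid, reps = 200, seed = 1)
  gam <- summed_specificity(spec, c("g1", "g4"))
  expect_true(all(abs(sweep(null$values, 2, gam)) < 1e-12))
  res <- bootstrap_test(gam, null)
  expect_equal(res$p, rep(1, 3))   # p = 1 by construction

  # degenerate grid (one cell): controlled == uncontrolled from that cell
  props1 <- tibble::tibble(gene = genes, transcript_length_bp = 500, gc_fraction = 0.5)
  grid1 <- suppressWarnings(build_decile_grid(genes, props1))
  null <- sample_controlled_lists(spec, c("g1", "g2"), grid1, reps = 300,
                                  seed = 5, keep_lists = TRUE)
  expect_true(all(null$lists %in% genes))
  expect_true(all(apply(null$lists, 1, function(x) length(unique(x)) == 2)))

  # two-cell grid, targets split 1/1: position i always from cell i
  props2 <- tibble::tibble(gene = genes,
                           transcript_length_bp = c(100, 100, 100, 900, 900, 900),
                           gc_fraction = 0.5)
  grid2 <- suppressWarnings(build_decile_grid(genes, props2))
  null <- sample_controlled_lists(spec, c("g2", "g5"), grid2, reps = 400,
                                  seed = 6, keep_lists = TRUE)
  expect_true(all(null$lists[, 1] %in% c("g1", "g2", "g3")))
  expect_true(all(null$lists[, 2] %in% c("g4", "g5", "g6")))

  # cell smaller than the positions assigned to it: duplicates allowed, noted
  expect_warning(
    null <- sample_controlled_lists(spec, c("g1", "g2", "g3", "g1"), grid2,
                                    reps = 50, seed = 7, keep_lists = TRUE),
    "fewer genes"
  )
})

test_that("bootstrap test computes p, fold and z from the null matrix", {
  spec <- tiny_spec()
  gam <- summed_specificity(spec, c("g1", "g2"))

  # hand-made null with known moments
  values <- matrix(c(0.1, 0.2, 0.3, 0.4,
                     1.0, 1.0, 1.0, 1.0,
                     0.5, 0.7, 0.9, 1.1),
                   nrow = 4, dimnames = list(NULL, c("A", "B", "C")))
  null <- ewcer:::new_bootstrap_null(values, list_length = 2,
                                     mode = "uncontrolled", seed = 1)
  res <- bootstrap_test(gam, null, correction = "none")
  # A: gamma 0.8, all four replicates below -> p = (0+1)/5
  expect_equal(res$p[res$group == "A"], 1 / 5)
  # B: gamma 1.0 ties all four replicates -> ties count against the target
  expect_equal(res$p[res$group == "B"], (4 + 1) / 5)
  # zero-spread null: z undefined, p and fold still valid
  expect_true(is.na(res$z[res$group == "B"]))
  expect_equal(res$fold[res$group == "B"], 1.0)
  # C: gamma 0.2; mean 0.8, sd = sd(c(.5,.7,.9,1.1))
  expect_equal(res$fold[res$group == "C"], 0.2 / 0.8)
  expect_equal(res$z[res$group == "C"], (0.2 - 0.8) / sd(c(0.5, 0.7, 0.9, 1.1)))

  # raw p-values can be zero; plus-one p-values cannot
  gam_hi <- c(A = 2, B = 2, C = 2)
  expect_equal(bootstrap_test(gam_hi, null, p_method = "raw")$p, rep(0, 3))
  expect_equal(bootstrap_test(gam_hi, null)$p, rep(1 / 5, 3))

  # target centered on the null mean: fold 1, z 0
  gam_mid <- c(A = 0.25, B = 1, C = 0.8)
  res <- bootstrap_test(gam_mid, null)
  expect_equal(res$fold[res$group == "A"], 1)
  expect_equal(res$z[res$group == "A"], 0)

  expect_error(bootstrap_test(c(X = 1), null), "identical")
})

test_that("multiple-testing corrections match hand computations", {
  expect_equal(correct_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(correct_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(correct_pvalues(0.3, "BH"), 0.3)
  # BH step-up by hand: (0.01,0.02,0.03,0.04)*4/(1..4), cumulative min from top
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(correct_pvalues(numeric(0), "BH"), numeric(0))
  expect_error(correct_pvalues(c(0.5, 0), "BH"), "p-values")
})

test_that("bootstrap p agrees with the exhaustive enumeration oracle", {
  spec <- tiny_spec()
  bg <- spec$gene
  target <- c("g1", "g3")
  exact <- enumerate_exact_p(spec, bg, target)

  reps <- 20000
  null <- sample_random_lists(spec, bg, n = 2, reps = reps, seed = 11)
  boot <- bootstrap_test(summed_specificity(spec, target), null,
                         correction = "none", p_method = "raw")
  for (grp in names(exact)) {
    se <- sqrt(exact[grp] * (1 - exact[grp]) / reps)
    expect_lt(abs(boot$p[boot$group == grp] - exact[grp]), 3 * se + 1e-9)
  }
})

test_that("the full background as target has fold about 1 in every group", {
  set.seed(2)
  m <- matrix(runif(80 * 4), nrow = 80,
              dimnames = list(sprintf("g%02d", 1:80), paste0("s", 1:4)))
  spec <- make_spec(m)
  null <- sample_random_lists(spec, spec$gene, n = 30, reps = 4000, seed = 12)
  gam <- summed_specificity(spec, sample(spec$gene, 30))
  # null mean scales as n/N times the column totals of the matrix
  expected <- colSums(as.matrix(as.data.frame(spec)[, -1])) * 30 / 80
  expect_equal(unname(colMeans(null$values)), unname(expected), tolerance = 0.05)
})

test_that("ewce_test filters the target, reports exclusions, and is reproducible", {
  spec <- tiny_spec()
  expect_message(
    res <- ewce_test(spec, c("g1", "g3", "NOT_THERE"), reps = 500, seed = 1),
    "excluded"
  )
  expect_equal(attr(res, "genes_used"), c("g1", "g3"))
  expect_equal(attr(res, "genes_excluded"), "NOT_THERE")
  expect_equal(unique(res$n_genes_used), 2L)

  res2 <- suppressMessages(ewce_test(spec, c("g1", "g3", "NOT_THERE"),
                                     reps = 500, seed = 1))
  expect_equal(tidy(res), tidy(res2))

  expect_error(suppressMessages(ewce_test(spec, "NOPE", reps = 10)), "No target gene")

  gl <- glance(res)
  expect_equal(gl$n_tests, 3L)
  expect_s3_class(autoplot(res), "ggplot")
})
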