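test_that("pseudo-expression is additive and monotone", {
  X <- rbind(a = c(0, 1, 3), b = c(2, 0, 1), c = c(5, 5, 5))
  ps_a <- pseudo_expression(X, "a")
  expect_equal(unname(ps_a), log1p(c(0, 1, 3)))
  expect_equal(pseudo_expression(X, c("a", "b")),
               pseudo_expression(X, "a") + pseudo_expression(X, "b"))
  expect_true(all(pseudo_expression(2 * X, c("a", "b"))[c(1, 2, 3)] >=
                    pseudo_expression(X, c("a", "b"))[c(1, 2, 3)]))
  expect_error(pseudo_expression(X, character(0)),
               class = "spectralsvg_input_error")
  expect_error(pseudo_expression(X, "zz"), class = "spectralsvg_input_error")
})

test_that("pseudo-expression does not double-log already-logged matrices", {
  rc <- raw_counts(matrix(c(4, 0, 9, 1), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   cbind(c(0, 1), c(0, 0)))
  expr <- normalize_counts(rc, scale = 1, log_transform = TRUE)
  ps <- pseudo_expression(expr, c("a", "b"))
  expect_equal(unname(ps), unname(colSums(expr$values)))
})

test_that("assign_spots does 1-D 2-means with deterministic seeds", {
  v <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 10, s5 = 10)
  expect_setequal(assign_spots(v), c("s4", "s5"))
  expect_equal(assign_spots(c(a = 0, b = 1)), "b")
  # affine invariance
  set.seed(15)
  w <- c(rnorm(20), rnorm(10, 8)); names(w) <- paste0("s", 1:30)
  expect_setequal(assign_spots(w), assign_spots(3 * w + 7))
  expect_error(assign_spots(c(a = 1, b = 1)),
               class = "spectralsvg_input_error")
})

test_that("overlap objective matches hand computation", {
  expect_equal(overlap_objective(list(c("a", "b"), c("c", "d"))), 0)
  expect_equal(overlap_objective(list(letters[1:7], letters[3:9])), 5)
  three <- list(c("a", "b", "x1", "x2"), c("a", "b", "y1", "y2"),
                c("a", "b", "z1", "z2"))
  expect_equal(overlap_objective(three), 2)
  expect_error(overlap_objective(list(letters)),
               class = "spectralsvg_input_error")
})

test_that("overlap objective is permutation invariant", {
  sets <- list(letters[1:5], letters[4:8], letters[7:12])
  expect_equal(overlap_objective(sets), overlap_objective(rev(sets)))
})

test_that("duplicate coefficient rows always co-cluster", {
  set.seed(16)
  fc <- matrix(rnorm(8 * 10), 8, 10)
  fc[5, ] <- fc[1, ]
  rownames(fc) <- paste0("g", 1:8)
  lab <- cluster_svgs(fc, resolution = 1, seed = 2)
  expect_equal(lab[["g1"]], lab[["g5"]])
  expect_identical(lab, cluster_svgs(fc, resolution = 1, seed = 2))
})

test_that("two planted FTU families cluster apart and their spot sets are recovered", {
  ds <- make_ftu_benchmark(seed = 5)
  expr <- normalize_counts(filter_genes(ds$raw))
  basis <- suppressWarnings(
    eigendecompose(laplacian(build_knn_graph(expr$coords))))
  fam <- ds$truth$gene[ds$truth$is_svg]
  fc_low <- low_frequency_fcs(expr, basis, genes = fam)

  lab <- cluster_svgs(fc_low, resolution = 1, seed = 1)
  expect_equal(max(lab), 2)
  fam_of <- sub("_g.*", "", names(lab))
  expect_equal(length(unique(paste(lab, fam_of))), 2)

  ftu <- optimize_resolution(fc_low, expr, seed = 1)
  expect_equal(length(ftu$spot_sets), 2)
  expect_equal(ftu$overlap, 0)
  best <- vapply(ftu$spot_sets, function(s)
    max(jaccard_sets(s, ds$truth_ftu$left),
        jaccard_sets(s, ds$truth_ftu$right)), numeric(1))
  expect_true(all(best >= 0.9))
  # gene clusters form a partition
  expect_setequal(names(ftu$gene_clusters), fam)
})

test_that("optimize_resolution handles degenerate grids", {
  set.seed(17)
  fc <- rbind(matrix(rnorm(10 * 6), 10, 6), matrix(rnorm(10 * 6, 5), 10, 6))
  rownames(fc) <- paste0("g", 1:20)
  X <- matrix(rpois(20 * 30, 4), 20, 30,
              dimnames = list(rownames(fc), paste0("s", 1:30)))
  one <- optimize_resolution(fc, X, res_grid = 1, seed = 3)
  expect_equal(one$resolution, 1)
  dup <- optimize_resolution(fc, X, res_grid = c(1, 1), seed = 3)
  expect_identical(dup$spot_sets, one$spot_sets)
  expect_error(optimize_resolution(fc, X, res_grid = numeric(0)),
               class = "spectralsvg_input_error")
})

test_that("ftu tables are written with the full spot universe", {
  ds <- make_ftu_benchmark(genes_per_family = 5, n_null = 60,
                           coords = make_grid(8, 8), seed = 2)
  expr <- normalize_counts(filter_genes(ds$raw))
  basis <- suppressWarnings(
    eigendecompose(laplacian(build_knn_graph(expr$coords))))
  fc_low <- low_frequency_fcs(expr, basis,
                              genes = ds$truth$gene[ds$truth$is_svg])
  ftu <- optimize_resolution(fc_low, expr, res_grid = c(0.5, 1), seed = 1)
  dir <- withr::local_tempdir()
  write_ftu_tables(ftu, dir, spot_ids = expr$spot_ids)
  memb <- read.delim(file.path(dir, "ftu_membership.tsv"))
  expect_equal(nrow(memb), length(expr$spot_ids))
  expect_true(all(unlist(memb[, -1]) %in% 0:1))
  gc <- read.delim(file.path(dir, "gene_clusters.tsv"))
  expect_setequal(gc$gene, names(ftu$gene_clusters))
})
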