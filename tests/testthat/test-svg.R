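test_that("normalized_fcs takes magnitudes and sums to one", {
  expect_equal(normalized_fcs(c(0, 2, -2)), c(0, 0.5, 0.5))
  expect_equal(normalized_fcs(c(0, 0, 7)), c(0, 0, 1))
  set.seed(4)
  expect_equal(sum(normalized_fcs(rnorm(40))), 1)
  expect_error(normalized_fcs(rep(0, 5)), class = "spectralsvg_input_error")
})

test_that("gftscore weights modes by exp(-lambda) and is scale invariant", {
  b <- path_basis(3)
  f2 <- b$modes[, 2]
  f3 <- b$modes[, 3]
  expect_equal(gftscore(b$eigenvalues, gft(b, f2)), exp(-1), tolerance = 1e-10)
  expect_equal(gftscore(b$eigenvalues, gft(b, f3)), exp(-3), tolerance = 1e-10)
  expect_gt(gftscore(b$eigenvalues, gft(b, f2)),
            gftscore(b$eigenvalues, gft(b, f3)))
  set.seed(5)
  f <- rnorm(3)
  expect_equal(gftscore(b$eigenvalues, gft(b, 5 * f)),
               gftscore(b$eigenvalues, gft(b, f)), tolerance = 1e-12)
})

test_that("gftscore is monotone across one-hot spectra", {
  lambda <- c(0, 0.5, 1.2, 2.5, 4)
  onehot <- function(k) {
    fc <- c(1, rep(0, 4)); fc[k] <- 1; fc
  }
  scores <- vapply(2:5, function(k) gftscore(lambda, onehot(k)), numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("score_cutoff places the knee at the score cliff", {
  scores <- c(10, 9.5, 9, 1.1, 1.0, 0.9, 0.85, 0.8)
  cut <- score_cutoff(scores, sensitivity = 1)
  expect_gte(cut, 1.1)
  expect_lte(cut, 9)
  expect_equal(sum(scores > cut), 3)
  expect_warning(fb <- score_cutoff(rep(2, 10)), "falls back")
  expect_equal(unname(fb), 2)
})

test_that("score_cutoff is stable to adding genes below the knee", {
  scores <- c(50, 45, 40, 2, 1.8, 1.5, 1.2, 1.1)
  cut1 <- score_cutoff(scores, sensitivity = 1)
  cut2 <- score_cutoff(c(scores, runif(20, 0.1, 1)), sensitivity = 1)
  expect_equal(sum(scores > cut1), sum(scores > cut2))
})

test_that("band_test reproduces exact enumeration on small bands", {
  # low = {5,6,7}, high = {1,2,3}: most extreme of C(6,3) = 20 arrangements
  fcs <- c(0, 5, 6, 7, 99, 1, 2, 3)
  expect_equal(band_test(fcs, 3, 3), 0.05)
  # mirror: the one-sided test must be near 1
  fcs_m <- c(0, 1, 2, 3, 99, 5, 6, 7)
  expect_gte(band_test(fcs_m, 3, 3), 0.95)

  # enumeration oracle for random magnitudes, band sizes up to 6 + 6
  enum_p <- function(low, high) {
    pool <- c(low, high)
    n1 <- length(low)
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(length(pool), n1)
    us <- apply(combos, 2, function(idx) {
      sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
    })
    mean(us >= u_obs)
  }
  set.seed(21)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    low <- abs(rnorm(n1)); high <- abs(rnorm(n2))
    fcs <- c(0, low, 99, 99, high)   # filler between the bands
    expect_equal(band_test(fcs, n1, n2), enum_p(low, high),
                 tolerance = 1e-12)
  }
})

test_that("band_test rejects overlapping bands", {
  expect_error(band_test(rnorm(10), 6, 5), class = "spectralsvg_input_error")
})

test_that("band_test null p-values are close to uniform at working band sizes", {
  set.seed(31)
  b <- grid_basis(12)   # bands 12/12 -> smoothed exact path
  X <- matrix(rnorm(2000 * 144), 2000, 144)
  fc <- X %*% b$modes
  p <- apply(fc, 1, band_test, n_low = b$n_low, n_high = b$n_high)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(p) - 0.5), 0.02)
})

test_that("fdr_adjust matches hand-computed Benjamini-Hochberg", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "spectralsvg_input_error")
})

test_that("identify_svgs separates planted patterns from noise genes", {
  set.seed(2)
  coords <- make_grid(14, 14)
  b <- grid_basis(14)
  n <- nrow(coords)
  X <- matrix(rnorm(120 * n), 120, n)
  for (i in 1:20) {
    X[i, ] <- X[i, ] + pattern_surface(coords, "hotspot", list(
      center = c(runif(1, 1, 14), runif(1, 1, 14)),
      radius = runif(1, 2, 4), baseline = 0, amplitude = 4
    ))
  }
  rownames(X) <- c(paste0("p", 1:20), paste0("n", 1:100))
  res <- identify_svgs(X, b)
  tbl <- tidy(res)
  expect_s3_class(tbl, "tbl_df")
  expect_setequal(tbl$rank, 1:120)
  # score curve ranks the planted genes first
  expect_gte(mean(tbl$gftscore[1:20] > tbl$cutoff_score[1]), 0.8)
  # every call satisfies the conjunction rule
  called <- tbl$is_svg
  expect_true(all(tbl$gftscore[called] > tbl$cutoff_score[called]))
  expect_true(all(tbl$qvalue[called] < 0.05))
  # determinism
  res2 <- identify_svgs(X, b)
  expect_identical(tidy(res2), tbl)
})

test_that("identify_svgs stays near the nominal rate on pure noise", {
  b <- grid_basis(10)
  frac <- vapply(1:5, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(150 * 100), 150, 100)
    rownames(X) <- paste0("g", seq_len(150))
    mean(tidy(identify_svgs(X, b))$is_svg)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("spot permutation destroys a planted gene's score advantage", {
  coords <- make_grid(20, 20)
  b <- grid_basis(20)
  surf <- pattern_surface(coords, "hotspot",
                          list(radius = 3, baseline = 1, amplitude = 8))
  wins <- vapply(1:20, function(s) {
    set.seed(400 + s)
    f <- log1p(rpois(length(surf), surf))
    s1 <- gftscore(b$eigenvalues, gft(b, f))
    s2 <- gftscore(b$eigenvalues, gft(b, sample(f)))
    s1 > s2
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("zero-variance genes get score 0 and p 1", {
  b <- grid_basis(7)
  X <- rbind(matrix(rnorm(5 * 49), 5), rep(3, 49))
  rownames(X) <- paste0("g", 1:6)
  tbl <- tidy(suppressWarnings(identify_svgs(X, b)))
  expect_equal(tbl$gftscore[6], 0)
  expect_equal(tbl$pvalue[6], 1)
  expect_false(tbl$is_svg[6])
})

test_that("svg table round-trips through its TSV writer", {
  b <- grid_basis(7)
  set.seed(8)
  X <- matrix(rnorm(10 * 49), 10, 49)
  rownames(X) <- paste0("g", 1:10)
  res <- identify_svgs(X, b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_svg_table(res, path)
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$gene, tidy(res)$gene)
  expect_equal(back$gftscore, tidy(res)$gftscore, tolerance = 1e-6)
  hdr <- readLines(path, n = 6)
  expect_true(any(grepl("^# alpha=", hdr)))
})
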