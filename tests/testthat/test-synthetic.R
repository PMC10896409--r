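test_that("make_grid produces a unit lattice with optional bounded jitter", {
  g <- make_grid(10, 10)
  expect_equal(nrow(g), 100)
  expect_equal(min(dist(g)), 1)
  gj <- make_grid(5, 5, jitter = 0.1, seed = 1)
  expect_true(max(abs(gj - make_grid(5, 5))) <= 0.1)
  expect_identical(gj, make_grid(5, 5, jitter = 0.1, seed = 1))
  expect_error(make_grid(1, 5), class = "spectralsvg_input_error")
})

test_that("pattern surfaces have the advertised shapes", {
  coords <- make_grid(9, 9)
  expect_equal(pattern_surface(coords, "null", list(baseline = 2)),
               rep(2, 81))
  hs <- pattern_surface(coords, "hotspot",
                        list(center = c(5, 5), radius = 2, baseline = 0.5,
                             amplitude = 4))
  expect_equal(which.max(hs), which(coords[, 1] == 5 & coords[, 2] == 5))
  expect_equal(max(hs), 4.5)

  # axis-aligned hard stripe elevates exactly the in-band spots
  st <- pattern_surface(coords, "stripe",
                        list(axis = 1, center = 3, width = 2, baseline = 1,
                             amplitude = 5))
  expect_equal(sum(st > 1), sum(abs(coords[, 1] - 3) <= 1))
  expect_setequal(unique(st), c(1, 6))

  dc <- pattern_surface(coords, "disc",
                        list(center = c(5, 5), radius = 2, baseline = 1,
                             amplitude = 3))
  expect_setequal(unique(dc), c(1, 4))
  gr <- pattern_surface(coords, "gradient",
                        list(direction = c(1, 0), baseline = 1, amplitude = 2))
  expect_equal(range(gr), c(1, 3))
  expect_error(pattern_surface(coords, "swirl"),
               class = "spectralsvg_input_error")
})

test_that("count simulation honours its moments", {
  coords <- make_grid(4, 4)
  zeros <- simulate_counts(matrix(0, 2, 16), coords = coords, seed = 1)
  expect_true(all(zeros$values == 0))

  mu <- matrix(5, 1, 10000)
  colnames(mu) <- paste0("s", 1:10000)
  big <- make_grid(100, 100); rownames(big) <- colnames(mu)
  pois <- simulate_counts(mu, model = "poisson", coords = big, seed = 2)
  expect_lt(abs(mean(pois$values) - 5), 3 * sqrt(5 / 10000))

  nb <- simulate_counts(mu, model = "nb", dispersion = 2, coords = big,
                        seed = 3)
  expect_gt(var(as.numeric(nb$values)), mean(nb$values))
  expect_error(simulate_counts(mu, model = "nb", dispersion = 0,
                               coords = big),
               class = "spectralsvg_input_error")
})

test_that("depth factors scale expected counts", {
  mu <- matrix(10, 1, 2000, dimnames = list("g", paste0("s", 1:2000)))
  coords <- make_grid(40, 50); rownames(coords) <- colnames(mu)
  d <- rep(c(0.5, 2), 1000)
  rc <- simulate_counts(mu, depth = d, coords = coords, seed = 4)
  expect_lt(abs(mean(rc$values[1, d == 0.5]) - 5), 0.5)
  expect_lt(abs(mean(rc$values[1, d == 2]) - 20), 1)
})

test_that("benchmark assembly records truth and is seed deterministic", {
  ds <- make_benchmark(n_svg = 5, n_null = 15, coords = make_grid(6, 6),
                       seed = 7)
  expect_equal(nrow(ds$raw$values), 20)
  expect_equal(sum(ds$truth$is_svg), 5)
  expect_true(all(ds$truth$kind[!ds$truth$is_svg] == "null"))
  ds2 <- make_benchmark(n_svg = 5, n_null = 15, coords = make_grid(6, 6),
                        seed = 7)
  expect_identical(ds$raw$values, ds2$raw$values)
  expect_identical(ds$truth, ds2$truth)

  none <- make_benchmark(n_svg = 0, n_null = 10, coords = make_grid(6, 6),
                         seed = 1)
  expect_false(any(none$truth$is_svg))
  expect_error(make_benchmark(n_svg = 0, n_null = 0),
               class = "spectralsvg_input_error")
})

test_that("ftu benchmark plants two disjoint truth regions", {
  ds <- make_ftu_benchmark(genes_per_family = 4, n_null = 30,
                           coords = make_grid(10, 10), seed = 2)
  expect_length(intersect(ds$truth_ftu$left, ds$truth_ftu$right), 0)
  expect_gt(length(ds$truth_ftu$left), 0)
  expect_equal(sum(ds$truth$is_svg), 8)
  ds2 <- make_ftu_benchmark(genes_per_family = 4, n_null = 30,
                            coords = make_grid(10, 10), seed = 2)
  expect_identical(ds$raw$values, ds2$raw$values)
})

test_that("benchmark files round-trip through the writers", {
  ds <- make_benchmark(n_svg = 3, n_null = 9, coords = make_grid(5, 5),
                       seed = 3)
  dir <- withr::local_tempdir()
  write_benchmark(ds, dir)
  back <- load_expression(file.path(dir, "counts.tsv"),
                          file.path(dir, "coords.tsv"))
  expect_equal(back$values, ds$raw$values)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(sum(truth$is_svg), 3)
})
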