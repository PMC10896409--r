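#' Regular spot lattice with optional jitter
#'
#' Visium-like rectangular grid of `nx * ny` spots at integer positions,
#' optionally perturbed by seeded uniform jitter.
#'
#' @param nx,ny Grid dimensions (both >= 2).
#' @param jitter Half-width of uniform positional noise (default 0).
#' @param seed Optional integer seed for the jitter.
#' @return Spot-by-2 coordinate matrix with row names `s1..s(nx*ny)`.
#' @export
make_grid <- function(nx, ny, jitter = 0, seed = NULL) {
  if (nx < 2 || ny < 2) stop_input("grid must be at least 2 x 2")
  coords <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    coords <- coords + matrix(runif(length(coords), -jitter, jitter),
                              ncol = 2)
  }
  rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  storage.mode(coords) <- "double"
  coords
}

#' Smooth spatial mean surface of a given archetype
#'
#' The pattern archetypes seen in real tissue: a radial `hotspot`
#' (Gaussian bump), a `stripe` (band of elevated expression), a `gradient`
#' (affine ramp), or a spatially flat `null`.
#'
#' @param coords Spot-by-2 coordinate matrix.
#' @param kind `"hotspot"`, `"disc"`, `"stripe"`, `"gradient"`, or
#'   `"null"`. `disc` is a sharp-edged hotspot (amplitude inside the radius,
#'   baseline outside), useful when the expressing region itself is the
#'   ground truth.
#' @param params Named list. hotspot/disc: `center` (length 2), `radius`,
#'   `amplitude`, `baseline`; stripe: `axis` (1 or 2), `center`, `width`,
#'   `amplitude`, `baseline`, optional `profile = "smooth"` for graded band
#'   edges; gradient: `direction` (length 2), `amplitude`, `baseline`;
#'   null: `baseline`.
#' @return Non-negative per-spot mean vector.
#' @export
pattern_surface <- function(coords, kind, params = list()) {
  p <- params
  baseline <- p$baseline %||% 0.5
  amplitude <- p$amplitude %||% (5 * baseline)
  switch(
    kind,
    hotspot = {
      ctr <- p$center %||% colMeans(coords)
      r <- p$radius %||% (diff(range(coords[, 1])) / 5)
      d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
      baseline + amplitude * exp(-d2 / (2 * r^2))
    },
    disc = {
      ctr <- p$center %||% colMeans(coords)
      r <- p$radius %||% (diff(range(coords[, 1])) / 5)
      d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
      baseline + amplitude * (d2 <= r^2)
    },
    stripe = {
      axis <- p$axis %||% 1
      ctr <- p$center %||% mean(range(coords[, axis]))
      w <- p$width %||% (diff(range(coords[, axis])) / 4)
      if (identical(p$profile, "smooth")) {
        # graded band edges, as real expression domains fade out
        baseline + amplitude * exp(-((coords[, axis] - ctr) / (w / 2))^2)
      } else {
        inside <- abs(coords[, axis] - ctr) <= w / 2
        baseline + amplitude * inside
      }
    },
    gradient = {
      dir <- p$direction %||% c(1, 0)
      t <- drop(coords %*% dir)
      t <- (t - min(t)) / (max(t) - min(t))
      baseline + amplitude * t
    },
    null = rep(baseline, nrow(coords)),
    stop_input(sprintf("unknown pattern kind: %s", kind))
  )
}

#' Draw counts from Poisson or negative binomial noise around mean surfaces
#'
#' Counts are drawn independently with expectation
#' `depth_s * mean_{g,s}`; the negative binomial uses
#' `variance = mu + mu^2 / dispersion`.
#'
#' @param means Gene-by-spot non-negative mean matrix.
#' @param model `"poisson"` or `"nb"`.
#' @param dispersion NB size parameter (> 0; ignored for Poisson).
#' @param depth Per-spot positive scale factors (default all 1),
#'   emulating library-size variation.
#' @param coords Spot coordinates carried into the result.
#' @param seed Optional integer seed.
#' @return A `raw_counts` object.
#' @export
simulate_counts <- function(means, model = c("poisson", "nb"),
                            dispersion = 10, depth = NULL, coords,
                            seed = NULL) {
  model <- match.arg(model)
  means <- as.matrix(means)
  if (any(means < 0)) stop_input("means must be non-negative")
  if (model == "nb" && (!is.numeric(dispersion) || dispersion <= 0)) {
    stop_input("nb model requires dispersion > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(depth)) depth <- rep(1, ncol(means))
  mu <- sweep(means, 2, depth, "*")
  counts <- if (model == "poisson") {
    matrix(rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(rnbinom(length(mu), size = dispersion, mu = mu), nrow(mu))
  }
  dimnames(counts) <- dimnames(means)
  raw_counts(counts, coords)
}

#' Synthetic spatial benchmark with planted ground truth
#'
#' Assembles a complete test dataset emulating a Visium-like capture:
#' `n_svg` genes carrying a randomly drawn pattern archetype (hotspot,
#' stripe, or gradient; random location and scale, patterns spanning a
#' meaningful fraction of the tissue as real expression domains do) and
#' `n_null` spatially flat genes. Per-gene baselines are drawn
#' log-uniformly from 1 to 10 mean counts — the regime of moderately
#' expressed genes — so that score scale-invariance is exercised; counts
#' follow Poisson or negative binomial noise with log-normal library-size
#' factors (`sdlog = 0.3`) stressing the CPM normalisation.
#'
#' @param n_svg Number of pattern genes.
#' @param n_null Number of spatially random genes.
#' @param coords Spot coordinates (default: 20 x 20 grid).
#' @param model Count model (`"poisson"` default).
#' @param dispersion NB dispersion if `model = "nb"`.
#' @param effect_size Peak fold change of pattern genes over their baseline
#'   (default 5).
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return A `synthetic_dataset` list: `raw` (a `raw_counts`), `truth`
#'   tibble (`gene`, `is_svg`, `kind`), `means`, and `seed`.
#' @export
make_benchmark <- function(n_svg = 50, n_null = 450, coords = make_grid(20, 20),
                           model = c("poisson", "nb"), dispersion = 10,
                           effect_size = 5, seed = 1) {
  model <- match.arg(model)
  if (n_svg < 0 || n_null < 0 || n_svg + n_null == 0) {
    stop_input("need a positive total number of genes")
  }
  set.seed(seed)
  n <- nrow(coords)
  xr <- range(coords[, 1]); yr <- range(coords[, 2])

  kinds <- character(0)
  means <- NULL
  for (g in seq_len(n_svg)) {
    baseline <- exp(runif(1, log(1), log(10)))
    kind <- sample(c("hotspot", "stripe", "gradient"), 1)
    params <- list(baseline = baseline,
                   amplitude = effect_size * baseline)
    if (kind == "hotspot") {
      params$center <- c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]))
      params$radius <- runif(1, diff(xr) / 8, diff(xr) / 4)
    } else if (kind == "stripe") {
      params$axis <- sample(1:2, 1)
      rng <- if (params$axis == 1) xr else yr
      params$center <- runif(1, rng[1], rng[2])
      params$width <- runif(1, diff(rng) / 5, diff(rng) / 3)
      params$profile <- "smooth"
    } else {
      th <- runif(1, 0, 2 * pi)
      params$direction <- c(cos(th), sin(th))
    }
    means <- rbind(means, pattern_surface(coords, kind, params))
    kinds <- c(kinds, kind)
  }
  for (g in seq_len(n_null)) {
    baseline <- exp(runif(1, log(1), log(10)))
    means <- rbind(means, pattern_surface(coords, "null",
                                          list(baseline = baseline)))
    kinds <- c(kinds, "null")
  }
  rownames(means) <- c(
    if (n_svg > 0) paste0("svg", seq_len(n_svg)),
    if (n_null > 0) paste0("null", seq_len(n_null))
  )
  colnames(means) <- rownames(coords)

  depth <- exp(rnorm(n, 0, 0.3))   # log-normal library-size factors
  raw <- simulate_counts(means, model = model, dispersion = dispersion,
                         depth = depth, coords = coords)

  structure(
    list(
      raw = raw,
      truth = tibble::tibble(
        gene = rownames(means),
        is_svg = kinds != "null",
        kind = kinds
      ),
      means = means,
      seed = seed
    ),
    class = "synthetic_dataset"
  )
}

#' Two-family benchmark for functional tissue unit recovery
#'
#' Plants two gene families whose expression occupies two sharp-edged,
#' spatially disjoint discs (left and right of the tissue), plus optional
#' flat null genes. Because the expressing region of each family is a hard
#' disc, the truth spot set of each tissue unit is unambiguous: the spots
#' inside the disc.
#'
#' @param genes_per_family Genes in each of the two families (default 20).
#' @param n_null Additional spatially flat background genes (default 450).
#'   A realistically sized background matters: with too few genes the two
#'   modules dominate the per-spot totals and CPM normalisation distorts
#'   every other gene.
#' @param coords Spot coordinates (default: 20 x 20 grid).
#' @param effect_size Fold change inside the disc (default 5).
#' @param seed Integer seed.
#' @return A `synthetic_dataset` whose `truth_ftu` field holds the two
#'   disjoint truth spot-ID sets.
#' @export
make_ftu_benchmark <- function(genes_per_family = 20, n_null = 450,
                               coords = make_grid(20, 20), effect_size = 5,
                               seed = 1) {
  set.seed(seed)
  n <- nrow(coords)
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  centers <- list(
    c(xr[1] + diff(xr) / 4, mean(yr)),
    c(xr[2] - diff(xr) / 4, mean(yr))
  )
  radius <- min(diff(xr), diff(yr)) / 5

  means <- NULL
  # module genes that define tissue compartments are moderately expressed;
  # the flat background supplies most of each spot's counts
  for (fam in 1:2) {
    for (g in seq_len(genes_per_family)) {
      baseline <- exp(runif(1, log(2), log(8)))
      means <- rbind(means, pattern_surface(coords, "disc", list(
        center = centers[[fam]], radius = radius,
        baseline = baseline, amplitude = effect_size * baseline
      )))
    }
  }
  for (g in seq_len(n_null)) {
    baseline <- exp(runif(1, log(1), log(10)))
    means <- rbind(means, pattern_surface(coords, "null",
                                          list(baseline = baseline)))
  }
  fam_label <- c(rep(1:2, each = genes_per_family), rep(0L, n_null))
  rownames(means) <- c(
    paste0("fam1_g", seq_len(genes_per_family)),
    paste0("fam2_g", seq_len(genes_per_family)),
    if (n_null > 0) paste0("null", seq_len(n_null))
  )
  colnames(means) <- rownames(coords)

  depth <- exp(rnorm(n, 0, 0.3))
  raw <- simulate_counts(means, depth = depth, coords = coords)

  truth_ftu <- lapply(centers, function(ctr) {
    d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
    rownames(coords)[d2 <= radius^2]
  })
  names(truth_ftu) <- c("left", "right")

  structure(
    list(
      raw = raw,
      truth = tibble::tibble(
        gene = rownames(means),
        is_svg = fam_label > 0,
        kind = ifelse(fam_label > 0, "disc", "null"),
        family = fam_label
      ),
      truth_ftu = truth_ftu,
      means = means,
      seed = seed
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes (%d planted SVGs) x %d spots, seed %d\n",
              nrow(x$raw$values), sum(x$truth$is_svg), ncol(x$raw$values),
              x$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk (matrix, coordinates, truth)
#'
#' @param x A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(x$raw, file.path(dir, "counts.tsv"))
  write_coords(x$raw$coords, file.path(dir, "coords.tsv"))
  write.table(as.data.frame(x$truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
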