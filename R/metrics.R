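#' Set-overlap metrics for recovered gene or spot sets
#'
#' Standard confusion-based metrics of a predicted set against a truth set:
#' Jaccard, precision, recall, F1, and the Tversky index
#' `TP / (TP + alpha * FP + beta * FN)` (which collapses to Jaccard at
#' `alpha = beta = 1` and to the Dice/F1 numerator weighting at 0.5/0.5).
#'
#' @param predicted Predicted set (vector of identifiers).
#' @param truth Non-empty truth set.
#' @param tversky_alpha,tversky_beta Tversky weights (defaults 0.5, 0.5).
#' @return One-row tibble with `jaccard`, `precision`, `recall`, `f1`,
#'   `tversky`, `tp`, `fp`, `fn`.
#' @export
set_metrics <- function(predicted, truth, tversky_alpha = 0.5,
                        tversky_beta = 0.5) {
  if (length(truth) == 0) stop_input("truth set is empty")
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  if (length(predicted) == 0) {
    warn("empty predicted set; precision defined as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(
    jaccard = tp / (tp + fp + fn),
    precision = precision,
    recall = recall,
    f1 = f1,
    tversky = tp / (tp + tversky_alpha * fp + tversky_beta * fn),
    tp = tp, fp = fp, fn = fn
  )
}

#' Adjusted Rand index between two labelings
#'
#' Agreement of two partitions of the same items, corrected for chance: 1
#' for identical partitions (up to relabeling), about 0 for independent
#' ones. Computed from the contingency table via
#' `mclust::adjustedRandIndex`.
#'
#' @param labels_a,labels_b Label vectors of equal length >= 2.
#' @return Scalar ARI.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_input("label vectors differ in length")
  }
  if (length(labels_a) < 2) stop_input("need at least 2 items")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Structural similarity (SSIM) between two pattern images
#'
#' Mean over dense (stride-1) square sliding windows of the product of
#' luminance, contrast, and structure comparisons:
#' `l = (2 mx my + C1) / (mx^2 + my^2 + C1)`,
#' `c = (2 sx sy + C2) / (sx^2 + sy^2 + C2)`,
#' `s = (sxy + C3) / (sx sy + C3)`, each raised to its exponent. Images are
#' globally min-max rescaled to \[0, 1\] first; the stabiliser constants
#' default to `(0.01)^2`, `(0.03)^2`, `C2 / 2` for that unit range. Identical
#' images score exactly 1.
#'
#' @param img_a,img_b Numeric matrices of identical shape, at least
#'   `window` in each dimension.
#' @param window Side length of the square window (default 8).
#' @param exponents Length-3 exponents (alpha, beta, gamma) for l, c, s.
#' @param constants Length-3 stabilisers (C1, C2, C3).
#' @return Scalar SSIM (<= 1).
#' @export
ssim <- function(img_a, img_b, window = 8, exponents = c(1, 1, 1),
                 constants = c(0.01^2, 0.03^2, 0.03^2 / 2)) {
  A <- as.matrix(img_a); B <- as.matrix(img_b)
  if (!all(dim(A) == dim(B))) stop_input("images differ in shape")
  if (nrow(A) < window || ncol(A) < window) {
    stop_input("images smaller than the window")
  }
  rescale01 <- function(M) {
    r <- range(M)
    if (r[1] == r[2]) return(M * 0)
    (M - r[1]) / (r[2] - r[1])
  }
  A <- rescale01(A); B <- rescale01(B)
  C1 <- constants[1]; C2 <- constants[2]; C3 <- constants[3]
  w2 <- window^2

  vals <- numeric(0)
  nr <- nrow(A) - window + 1L
  nc <- ncol(A) - window + 1L
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x <- A[i:(i + window - 1L), j:(j + window - 1L)]
      y <- B[i:(i + window - 1L), j:(j + window - 1L)]
      mx <- mean(x); my <- mean(y)
      # population (1/n) moments, as in the reference SSIM formulation
      sx2 <- sum((x - mx)^2) / w2
      sy2 <- sum((y - my)^2) / w2
      sxy <- sum((x - mx) * (y - my)) / w2
      sx <- sqrt(sx2); sy <- sqrt(sy2)
      l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
      cc <- (2 * sx * sy + C2) / (sx2 + sy2 + C2)
      ss <- (sxy + C3) / (sx * sy + C3)
      vals[i, j] <- (l^exponents[1]) * (cc^exponents[2]) *
        sign(ss) * abs(ss)^exponents[3]
    }
  }
  mean(vals)
}

#' Rasterise a per-spot signal on a lattice into an image matrix
#'
#' Helper for SSIM comparisons of spatial patterns: places each spot's value
#' at its (rounded) lattice position.
#'
#' @param coords Spot-by-2 coordinate matrix (approximately integer lattice).
#' @param values Per-spot numeric vector.
#' @return Numeric matrix with `NA`-free cells (missing cells get 0).
#' @export
rasterize_spots <- function(coords, values) {
  xi <- round(coords[, 1] - min(round(coords[, 1]))) + 1L
  yi <- round(coords[, 2] - min(round(coords[, 2]))) + 1L
  img <- matrix(0, max(yi), max(xi))
  img[cbind(yi, xi)] <- values
  img
}
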