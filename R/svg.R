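#' Normalised Fourier coefficient magnitudes
#'
#' Converts a signed coefficient vector into a probability-like weight
#' vector: `|f_hat_k| / sum(|f_hat|)`. Magnitudes are used because signed
#' coefficients could cancel in the sum.
#'
#' @param fcs Numeric coefficient vector, not all zero.
#' @return Non-negative vector of the same length summing to 1.
#' @export
normalized_fcs <- function(fcs) {
  a <- abs(as.numeric(fcs))
  s <- sum(a)
  if (s == 0) stop_input("all Fourier coefficients are zero (constant-zero gene?)")
  a / s
}

#' Frequency-weighted spatial-organisation score for one gene
#'
#' Scores the low-frequency content of a signal's spectrum:
#' `sum_k exp(-lambda_k) * fnorm_k`, where `fnorm` are the normalised
#' coefficient magnitudes and all zero-eigenvalue (constant/DC) modes are
#' excluded from the sum. Smooth spatial patterns concentrate energy at small
#' eigenvalues and score high; spatially random signals spread energy across
#' the spectrum and score low. The score is invariant to positive rescaling
#' of the signal.
#'
#' @param eigenvalues Ascending eigenvalue vector of the basis.
#' @param fcs Fourier coefficient vector of the same length.
#' @return Non-negative scalar score.
#' @export
gftscore <- function(eigenvalues, fcs) {
  if (length(eigenvalues) != length(fcs)) {
    stop_input("eigenvalues and coefficients differ in length")
  }
  fn <- normalized_fcs(fcs)
  keep <- eigenvalues > 1e-8           # drop lambda_1 and any other zero modes
  sum(exp(-eigenvalues[keep]) * fn[keep])
}

#' Knee-point cutoff on a ranked score curve
#'
#' Sorts scores in decreasing order and locates the knee of the resulting
#' curve (convex, decreasing) with [kneedle()]; the score at the knee is the
#' cutoff separating high-scoring genes from the bulk. Falls back to the 90th
#' percentile, with a warning, when no knee is found (e.g. all scores equal).
#'
#' @param scores Numeric vector, at least 4 values.
#' @param sensitivity Kneedle sensitivity S (default 6).
#' @return The cutoff score (a value on the scale of `scores`).
#' @export
score_cutoff <- function(scores, sensitivity = 6) {
  scores <- as.numeric(scores)
  if (length(scores) < 4) stop_input("need at least 4 scores for a cutoff")
  y <- sort(scores, decreasing = TRUE)
  k <- kneedle(y, sensitivity = sensitivity,
               shape = "convex", direction = "decreasing")
  if (is.na(k)) {
    warn("no knee found on the score curve; cutoff falls back to the 90th percentile")
    return(unname(stats::quantile(scores, 0.9)))
  }
  y[k]
}

#' One-sided low- vs high-frequency band test for one gene
#'
#' Wilcoxon rank-sum test of whether the low-frequency coefficient
#' magnitudes exceed the high-frequency ones (alternative: low > high). The
#' low band is coefficients `2..(1 + n_low)` (the zero mode is excluded), the
#' high band the last `n_high` coefficients.
#'
#' Small bands (`n_low + n_high <= 25`) use the classical exact null
#' distribution, guaranteeing a valid (conservative) p-value. Larger bands
#' use an exact smoothed (fuzzy) p-value, `P(U > u) + c * P(U = u)`: at
#' these sizes the discrete null still has p-value atoms of the order of a
#' percent, which visibly distorts the null p-value distribution and hence
#' the downstream FDR step. The smoothing variate `c` is derived
#' deterministically from the coefficient magnitudes themselves (for
#' continuous i.i.d. data the ranks are independent of the order
#' statistics, so `c` is uniform and independent of the rank-sum under the
#' null); the resulting p-values are uniform under the null and
#' reproducible for identical input. Very large bands (sum > 200) or tied
#' magnitudes fall back to the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param fcs Fourier coefficient vector for one gene.
#' @param n_low,n_high Band sizes (both >= 1; bands must not overlap).
#' @return One-sided p-value in \[0, 1\].
#' @export
band_test <- function(fcs, n_low, n_high) {
  n <- length(fcs)
  n_low <- as.integer(n_low); n_high <- as.integer(n_high)
  if (n_low < 1 || n_high < 1) stop_input("band sizes must be >= 1")
  if (1 + n_low > n - n_high) stop_input("low and high bands overlap")
  low <- abs(fcs[seq(2L, 1L + n_low)])
  high <- abs(fcs[seq(n - n_high + 1L, n)])

  size <- n_low + n_high
  ties <- anyDuplicated(c(low, high)) > 0
  if (size <= 25) {
    return(suppressWarnings(
      stats::wilcox.test(low, high, alternative = "greater",
                         exact = TRUE)$p.value
    ))
  }
  if (!ties && size <= 200) {
    u <- sum(rank(c(low, high))[seq_len(n_low)]) - n_low * (n_low + 1) / 2
    # atom-smoothing variate: a fine-scale function of the order statistics,
    # uniform on (0, 1) and independent of the ranks for continuous data
    cc <- (sum(c(low, high)) * 1e6) %% 1
    return(stats::pwilcox(u, n_low, n_high, lower.tail = FALSE) +
             cc * stats::dwilcox(u, n_low, n_high))
  }
  suppressWarnings(
    stats::wilcox.test(low, high, alternative = "greater",
                       exact = FALSE, correct = FALSE)$p.value
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named step
#' so the SVG pipeline reads as in its description.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, elementwise >= the input and <= 1.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Identify spatially variable genes
#'
#' Full SVG pipeline: transform every gene into the frequency domain, score
#' its low-frequency content ([gftscore()]), place the knee-point cutoff on
#' the ranked score curve ([score_cutoff()]), test low- against
#' high-frequency coefficient magnitudes per gene ([band_test()]), adjust
#' p-values by Benjamini-Hochberg, and call a gene an SVG when its score
#' exceeds the cutoff *and* its q-value is below `alpha`.
#'
#' Genes with zero spatial variance receive score 0 and p-value 1 and are
#' excluded from the knee-point curve.
#'
#' @param expr An `expression_matrix` (see [normalize_counts()]) or a plain
#'   gene-by-spot numeric matrix with row names.
#' @param basis A `spectral_basis` over the same spots.
#' @param sensitivity Kneedle sensitivity for the score cutoff (default 6).
#' @param alpha FDR threshold for the SVG call (default 0.05).
#' @return An object of class `svg_result` wrapping a tibble with columns
#'   `gene`, `gftscore`, `rank`, `pvalue`, `qvalue`, `is_svg`, plus the
#'   shared `cutoff_score` and band sizes as attributes. Use [tidy()] /
#'   [glance()] to extract.
#' @export
identify_svgs <- function(expr, basis, sensitivity = 6, alpha = 0.05) {
  X <- expr_values(expr)
  stopifnot(inherits(basis, "spectral_basis"))
  n <- length(basis$eigenvalues)
  if (ncol(X) != n) stop_input("expression spots do not match the spectral basis")
  m <- nrow(X)
  if (m < 4) stop_input("need at least 4 genes to identify SVGs")

  fc <- X %*% basis$modes                     # gene x mode coefficient matrix
  variable <- apply(X, 1, function(r) max(r) > min(r))

  scores <- rep(0, m)
  pvals <- rep(1, m)
  for (i in which(variable)) {
    scores[i] <- gftscore(basis$eigenvalues, fc[i, ])
    pvals[i] <- band_test(fc[i, ], basis$n_low, basis$n_high)
  }

  if (sum(variable) < 4) stop_input("fewer than 4 genes with spatial variance")
  cutoff <- score_cutoff(scores[variable], sensitivity = sensitivity)
  qvals <- fdr_adjust(pvals)

  tbl <- tibble::tibble(
    gene = rownames(X) %||% paste0("gene", seq_len(m)),
    gftscore = scores,
    rank = as.integer(rank(-scores, ties.method = "first")),
    pvalue = pvals,
    qvalue = qvals,
    is_svg = scores > cutoff & qvals < alpha,
    cutoff_score = cutoff
  )

  structure(
    list(
      table = tbl,
      cutoff_score = cutoff,
      n_low = basis$n_low,
      n_high = basis$n_high,
      sensitivity = sensitivity,
      alpha = alpha,
      basis_hash = basis$basis_hash
    ),
    class = "svg_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.svg_result <- function(x, ...) {
  cat(sprintf(
    "<svg_result> %d genes, %d SVGs (cutoff %.4g, n_low %d, n_high %d, alpha %g)\n",
    nrow(x$table), sum(x$table$is_svg), x$cutoff_score, x$n_low, x$n_high,
    x$alpha
  ))
  invisible(x)
}

#' List of genes called spatially variable
#'
#' @param x An `svg_result`.
#' @return Character vector of SVG gene identifiers, in rank order.
#' @export
svg_genes <- function(x) {
  stopifnot(inherits(x, "svg_result"))
  tbl <- x$table[x$table$is_svg, ]
  tbl$gene[order(tbl$rank)]
}

#' Write an SVG table to TSV with a parameter header
#'
#' @param x An `svg_result`.
#' @param path Output file path.
#' @param extra Named character vector of additional `# key=value` header
#'   lines (e.g. graph parameters).
#' @return `path`, invisibly.
#' @export
write_svg_table <- function(x, path, extra = character()) {
  stopifnot(inherits(x, "svg_result"))
  hdr <- c(
    sprintf("# sensitivity=%g", x$sensitivity),
    sprintf("# alpha=%g", x$alpha),
    sprintf("# n_low=%d", x$n_low),
    sprintf("# n_high=%d", x$n_high),
    sprintf("# cutoff_score=%.10g", x$cutoff_score),
    if (length(extra)) sprintf("# %s=%s", names(extra), extra)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- x$table[, c("gene", "gftscore", "rank", "pvalue", "qvalue", "is_svg")]
  names(out)[6] <- "svg"
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
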