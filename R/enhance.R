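#' Low-pass filter configuration
#'
#' The enhancement filter has two knobs: the smoothness weight `c` of the
#' graph-regularised denoising problem, and the truncation multiplier
#' `ratio_fms` that keeps only the first `round(ratio_fms * sqrt(n))`
#' low-frequency coefficients before the inverse transform. The Visium-scale
#' defaults are `c = 0.005` and `ratio_fms = 15`. With `keep_all = TRUE` no
#' truncation is applied and the filter is exactly the closed-form minimiser
#' of `||f - f_g||^2 + c * t(f) L f`.
#'
#' @param c Positive regularisation weight (default 0.005).
#' @param ratio_fms Positive truncation multiplier (default 15).
#' @param keep_all If `TRUE`, weight all coefficients and skip truncation.
#' @param clip_negative If `TRUE`, clip negative enhanced values to zero
#'   (off by default; the filter is linear and small negatives are expected).
#' @return A `filter_config` list.
#' @export
filter_config <- function(c = 0.005, ratio_fms = 15, keep_all = FALSE,
                          clip_negative = FALSE) {
  if (!is.numeric(c) || c <= 0) stop_input("c must be positive")
  if (!is.numeric(ratio_fms) || ratio_fms <= 0) {
    stop_input("ratio_fms must be positive")
  }
  structure(
    list(c = c, ratio_fms = ratio_fms, keep_all = isTRUE(keep_all),
         clip_negative = isTRUE(clip_negative)),
    class = "filter_config"
  )
}

#' Spectral low-pass filter weights
#'
#' The diagonal filter `1 / (1 + c * lambda_k)`: weight 1 at the zero mode,
#' strictly decreasing in frequency, so high-frequency (noise-dominated)
#' coefficients are shrunk hardest.
#'
#' @param eigenvalues Ascending eigenvalue vector.
#' @param c Positive regularisation weight.
#' @return Weight vector in (0, 1], non-increasing.
#' @export
low_pass_weights <- function(eigenvalues, c) {
  if (!is.numeric(c) || c <= 0) stop_input("c must be positive")
  1 / (1 + c * eigenvalues)
}

#' Enhance one spatial signal by low-pass filtering
#'
#' Transforms the signal to the frequency domain, shrinks each coefficient
#' by `1 / (1 + c * lambda_k)`, optionally zeroes everything beyond the first
#' `round(ratio_fms * sqrt(n))` modes, and reconstructs via the inverse
#' transform. With `keep_all = TRUE` the output is the unique minimiser of
#' `||f - signal||^2 + c * t(f) L f`, i.e. it solves
#' `(I + c L) f_star = signal`.
#'
#' @param basis A `spectral_basis`.
#' @param signal Numeric vector over spots.
#' @param cfg A [filter_config()].
#' @return Enhanced signal vector of the same length.
#' @export
enhance_signal <- function(basis, signal, cfg = filter_config()) {
  stopifnot(inherits(basis, "spectral_basis"), inherits(cfg, "filter_config"))
  n <- length(basis$eigenvalues)
  fhat <- gft(basis, signal)
  w <- low_pass_weights(basis$eigenvalues, cfg$c)
  if (cfg$keep_all) {
    fhat <- fhat * w
  } else {
    k_low <- as.integer(round(cfg$ratio_fms * sqrt(n)))
    if (k_low > n) stop_input("ratio_fms keeps more modes than exist; lower it or set keep_all")
    k_low <- max(1L, k_low)
    fhat <- c(fhat[seq_len(k_low)] * w[seq_len(k_low)], rep(0, n - k_low))
  }
  out <- igft(basis, fhat)
  if (cfg$clip_negative) out <- pmax(out, 0)
  out
}

#' Enhance selected genes of an expression matrix
#'
#' Applies [enhance_signal()] to each selected gene row; unselected genes
#' pass through unchanged. The filter configuration is recorded as an
#' attribute of the result.
#'
#' @param expr An `expression_matrix` (or gene-by-spot matrix).
#' @param basis A `spectral_basis` over the same spots.
#' @param cfg A [filter_config()].
#' @param genes Optional character vector of gene identifiers to enhance
#'   (default: all genes).
#' @return An `expression_matrix` with enhanced values.
#' @export
enhance_matrix <- function(expr, basis, cfg = filter_config(), genes = NULL) {
  X <- expr_values(expr)
  if (ncol(X) != length(basis$eigenvalues)) {
    stop_input("expression spots do not match the spectral basis")
  }
  if (is.null(genes)) {
    rows <- seq_len(nrow(X))
  } else {
    rows <- match(genes, rownames(X))
    if (anyNA(rows)) {
      stop_input(sprintf("unknown gene(s): %s",
                         paste(genes[is.na(rows)], collapse = ", ")))
    }
  }
  out <- X
  for (i in rows) out[i, ] <- enhance_signal(basis, X[i, ], cfg)

  res <- if (inherits(expr, "expression_matrix")) {
    expr$values <- out
    expr
  } else {
    out
  }
  attr(res, "filter_config") <- cfg
  res
}
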