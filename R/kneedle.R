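#' Kneedle knee/elbow detection
#'
#' Locates the point of maximum curvature ("knee") of a curve sampled at
#' indices `1..n`, following the Kneedle procedure: rescale the curve to the
#' unit square, rotate it so the curve becomes concave increasing, form the
#' difference curve between the rotated values and the diagonal, and accept
#' the first local maximum of the difference curve whose lead over the
#' subsequent values exceeds a sensitivity-scaled threshold
#' `T = y_max - S * mean(diff(x))`.
#'
#' @param y Finite numeric vector of length >= 4, sampled at equal index
#'   spacing.
#' @param sensitivity Positive sensitivity S; larger values demand a sharper
#'   knee before one is declared (default 6).
#' @param shape `"convex"` or `"concave"` — the curvature of `y` as given.
#' @param direction `"increasing"` or `"decreasing"` — the trend of `y`.
#' @return 1-based integer index of the knee in `y`, or `NA_integer_` when no
#'   knee passes the sensitivity threshold (e.g. a straight line).
#' @examples
#' kneedle(c(100, 50, 25, 12, 11, 10.5, 10.2, 10),
#'         shape = "convex", direction = "decreasing")
#' @export
kneedle <- function(y, sensitivity = 6,
                    shape = c("convex", "concave"),
                    direction = c("increasing", "decreasing")) {
  shape <- match.arg(shape)
  direction <- match.arg(direction)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4) stop_input("kneedle needs at least 4 points")
  if (!all(is.finite(y))) stop_input("kneedle input must be finite")
  if (!is.numeric(sensitivity) || sensitivity <= 0) {
    stop_input("sensitivity must be positive")
  }

  rng <- diff(range(y))
  if (rng == 0) return(NA_integer_)   # flat curve: no curvature
  x_n <- (seq_len(n) - 1) / (n - 1)
  y_n <- (y - min(y)) / rng

  # rotate every shape/direction combination into concave-increasing form,
  # tracking whether the x axis was flipped so the index maps back
  flipped <- FALSE
  if (direction == "decreasing") {
    if (shape == "concave") {
      y_n <- rev(y_n)
      flipped <- TRUE
    } else {            # convex decreasing
      y_n <- 1 - y_n
    }
  } else if (shape == "convex") {     # convex increasing
    y_n <- rev(1 - y_n)
    flipped <- TRUE
  }

  y_d <- y_n - x_n
  if (max(y_d) <= 1e-10) return(NA_integer_)   # straight line: no curvature

  # interior local maxima of the difference curve (plateaus take the first index)
  is_lmx <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    y_d[i] >= y_d[i - 1] && y_d[i] > y_d[i + 1]
  }, logical(1))
  lmx <- which(is_lmx)
  if (length(lmx) == 0) return(NA_integer_)

  is_lmn <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    y_d[i] <= y_d[i - 1] && y_d[i] < y_d[i + 1]
  }, logical(1))

  threshold_drop <- sensitivity * mean(diff(x_n))
  knee_t <- NA_integer_
  for (m in lmx) {
    threshold <- y_d[m] - threshold_drop
    j <- m + 1L
    while (j <= n) {
      if (is_lmx[j]) break                      # next candidate takes over
      if (is_lmn[j]) threshold <- 0             # curve turned back up: reset
      if (y_d[j] < threshold - 1e-12) { knee_t <- m; break }
      j <- j + 1L
    }
    if (!is.na(knee_t)) break
  }
  if (is.na(knee_t)) return(NA_integer_)

  if (flipped) n - knee_t + 1L else knee_t
}
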