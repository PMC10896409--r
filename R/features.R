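#' Frequency-domain spot features from a spot-similarity matrix
#'
#' Computes the spot cosine/inner-product similarity matrix
#' `X_s = X %*% t(X)` from a spot-major expression matrix, transforms it
#' into the frequency domain (`t(U) %*% X_s`), and keeps the first `n_fc`
#' coefficient rows. The result, transposed to spot-major, can be
#' concatenated to the expression matrix as additional input features for a
#' spatial-domain classifier (see [augment_features()]).
#'
#' @param expr_spot_major Spot-by-gene numeric matrix.
#' @param basis A `spectral_basis` over the same spots.
#' @param n_fc Number of Fourier coefficients to keep (default 1000, capped
#'   at the number of spots).
#' @return A `frequency_features` list with `spot_fcs` (spot-by-`n_fc`),
#'   `n_fc`, and `basis_hash`.
#' @export
spot_fc_features <- function(expr_spot_major, basis, n_fc = 1000) {
  X <- as.matrix(expr_spot_major)
  n <- length(basis$eigenvalues)
  if (nrow(X) != n) stop_input("spot count does not match the spectral basis")
  if (n_fc > n) stop_input("n_fc exceeds the number of modes")
  Xs <- tcrossprod(X)                       # spot x spot similarity
  Xhat <- crossprod(basis$modes, Xs)        # mode x spot
  structure(
    list(
      spot_fcs = t(Xhat[seq_len(n_fc), , drop = FALSE]),
      n_fc = as.integer(n_fc),
      basis_hash = basis$basis_hash
    ),
    class = "frequency_features"
  )
}

#' Concatenate frequency features onto a spot-major expression matrix
#'
#' @param expr_spot_major Spot-by-gene matrix.
#' @param features A `frequency_features` object over the same spots.
#' @return Spot-by-(gene + n_fc) matrix; feature columns named `FC1..`.
#' @export
augment_features <- function(expr_spot_major, features) {
  stopifnot(inherits(features, "frequency_features"))
  X <- as.matrix(expr_spot_major)
  if (nrow(X) != nrow(features$spot_fcs)) {
    stop_input("spot counts differ between expression and features")
  }
  fc <- features$spot_fcs
  colnames(fc) <- paste0("FC", seq_len(ncol(fc)))
  cbind(X, fc)
}

#' Cosine-distance cost matrix between annotation and spot coefficients
#'
#' Entry (t, b) is `1 - cosine(annotation_t, spot_b)`, in \[0, 2\]: the
#' frequency-domain transport cost from annotation (e.g. cell type) t to
#' spatial object b.
#'
#' @param annotation_fcs Annotation-by-`n_fc` matrix.
#' @param spot_fcs Spot-by-`n_fc` matrix.
#' @return Annotation-by-spot cost matrix.
#' @export
fc_cost_matrix <- function(annotation_fcs, spot_fcs) {
  A <- as.matrix(annotation_fcs)
  B <- as.matrix(spot_fcs)
  if (ncol(A) != ncol(B)) stop_input("coefficient dimensions differ")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop_input("zero rows are not allowed")
  1 - tcrossprod(A / na, B / nb)
}

#' Fuse a base and an update cost matrix
#'
#' `beta * base + (1 - beta) * update`; `beta = 0.8` is the default balance
#' for annotation-transfer cost fusion.
#'
#' @param base_cost,update_cost Matrices of identical shape.
#' @param beta Mixing weight in \[0, 1\].
#' @return Fused cost matrix.
#' @export
fuse_costs <- function(base_cost, update_cost, beta = 0.8) {
  if (!all(dim(base_cost) == dim(update_cost))) {
    stop_input("cost matrices differ in shape")
  }
  if (beta < 0 || beta > 1) stop_input("beta must lie in [0, 1]")
  beta * base_cost + (1 - beta) * update_cost
}

#' Frequency-domain similarity terms for reconstruction objectives
#'
#' Given a reconstructed and a reference spot-by-gene matrix, returns two
#' unweighted objective terms: the sum over genes of the cosine similarity
#' between the frequency-domain gene profiles (`t(U) %*% X` columns), and
#' the sum over spots of the cosine similarity between the frequency-domain
#' columns of the spot similarity matrices (`t(U) %*% X %*% t(X)`). Callers
#' apply their own weights.
#'
#' @param x_recon,x_ref Spot-by-gene matrices of identical shape.
#' @param basis A `spectral_basis` over the spots.
#' @param n_fc Number of coefficient rows to use (default: all).
#' @return Named list `gene_term`, `spot_term`.
#' @export
frequency_similarity_terms <- function(x_recon, x_ref, basis,
                                       n_fc = length(basis$eigenvalues)) {
  A <- as.matrix(x_recon); B <- as.matrix(x_ref)
  n <- length(basis$eigenvalues)
  if (!all(dim(A) == dim(B))) stop_input("matrices differ in shape")
  if (nrow(A) != n) stop_input("spot count does not match the spectral basis")
  Uk <- basis$modes[, seq_len(n_fc), drop = FALSE]

  cos_cols <- function(M1, M2) {
    num <- colSums(M1 * M2)
    den <- sqrt(colSums(M1^2)) * sqrt(colSums(M2^2))
    num / ifelse(den == 0, 1, den)
  }

  gene_term <- sum(cos_cols(crossprod(Uk, A), crossprod(Uk, B)))
  spot_term <- sum(cos_cols(crossprod(Uk, tcrossprod(A)),
                            crossprod(Uk, tcrossprod(B))))
  list(gene_term = gene_term, spot_term = spot_term)
}

#' Spectral spreading entropy of coefficient channels
#'
#' For each channel (column), normalises the squared coefficients to a
#' probability vector `p_k = fc_k^2 / sum(fc^2)` and computes the Shannon
#' entropy `-sum p_k log p_k` (natural log, `0 log 0 = 0`); channel
#' entropies are summed. A one-hot spectrum scores 0 (fully concentrated), a
#' uniform spectrum scores `log(n_fc)` — so the value measures how spread a
#' signal is across frequencies and can serve as a concentration
#' regulariser.
#'
#' @param fcs `n_fc`-by-channel numeric matrix (a vector is treated as one
#'   channel).
#' @return Non-negative scalar; each channel contributes at most
#'   `log(n_fc)`.
#' @export
spreading_entropy <- function(fcs) {
  M <- as.matrix(fcs)
  tot <- colSums(M^2)
  if (any(tot == 0)) stop_input("all-zero channel in coefficient matrix")
  P <- sweep(M^2, 2, tot, "/")
  plogp <- ifelse(P > 0, P * log(P), 0)
  -sum(plogp)
}
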