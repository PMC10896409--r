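#' Cluster SVGs on their low-frequency Fourier coefficients
#'
#' Builds a gene KNN graph from cosine similarity between low-frequency
#' coefficient vectors (k = `min(n_neighbors, n_svg - 1)`, edges weighted by
#' similarity, non-positive similarities dropped) and partitions it with
#' Louvain community detection at the given resolution.
#'
#' @param fc_low SVG-by-mode numeric matrix of low-frequency coefficients
#'   (row names are gene identifiers).
#' @param resolution Positive Louvain resolution.
#' @param n_neighbors Gene-graph neighbourhood size (default 15).
#' @param seed Integer seed controlling the Louvain run.
#' @return Integer cluster labels (contiguous from 1), named by gene.
#' @export
cluster_svgs <- function(fc_low, resolution, n_neighbors = 15, seed = 1) {
  fc_low <- as.matrix(fc_low)
  m <- nrow(fc_low)
  if (m < 2) stop_input("need at least 2 SVGs to cluster")
  if (resolution <= 0) stop_input("resolution must be positive")

  nrm <- sqrt(rowSums(fc_low^2))
  nrm[nrm == 0] <- 1
  cosim <- tcrossprod(fc_low / nrm)
  diag(cosim) <- -Inf

  k <- min(n_neighbors, m - 1L)
  edges <- NULL
  weights <- NULL
  for (i in seq_len(m)) {
    nb <- order(cosim[i, ], decreasing = TRUE)[seq_len(k)]
    keep <- cosim[i, nb] > 0     # Louvain needs non-negative weights
    nb <- nb[keep]
    if (length(nb)) {
      edges <- c(edges, rbind(i, nb))
      weights <- c(weights, cosim[i, nb])
    }
  }
  gr <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, m - igraph::vcount(gr)))
  igraph::E(gr)$weight <- weights
  gr <- igraph::simplify(gr, edge.attr.comb = list(weight = "max"))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  comm <- igraph::cluster_louvain(gr, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  labels <- match(labels, unique(labels))   # contiguous from 1, first-seen order
  names(labels) <- rownames(fc_low)
  labels
}

#' Pseudo-expression of a gene set per spot
#'
#' The per-spot sum over the set of log-scale expression values: a single
#' surface summarising where a gene module is expressed. Values not yet on
#' the log scale are `log1p`-transformed first (an `expression_matrix`
#' produced by [normalize_counts()] records whether its values are already
#' logged); additive over disjoint gene sets either way.
#'
#' @param expr An `expression_matrix` (or gene-by-spot matrix of
#'   non-logged values).
#' @param gene_set Non-empty character vector of gene identifiers.
#' @return Named numeric vector over spots.
#' @export
pseudo_expression <- function(expr, gene_set) {
  X <- expr_values(expr)
  if (length(gene_set) == 0) stop_input("gene_set is empty")
  idx <- match(gene_set, rownames(X))
  if (anyNA(idx)) {
    stop_input(sprintf("unknown gene(s): %s",
                       paste(gene_set[is.na(idx)], collapse = ", ")))
  }
  logged <- inherits(expr, "expression_matrix") &&
    isTRUE(expr$log_transformed)
  V <- X[idx, , drop = FALSE]
  if (!logged) V <- log1p(V)
  colSums(V)
}

#' Pick the high-expression spot set of a pseudo-expression surface
#'
#' One-dimensional 2-means with deterministic initialisation at the minimum
#' and maximum values; returns the spots of the cluster with the larger
#' mean. Invariant to increasing affine transforms of the input.
#'
#' @param pseudo Named numeric vector over spots.
#' @return Character vector of spot identifiers in the high cluster.
#' @export
assign_spots <- function(pseudo) {
  v <- as.numeric(pseudo)
  ids <- names(pseudo) %||% as.character(seq_along(v))
  if (length(v) < 2 || max(v) == min(v)) {
    stop_input("pseudo-expression is constant; cannot split spots")
  }
  # Lloyd iterations in 1-D from (min, max): deterministic and robust for
  # any input size
  ctr <- c(min(v), max(v))
  assign <- NULL
  for (it in 1:100) {
    new_assign <- as.integer(abs(v - ctr[1]) > abs(v - ctr[2])) + 1L
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in 1:2) if (any(assign == k)) ctr[k] <- mean(v[assign == k])
  }
  ids[assign == which.max(ctr)]
}

#' Mean pairwise overlap of FTU spot sets
#'
#' `2 * sum_{k<l} |S_k intersect S_l| / (n * (n - 1))`: the average
#' intersection size over ordered pairs. Zero exactly when all sets are
#' pairwise disjoint.
#'
#' @param spot_sets List (length >= 2) of character vectors of spot IDs.
#' @return Non-negative scalar.
#' @export
overlap_objective <- function(spot_sets) {
  n <- length(spot_sets)
  if (n < 2) stop_input("need at least 2 spot sets")
  total <- 0
  for (k in seq_len(n - 1)) {
    for (l in seq(k + 1, n)) {
      total <- total + length(intersect(spot_sets[[k]], spot_sets[[l]]))
    }
  }
  2 * total / (n * (n - 1))
}

#' Detect functional tissue units across a resolution grid
#'
#' For each candidate Louvain resolution: cluster the SVGs on their
#' low-frequency coefficients, build each cluster's pseudo-expression
#' surface, split spots by 1-D 2-means, and score the partition by the mean
#' pairwise overlap of the resulting spot sets. The resolution with the
#' smallest overlap wins (ties go to the smallest resolution); resolutions
#' yielding fewer than 2 gene clusters are skipped.
#'
#' @param fc_low SVG-by-mode matrix of low-frequency coefficients.
#' @param expr An `expression_matrix` covering the same genes.
#' @param res_grid Candidate resolutions (default `seq(0.2, 3, by = 0.2)`).
#' @param n_neighbors Gene-graph neighbourhood size (default 15).
#' @param seed Integer seed for the Louvain runs.
#' @return An object of class `ftu_result`: list with the chosen
#'   `resolution`, `gene_clusters` (named integer vector), `spot_sets`
#'   (list of spot-ID vectors), `overlap`, the cluster-by-spot `pseudo`
#'   matrix, and the full `grid` tibble of evaluated resolutions.
#' @export
optimize_resolution <- function(fc_low, expr, res_grid = seq(0.2, 3, by = 0.2),
                                n_neighbors = 15, seed = 1) {
  if (length(res_grid) == 0) stop_input("res_grid is empty")
  res_grid <- sort(unique(as.numeric(res_grid)))

  best <- NULL
  grid_rows <- list()
  for (res in res_grid) {
    labels <- cluster_svgs(fc_low, resolution = res,
                           n_neighbors = n_neighbors, seed = seed)
    n_cl <- max(labels)
    if (n_cl < 2) {
      grid_rows[[length(grid_rows) + 1]] <-
        tibble::tibble(resolution = res, n_clusters = n_cl, overlap = NA_real_)
      next
    }
    sets <- vector("list", n_cl)
    pseudo <- NULL
    for (kk in seq_len(n_cl)) {
      ps <- pseudo_expression(expr, names(labels)[labels == kk])
      pseudo <- rbind(pseudo, ps)
      sets[[kk]] <- assign_spots(ps)
    }
    rownames(pseudo) <- paste0("FTU", seq_len(n_cl))
    ov <- overlap_objective(sets)
    grid_rows[[length(grid_rows) + 1]] <-
      tibble::tibble(resolution = res, n_clusters = n_cl, overlap = ov)
    if (is.null(best) || ov < best$overlap) {
      best <- list(resolution = res, gene_clusters = labels,
                   spot_sets = sets, overlap = ov, pseudo = pseudo)
    }
  }
  if (is.null(best)) {
    stop_input("no resolution produced >= 2 gene clusters; widen res_grid")
  }
  best$grid <- do.call(rbind, grid_rows)
  best$seed <- seed
  class(best) <- "ftu_result"
  best
}

#' @export
print.ftu_result <- function(x, ...) {
  cat(sprintf(
    "<ftu_result> %d FTUs at resolution %.2g (mean pairwise overlap %.3g)\n",
    length(x$spot_sets), x$resolution, x$overlap
  ))
  invisible(x)
}

#' Write FTU results as TSV tables
#'
#' Writes the gene-to-cluster map, the multi-label spot membership matrix
#' (one 0/1 column per FTU), and a one-line run summary.
#'
#' @param x An `ftu_result`.
#' @param dir Output directory (created if missing).
#' @param spot_ids Full spot universe (default: spots seen in the pseudo
#'   matrix).
#' @return `dir`, invisibly.
#' @export
write_ftu_tables <- function(x, dir, spot_ids = NULL) {
  stopifnot(inherits(x, "ftu_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(
    data.frame(gene = names(x$gene_clusters), cluster = x$gene_clusters),
    file.path(dir, "gene_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (is.null(spot_ids)) spot_ids <- colnames(x$pseudo)
  memb <- sapply(x$spot_sets, function(s) as.integer(spot_ids %in% s))
  colnames(memb) <- paste0("FTU", seq_along(x$spot_sets))
  write.table(
    data.frame(spot_id = spot_ids, memb),
    file.path(dir, "ftu_membership.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(
    c(sprintf("resolution\t%g", x$resolution),
      sprintf("overlap\t%g", x$overlap),
      sprintf("n_ftu\t%d", length(x$spot_sets))),
    file.path(dir, "ftu_summary.tsv")
  )
  invisible(dir)
}

#' Low-frequency coefficient matrix for a set of genes
#'
#' Convenience helper: transforms each gene and keeps the low-band
#' coefficients `2..(1 + n_low)` (the zero mode carries no spatial
#' information). Used as the clustering space for FTU detection.
#'
#' @param expr An `expression_matrix` (or gene-by-spot matrix).
#' @param basis A `spectral_basis`.
#' @param genes Optional subset of gene identifiers.
#' @param n_low Number of low-frequency modes (default: the basis band).
#' @return Gene-by-`n_low` numeric matrix.
#' @export
low_frequency_fcs <- function(expr, basis, genes = NULL, n_low = basis$n_low) {
  X <- expr_values(expr)
  if (!is.null(genes)) {
    idx <- match(genes, rownames(X))
    if (anyNA(idx)) stop_input("unknown gene(s) in subset")
    X <- X[idx, , drop = FALSE]
  }
  fc <- X %*% basis$modes
  fc[, seq(2L, 1L + n_low), drop = FALSE]
}
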