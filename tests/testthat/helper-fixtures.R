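# shared fixtures: tiny graphs and bases built in code

# path graph on n collinear equispaced spots (K forced to 1)
path_graph <- function(n = 3) {
  coords <- cbind(x = seq_len(n), y = rep(0, n))
  rownames(coords) <- paste0("s", seq_len(n))
  build_knn_graph(coords, ratio_neighbors = 1 / sqrt(n))
}

path_basis <- function(n = 3) {
  eigendecompose(laplacian(path_graph(n)))
}

grid_basis <- function(nx, ny = nx, ...) {
  eigendecompose(laplacian(build_knn_graph(make_grid(nx, ny))), ...)
}

# a spot_graph with no edges at all (cannot arise from KNN construction)
edgeless_graph <- function(n = 4) {
  coords <- cbind(seq_len(n), 0)
  structure(
    list(coords = coords, K = 0L, ratio_neighbors = NA_real_,
         adjacency = matrix(0L, n, n), degrees = rep(0L, n)),
    class = "spot_graph"
  )
}

jaccard_sets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
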