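#' Load a gene-by-spot expression matrix with spot coordinates
#'
#' Reads either a Matrix Market triplet file with `features.tsv` /
#' `barcodes.tsv` sidecars (10x-style, genes in rows) or a delimited
#' CSV/TSV with gene identifiers in the first column and spot identifiers in
#' the header. Spots are reordered to follow the coordinate table; spots
#' without coordinates are dropped with a warning.
#'
#' @param path Matrix file (`.mtx` or delimited text).
#' @param coords_path Coordinate table with columns `spot_id`, `x`, `y`
#'   (TSV or CSV, header required).
#' @param fmt `"mtx"` or `"delimited"`; the default guesses from the file
#'   extension.
#' @param transpose If `TRUE`, the delimited file is spot-major
#'   (spots in rows) and is transposed to the gene-by-spot canonical
#'   orientation after reading.
#' @return An object of class `raw_counts`: list with the integer-like
#'   `values` matrix (genes x spots), `gene_ids`, `spot_ids`, and the
#'   spot-by-2 `coords` matrix.
#' @export
load_expression <- function(path, coords_path,
                            fmt = c("auto", "mtx", "delimited"),
                            transpose = FALSE) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  }
  if (!file.exists(path)) stop_input(sprintf("matrix file not found: %s", path))
  if (!file.exists(coords_path)) {
    stop_input(sprintf("coordinates file not found: %s", coords_path))
  }

  if (fmt == "mtx") {
    dir <- dirname(path)
    feat_path <- file.path(dir, "features.tsv")
    if (!file.exists(feat_path)) feat_path <- file.path(dir, "genes.tsv")
    bc_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat_path) || !file.exists(bc_path)) {
      stop_input("mtx input requires features.tsv (or genes.tsv) and barcodes.tsv sidecars")
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      rlang::abort(sprintf("malformed Matrix Market file: %s", conditionMessage(e)),
                   class = "spectralsvg_format_error")
    })
    values <- as.matrix(m)
    gene_ids <- read.delim(feat_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    spot_ids <- read.delim(bc_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    if (transpose) {
      values <- t(values)
      tmp <- gene_ids; gene_ids <- spot_ids; spot_ids <- tmp
    }
    if (length(gene_ids) != nrow(values) || length(spot_ids) != ncol(values)) {
      rlang::abort("sidecar lengths do not match the matrix dimensions",
                   class = "spectralsvg_format_error")
    }
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    spot_ids <- colnames(values)
    if (transpose) {
      values <- t(values)
      tmp <- gene_ids; gene_ids <- spot_ids; spot_ids <- tmp
    }
  }

  if (anyDuplicated(gene_ids)) stop_input("duplicate gene identifiers in input")
  if (anyDuplicated(spot_ids)) stop_input("duplicate spot identifiers in input")

  sep2 <- if (grepl("\\.csv$", coords_path, ignore.case = TRUE)) "," else "\t"
  cdf <- read.delim(coords_path, sep = sep2, header = TRUE,
                    stringsAsFactors = FALSE)
  if (ncol(cdf) < 3) stop_input("coordinates table needs columns spot_id, x, y")
  names(cdf)[1:3] <- c("spot_id", "x", "y")

  keep <- intersect(cdf$spot_id, spot_ids)
  if (length(keep) == 0) stop_input("no spots shared between matrix and coordinates")
  if (length(keep) < length(spot_ids)) {
    warn(sprintf("%d spot(s) without coordinates dropped",
                 length(spot_ids) - length(keep)))
  }
  cdf <- cdf[match(keep, cdf$spot_id), ]
  values <- values[, match(keep, spot_ids), drop = FALSE]
  coords <- as.matrix(cdf[, c("x", "y")])
  rownames(coords) <- cdf$spot_id
  dimnames(values) <- list(gene_ids, cdf$spot_id)

  new_raw_counts(values, coords)
}

new_raw_counts <- function(values, coords) {
  if (any(values < 0)) stop_input("counts must be non-negative")
  structure(
    list(
      values = values,
      gene_ids = rownames(values),
      spot_ids = colnames(values),
      coords = coords
    ),
    class = "raw_counts"
  )
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("<raw_counts> %d genes x %d spots\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Assemble raw counts from in-memory objects
#'
#' @param values Gene-by-spot non-negative matrix (row/column names become
#'   gene and spot identifiers).
#' @param coords Spot-by-2 coordinate matrix aligned with the columns.
#' @return A `raw_counts` object.
#' @export
raw_counts <- function(values, coords) {
  values <- as.matrix(values)
  coords <- as.matrix(coords)
  if (ncol(values) != nrow(coords)) {
    stop_input("number of spots differs between values and coords")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- rownames(coords) %||% paste0("spot", seq_len(ncol(values)))
  }
  rownames(coords) <- colnames(values)
  new_raw_counts(values, coords)
}

#' Drop genes expressed in too few spots
#'
#' Keeps genes with a nonzero value in at least `min_spots` spots (default
#' 10), preserving gene order. Idempotent.
#'
#' @param rc A `raw_counts` object.
#' @param min_spots Minimum number of expressing spots (>= 0).
#' @return Filtered `raw_counts`.
#' @export
filter_genes <- function(rc, min_spots = 10) {
  stopifnot(inherits(rc, "raw_counts"))
  if (min_spots < 0) stop_input("min_spots must be >= 0")
  n_expr <- rowSums(rc$values > 0)
  keep <- n_expr >= min_spots
  if (!any(keep)) {
    stop_input(sprintf(
      "all genes removed: none expressed in at least %d spots", min_spots
    ), class = "spectralsvg_empty_result")
  }
  new_raw_counts(rc$values[keep, , drop = FALSE], rc$coords)
}

#' Counts-per-million normalisation with optional log transform
#'
#' Scales every spot to a common total (`scale`, default 1e6 = CPM) and then
#' applies the natural `log(1 + x)` transform. Spots whose total count is
#' zero carry no information and are dropped with a warning.
#'
#' @param rc A `raw_counts` object.
#' @param scale Per-spot target total (default 1e6).
#' @param log_transform Apply `log1p` after scaling (default `TRUE`).
#' @return An object of class `expression_matrix`: list with the normalised
#'   `values` (genes x spots), identifiers, `coords`, and a `normalized`
#'   flag.
#' @export
normalize_counts <- function(rc, scale = 1e6, log_transform = TRUE) {
  stopifnot(inherits(rc, "raw_counts"))
  totals <- colSums(rc$values)
  keep <- totals > 0
  if (!any(keep)) stop_input("every spot has zero total count")
  if (!all(keep)) {
    warn(sprintf("%d spot(s) with zero total count dropped", sum(!keep)))
  }
  v <- rc$values[, keep, drop = FALSE]
  v <- sweep(v, 2, totals[keep], "/") * scale
  if (log_transform) v <- log1p(v)
  structure(
    list(
      values = v,
      gene_ids = rownames(v),
      spot_ids = colnames(v),
      coords = rc$coords[keep, , drop = FALSE],
      normalized = TRUE,
      log_transformed = log_transform
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d spots%s\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$normalized)) " (normalised)" else ""))
  invisible(x)
}

# accept either an expression_matrix / raw_counts container or a bare matrix
expr_values <- function(expr) {
  if (inherits(expr, c("expression_matrix", "raw_counts"))) {
    expr$values
  } else {
    as.matrix(expr)
  }
}

#' Write a gene-by-spot matrix as delimited TSV
#'
#' Round-trips exactly with [load_expression()] (`fmt = "delimited"`).
#'
#' @param expr An `expression_matrix`, `raw_counts`, or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  v <- expr_values(expr)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write spot coordinates as a three-column TSV
#'
#' @param coords Spot-by-2 matrix with spot identifiers as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  df <- data.frame(spot_id = rownames(coords), x = coords[, 1], y = coords[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
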