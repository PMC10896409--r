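#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene SVG table
#'
#' @param x An `svg_result`.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene`, `gftscore`, `rank`,
#'   `pvalue`, `qvalue`, `is_svg`, `cutoff_score`.
#' @method tidy svg_result
#' @export
tidy.svg_result <- function(x, ...) {
  x$table
}

#' One-row summary of an SVG analysis
#'
#' @param x An `svg_result`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_svg`, `cutoff_score`, `n_low`,
#'   `n_high`, `sensitivity`, `alpha`.
#' @method glance svg_result
#' @export
glance.svg_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_svg = sum(x$table$is_svg),
    cutoff_score = x$cutoff_score,
    n_low = x$n_low,
    n_high = x$n_high,
    sensitivity = x$sensitivity,
    alpha = x$alpha
  )
}

#' Tidy the gene-to-FTU assignment
#'
#' @param x An `ftu_result`.
#' @param ... Unused.
#' @return Tibble with `gene` and `cluster`.
#' @method tidy ftu_result
#' @export
tidy.ftu_result <- function(x, ...) {
  tibble::tibble(gene = names(x$gene_clusters),
                 cluster = unname(x$gene_clusters))
}

#' One-row summary of an FTU analysis
#'
#' @param x An `ftu_result`.
#' @param ... Unused.
#' @return Tibble with `resolution`, `n_ftu`, `overlap`, `seed`.
#' @method glance ftu_result
#' @export
glance.ftu_result <- function(x, ...) {
  tibble::tibble(
    resolution = x$resolution,
    n_ftu = length(x$spot_sets),
    overlap = x$overlap,
    seed = x$seed
  )
}
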