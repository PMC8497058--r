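#' Per-cell mitochondrial fission metric
#'
#' The fission metric of a cell is its total mitochondria number divided
#' by its total mitochondrial length (units 1/um). A fully fragmented
#' network of many short components scores high; a single fused network
#' scores `1 / total length`.
#'
#' @param cell A [mito_cell()].
#' @return Numeric scalar, 1/um.
#' @examples
#' fission_metric(mito_cell("c", c(2, 2, 2, 2, 2)))  # 5 / 10 = 0.5
#' @export
fission_metric <- function(cell) {
  stopifnot(inherits(cell, "mito_cell"))
  length(cell$lengths) / sum(cell$lengths)
}

#' Per-cell mitochondrial fusion metric
#'
#' `fusion_k_metric()` is the percentage of a cell's total mitochondrial
#' length contained in its `k` longest components. `k = 5` gives the
#' fusion5 metric (100 = all mass in at most five networks, i.e. fully
#' fused at the 5-network level); `k = 1` gives fusion1, the share of the
#' single longest element. When the cell has fewer than `k` components
#' all of them are taken, so the metric is 100 exactly.
#'
#' Ties among equal lengths do not affect the top-`k` sum, so no
#' tie-breaking rule is needed.
#'
#' @param cell A [mito_cell()].
#' @param k Number of longest components to sum (integer >= 1).
#' @return Numeric scalar on the 0-100 percent scale.
#' @examples
#' fusion_k_metric(mito_cell("c", c(8, 1, 1)), k = 1)  # 80
#' @export
fusion_k_metric <- function(cell, k) {
  stopifnot(inherits(cell, "mito_cell"))
  if (length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  len <- cell$lengths
  k <- min(as.integer(k), length(len))
  top <- sort(len, decreasing = TRUE)[seq_len(k)]
  100 * sum(top) / sum(len)
}

#' Per-cell metric table
#'
#' Computes the full per-cell metric record for a set of cells: component
#' count, total length (um), `fission` (1/um), `fusion1` and `fusion5`
#' (percent). Output row order follows input order.
#'
#' @param cells A list of [mito_cell()] objects, or a long-format
#'   component table accepted by [as_mito_cells()].
#' @return A `data.frame` with columns `cell_id`, `population`,
#'   `archetype`, `n_components`, `total_length`, `fission`, `fusion1`,
#'   `fusion5`.
#' @examples
#' cells <- list(mito_cell("a", c(8, 1, 1)), mito_cell("b", 5))
#' metrics_table(cells)
#' @export
metrics_table <- function(cells) {
  if (is.data.frame(cells)) cells <- as_mito_cells(cells)
  cells <- check_cell_list(cells)
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    cell_id = ids,
    population = vapply(cells, `[[`, character(1), "population"),
    archetype = vapply(cells, `[[`, character(1), "archetype"),
    n_components = vapply(cells, function(c) length(c$lengths), integer(1)),
    total_length = vapply(cells, function(c) sum(c$lengths), numeric(1)),
    fission = vapply(cells, fission_metric, numeric(1)),
    fusion1 = vapply(cells, fusion_k_metric, numeric(1), k = 1),
    fusion5 = vapply(cells, fusion_k_metric, numeric(1), k = 5)
  )
}
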