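#' Construct a single-cell mitochondrial network record
#'
#' A `mito_cell` holds one cell's mitochondrial network as the multiset of
#' its component lengths (micrometres) - the summary level emitted by
#' skeletonization software from confocal z-stacks. Lengths must be
#' strictly positive and finite; cells with zero components are invalid.
#' Invalid lengths are rejected rather than dropped, because silent
#' filtering would shift every downstream metric distribution.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param lengths Numeric vector of component lengths in micrometres.
#' @param population Character scalar; the sample/population label.
#' @param archetype Optional character scalar recording which generating
#'   archetype produced a simulated cell (`NA` for real data).
#' @return An object of class `mito_cell`: a list with elements
#'   `cell_id`, `population`, `lengths`, `archetype`.
#' @examples
#' mito_cell("c1", c(8, 1, 1), population = "Parental")
#' @export
mito_cell <- function(cell_id, lengths, population = NA_character_,
                      archetype = NA_character_) {
  if (length(cell_id) != 1L || is.na(cell_id)) {
    stop("`cell_id` must be a single non-missing value", call. = FALSE)
  }
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L) {
    stop("a mito_cell needs at least one component", call. = FALSE)
  }
  if (anyNA(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("component lengths must be finite and > 0 (cell ", cell_id, ")",
         call. = FALSE)
  }
  structure(
    list(cell_id = as.character(cell_id),
         population = as.character(population),
         lengths = lengths,
         archetype = as.character(archetype)),
    class = "mito_cell"
  )
}

#' @export
print.mito_cell <- function(x, ...) {
  cat(sprintf("<mito_cell> %s (%s): %d component(s), total %.3f um\n",
              x$cell_id, x$population, length(x$lengths), sum(x$lengths)))
  invisible(x)
}

#' Convert a list of mito_cell objects to a long-format table
#'
#' One row per mitochondrial component, with columns `cell_id`,
#' `population`, `component_index`, `length_um` (the on-disk CSV schema).
#'
#' @param cells List of [mito_cell()] objects.
#' @return A `data.frame` in long format.
#' @seealso [as_mito_cells()] for the inverse, [read_mito_cells()]
#' @export
cells_to_table <- function(cells) {
  cells <- check_cell_list(cells)
  n <- vapply(cells, function(c) length(c$lengths), integer(1))
  data.frame(
    cell_id = rep(vapply(cells, `[[`, character(1), "cell_id"), n),
    population = rep(vapply(cells, `[[`, character(1), "population"), n),
    component_index = unlist(lapply(n, seq_len), use.names = FALSE),
    length_um = unlist(lapply(cells, `[[`, "lengths"), use.names = FALSE)
  )
}

#' Build mito_cell objects from a long-format component table
#'
#' @param df A `data.frame` with columns `cell_id`, `length_um` and
#'   optionally `population`. Rows are grouped by `cell_id`; input order
#'   of first appearance is preserved.
#' @return A list of [mito_cell()] objects.
#' @export
as_mito_cells <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("cell_id", "length_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"population" %in% names(df)) df$population <- NA_character_
  ids <- unique(as.character(df$cell_id))
  lapply(ids, function(id) {
    rows <- df[df$cell_id == id, , drop = FALSE]
    pop <- unique(as.character(rows$population))
    if (length(pop) > 1L) {
      stop("cell ", id, " appears under more than one population",
           call. = FALSE)
    }
    mito_cell(id, rows$length_um, population = pop)
  })
}

#' Read / write mitochondrial component tables
#'
#' CSV schema: `cell_id, population, component_index, length_um`.
#'
#' @param path Path to a CSV file.
#' @return `read_mito_cells()`: a list of [mito_cell()] objects.
#' @export
read_mito_cells <- function(path) {
  as_mito_cells(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_mito_cells
#' @param cells List of [mito_cell()] objects.
#' @return `write_mito_cells()`: the path, invisibly.
#' @export
write_mito_cells <- function(cells, path) {
  write.csv(cells_to_table(cells), path, row.names = FALSE)
  invisible(path)
}

check_cell_list <- function(cells) {
  if (inherits(cells, "mito_cell")) cells <- list(cells)
  if (!is.list(cells) || !length(cells) ||
      !all(vapply(cells, inherits, logical(1), "mito_cell"))) {
    stop("expected a list of mito_cell objects", call. = FALSE)
  }
  cells
}
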