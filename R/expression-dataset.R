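#' Construct an expression dataset
#'
#' Container for a genes x cells experiment: raw counts (sparse), an
#' optional log-normalized layer, and per-cell metadata. Gene symbols are
#' case-normalized to uppercase at construction since datasets from
#' different sources mix case conventions.
#'
#' @param counts non-negative integer matrix, genes x cells. Coerced to
#'   `dgCMatrix`. Must carry unique rownames (gene symbols) and unique
#'   colnames (cell barcodes).
#' @param cell_meta data.frame with one row per cell; must contain a
#'   `group_label` column. Rows are matched to `colnames(counts)` via a
#'   `cell_id` column (or rownames).
#' @param lognorm optional log-normalized layer of identical shape; zero
#'   exactly where `counts` is zero.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `counts`, `lognorm`, `cell_meta`.
#' @export
expression_dataset <- function(counts, cell_meta, lognorm = NULL) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_contract("counts must have rownames (genes) and colnames (cells)")
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop_contract("gene symbols must be unique; collapse duplicates first")
  if (anyDuplicated(colnames(counts)))
    stop_contract("cell barcodes must be unique")
  if (any(counts@x < 0)) stop_contract("counts must be non-negative")

  cell_meta <- as.data.frame(cell_meta)
  if (!is.null(cell_meta$cell_id)) rownames(cell_meta) <- cell_meta$cell_id
  if (!all(colnames(counts) %in% rownames(cell_meta)))
    stop_contract("cell_meta must cover every cell barcode")
  cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  cell_meta$cell_id <- colnames(counts)
  if (is.null(cell_meta$group_label))
    stop_contract("cell_meta must contain a group_label column")

  if (!is.null(lognorm)) {
    lognorm <- as_dgc(lognorm)
    rownames(lognorm) <- toupper(rownames(lognorm))
    if (!identical(dim(lognorm), dim(counts)))
      stop_contract("lognorm layer must match counts dimensions")
    dimnames(lognorm) <- dimnames(counts)
  }
  structure(list(counts = counts, lognorm = lognorm, cell_meta = cell_meta),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  lognorm layer: %s\n", if (is.null(x$lognorm)) "absent" else "present"))
  tab <- table(x$cell_meta$group_label)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Gene symbols of a dataset
#' @param dataset an `ExpressionDataset`.
#' @return character vector of gene symbols.
#' @export
gene_ids <- function(dataset) rownames(dataset$counts)

#' Cell barcodes of a dataset
#' @param dataset an `ExpressionDataset`.
#' @return character vector of cell barcodes.
#' @export
cell_ids <- function(dataset) colnames(dataset$counts)

#' Cells belonging to a group
#' @param dataset an `ExpressionDataset`.
#' @param group_label group label to look up.
#' @return character vector of cell ids (order of the dataset).
#' @export
group_cells <- function(dataset, group_label) {
  if (!group_label %in% dataset$cell_meta$group_label)
    stop_contract("unknown group '%s'", group_label)
  dataset$cell_meta$cell_id[dataset$cell_meta$group_label == group_label]
}

#' Subset a dataset by cells and/or genes
#' @param dataset an `ExpressionDataset`.
#' @param cells character vector of cell ids (default all).
#' @param genes character vector of gene symbols (default all).
#' @return an `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, cells = NULL, genes = NULL) {
  cells <- cells %||% cell_ids(dataset)
  genes <- genes %||% gene_ids(dataset)
  expression_dataset(dataset$counts[genes, cells, drop = FALSE],
                     dataset$cell_meta[cells, , drop = FALSE],
                     lognorm = if (!is.null(dataset$lognorm))
                       dataset$lognorm[genes, cells, drop = FALSE])
}
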