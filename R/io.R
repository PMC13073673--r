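#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx` plus `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`. The features file may have one column (symbol) or the
#' 10x three-column layout (id, symbol, type); the symbol column is used.
#' Duplicate gene symbols are collapsed by element-wise summation with a
#' warning, which conserves total counts per cell. An optional
#' `cell_meta.tsv` (columns `cell_id`, `group_label`, ...) supplies
#' metadata; otherwise all cells get `group_label = "all"`.
#'
#' @param directory_path directory holding the triplet files.
#' @return an [expression_dataset()] with counts populated and no lognorm
#'   layer.
#' @export
read_matrix_market <- function(directory_path) {
  if (!dir.exists(directory_path))
    stop_contract("input error: directory '%s' does not exist", directory_path)
  path_of <- function(cands) {
    for (f in cands) {
      p <- file.path(directory_path, f)
      if (file.exists(p)) return(p)
    }
    stop_contract("input error: none of [%s] found in '%s'",
                  paste(cands, collapse = ", "), directory_path)
  }
  mtx <- path_of("matrix.mtx")
  feats <- path_of(c("features.tsv", "genes.tsv"))
  bcs <- path_of("barcodes.tsv")

  counts <- as_dgc(Matrix::readMM(mtx))
  ftab <- utils::read.delim(feats, header = FALSE, stringsAsFactors = FALSE)
  symbols <- toupper(if (ncol(ftab) >= 2) ftab[[2]] else ftab[[1]])
  barcodes <- utils::read.delim(bcs, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (length(symbols) != nrow(counts))
    stop_contract("format error: %d features listed but matrix has %d rows",
                  length(symbols), nrow(counts))
  if (length(barcodes) != ncol(counts))
    stop_contract("format error: %d barcodes listed but matrix has %d columns",
                  length(barcodes), ncol(counts))

  if (anyDuplicated(symbols)) {
    dups <- unique(symbols[duplicated(symbols)])
    warning(sprintf("collapsing %d duplicated gene symbol(s) by summation: %s",
                    length(dups), paste(head(dups, 5), collapse = ", ")))
    fac <- factor(symbols, levels = unique(symbols))
    collapse <- Matrix::sparseMatrix(i = as.integer(fac),
                                     j = seq_along(symbols), x = 1,
                                     dims = c(nlevels(fac), length(symbols)))
    counts <- as_dgc(collapse %*% counts)
    symbols <- levels(fac)
  }
  dimnames(counts) <- list(symbols, barcodes)

  meta_path <- file.path(directory_path, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, header = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = barcodes, group_label = "all",
               stringsAsFactors = FALSE)
  }
  expression_dataset(counts, cell_meta)
}

#' Write a dataset as a 10x-style Matrix Market triplet directory
#'
#' Counterpart of [read_matrix_market()]; also writes `cell_meta.tsv` and,
#' when a truth table is attached to the dataset (synthetic data), a
#' `truth.tsv`.
#'
#' @param dataset an `ExpressionDataset`.
#' @param directory_path output directory (created if needed).
#' @return `directory_path`, invisibly.
#' @export
write_matrix_market <- function(dataset, directory_path) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$counts, file.path(directory_path, "matrix.mtx"))
  utils::write.table(data.frame(id = gene_ids(dataset),
                                symbol = gene_ids(dataset),
                                type = "Gene Expression"),
                     file.path(directory_path, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(dataset), file.path(directory_path, "barcodes.tsv"))
  utils::write.table(dataset$cell_meta,
                     file.path(directory_path, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory_path)
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited lines: set name, description, then member genes. Gene
#' symbols are uppercased; empty lines are skipped; set names must be
#' unique.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_contract("input error: '%s' not found", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_contract("format error at line %d: GMT lines need name, description and >= 1 gene", i)
    nm <- fields[1]
    if (nm %in% names(sets))
      stop_contract("format error: duplicated set name '%s'", nm)
    genes <- toupper(fields[-(1:2)])
    sets[[nm]] <- genes[nzchar(genes)]
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled; default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], toupper(sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-cell scores and labels to TSV
#'
#' @param cell_ids character vector of cell barcodes.
#' @param scores numeric scores (serialized with 8 significant digits).
#' @param labels character labels (e.g. "senescent"/"normal").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(cell_ids, scores, labels, path) {
  if (length(cell_ids) != length(scores) || length(scores) != length(labels))
    stop_contract("cell_ids, scores and labels must have equal lengths")
  df <- data.frame(cell_id = cell_ids,
                   sasp_score = sprintf("%.8g", scores),
                   label = labels, stringsAsFactors = FALSE)
  if (length(cell_ids) == 0)
    df <- data.frame(cell_id = character(), sasp_score = character(),
                     label = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scores TSV written by [write_scores_tsv()]
#' @param path file path.
#' @return data.frame with columns `cell_id`, `sasp_score` (numeric), `label`.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character"))
  df
}
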