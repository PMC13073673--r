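#' Log-normalize counts
#'
#' Standard single-cell log normalization:
#' `lognorm[g, c] = ln(1 + counts[g, c] * scale_factor / total_counts[c])`.
#' Cells with zero total count are dropped with a warning.
#'
#' @param dataset an `ExpressionDataset` with counts.
#' @param scale_factor library-size scale; default 1e4.
#' @return the dataset with a `lognorm` layer added.
#' @export
lognormalize <- function(dataset, scale_factor = 1e4) {
  totals <- Matrix::colSums(dataset$counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping %d cell(s) with zero total count", sum(totals == 0)))
    keep <- cell_ids(dataset)[totals > 0]
    dataset <- subset_dataset(dataset, cells = keep)
    totals <- totals[totals > 0]
  }
  scaled <- dataset$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  dataset$lognorm <- as_dgc(log1p(scaled))
  dimnames(dataset$lognorm) <- dimnames(dataset$counts)
  dataset
}

#' Per-gene reference statistics over control cells
#'
#' Mean and standard deviation (denominator n - 1) of the log-normalized
#' expression of every gene across the designated control cells. These
#' statistics are frozen into the ensemble model and reused verbatim when
#' scoring new data, so z-scores of tissue cells are always relative to the
#' proliferating reference population.
#'
#' @param dataset an `ExpressionDataset` with a lognorm layer.
#' @param control_cell_ids barcodes of the control (reference) cells; >= 2.
#' @return an object of class `ReferenceStats`: list with `gene_ids`,
#'   `mean`, `sd`, `n_control_cells`.
#' @export
compute_reference_stats <- function(dataset, control_cell_ids) {
  if (is.null(dataset$lognorm))
    stop_contract("lognormalize() the dataset before computing reference stats")
  if (length(control_cell_ids) < 2)
    stop_contract("need >= 2 control cells (got %d)", length(control_cell_ids))
  if (!all(control_cell_ids %in% cell_ids(dataset)))
    stop_contract("unknown control cell ids")
  x <- dataset$lognorm[, control_cell_ids, drop = FALSE]
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  ss <- Matrix::rowSums(x^2)
  v <- pmax(0, (ss - n * mu^2) / (n - 1))
  structure(list(gene_ids = gene_ids(dataset),
                 mean = as.numeric(mu),
                 sd = sqrt(as.numeric(v)),
                 n_control_cells = n),
            class = "ReferenceStats")
}

#' @export
print.ReferenceStats <- function(x, ...) {
  cat(sprintf("ReferenceStats: %d genes over %d control cells (%d with sd > 0)\n",
              length(x$gene_ids), x$n_control_cells, sum(x$sd > 0)))
  invisible(x)
}

#' Gene-wise z-score matrix against a stored reference
#'
#' `z[g, c] = (lognorm[g, c] - mean[g]) / sd[g]`. Genes whose reference sd
#' is zero get z = 0 for all cells and are flagged unusable as driver genes
#' (attribute `usable`, a named logical vector).
#'
#' @param dataset an `ExpressionDataset` with a lognorm layer.
#' @param ref_stats a `ReferenceStats` object.
#' @param genes genes to compute (default: all genes shared between the
#'   dataset and the reference).
#' @return dense numeric matrix, genes x cells, with attribute `usable`.
#' @export
zscore_matrix <- function(dataset, ref_stats, genes = NULL) {
  if (is.null(dataset$lognorm))
    stop_contract("lognormalize() the dataset before z-scoring")
  genes <- genes %||% intersect(gene_ids(dataset), ref_stats$gene_ids)
  missing_ref <- setdiff(genes, ref_stats$gene_ids)
  if (length(missing_ref))
    stop_contract("gene(s) absent from reference stats: %s",
                  paste(head(missing_ref, 5), collapse = ", "))
  missing_ds <- setdiff(genes, gene_ids(dataset))
  if (length(missing_ds))
    stop_contract("gene(s) absent from dataset: %s",
                  paste(head(missing_ds, 5), collapse = ", "))
  idx <- match(genes, ref_stats$gene_ids)
  mu <- ref_stats$mean[idx]
  sdv <- ref_stats$sd[idx]
  x <- as.matrix(dataset$lognorm[genes, , drop = FALSE])
  usable <- sdv > 0
  denom <- ifelse(usable, sdv, 1)
  z <- (x - mu) / denom
  z[!usable, ] <- 0
  attr(z, "usable") <- setNames(usable, genes)
  z
}

# mean lognorm of `genes` minus mean lognorm of bin-matched sampled control
# genes, per cell; shared by module_score() and proliferation_score().
# Must be called inside with_seed(). Genes and bin pools are iterated in
# sorted order so the result is invariant to gene order in the dataset.
binned_control_score <- function(dataset, genes, n_bins, n_ctrl_per_gene) {
  all_genes <- gene_ids(dataset)
  genes <- sort(intersect(genes, all_genes))
  if (length(genes) == 0) stop_contract("no signature gene present in dataset")
  avg <- Matrix::rowMeans(dataset$lognorm)
  ord <- order(avg, all_genes)             # canonical: by expression, then name
  bins <- integer(length(all_genes))
  bins[ord] <- as.integer(cut(seq_along(ord), breaks = min(n_bins, length(ord))))
  names(bins) <- all_genes
  ctrl <- unlist(lapply(genes, function(g) {
    pool <- sort(all_genes[bins == bins[g]])
    sample(pool, n_ctrl_per_gene, replace = length(pool) < n_ctrl_per_gene)
  }), use.names = FALSE)
  sig_score <- Matrix::colMeans(dataset$lognorm[genes, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(dataset$lognorm[ctrl, , drop = FALSE])
  as.numeric(sig_score - ctrl_score)
}

#' Cell-cycle proliferation score
#'
#' For each of the S and G2/M phases, the phase score of a cell is the mean
#' log-normalized expression of the phase genes minus the mean of
#' expression-bin-matched randomly sampled control genes (equal-frequency
#' bins over per-gene mean expression, `n_ctrl_per_gene` draws per
#' signature gene, fixed seed). The proliferation score is the larger of
#' the two phase scores; a cell is called proliferative iff its score is
#' strictly positive. Senescent cells, being G1-arrested, express neither
#' program and score at or below zero.
#'
#' @param dataset an `ExpressionDataset` with a lognorm layer.
#' @param s_genes S-phase signature genes.
#' @param g2m_genes G2/M signature genes.
#' @param n_bins expression bins; default 24.
#' @param n_ctrl_per_gene control genes sampled per signature gene; default 100.
#' @param rng_seed seed for control-gene sampling; default 1.
#' @return a data.frame of class `ProliferationResult` with columns
#'   `cell_id`, `s_score`, `g2m_score`, `score`, `is_proliferative`.
#' @export
proliferation_score <- function(dataset, s_genes, g2m_genes,
                                n_bins = 24L, n_ctrl_per_gene = 100L,
                                rng_seed = 1L) {
  if (is.null(dataset$lognorm))
    stop_contract("lognormalize() the dataset before proliferation scoring")
  if (!length(intersect(s_genes, gene_ids(dataset))))
    stop_contract("no S-phase gene present in dataset")
  if (!length(intersect(g2m_genes, gene_ids(dataset))))
    stop_contract("no G2/M gene present in dataset")
  res <- with_seed(rng_seed, {
    s <- binned_control_score(dataset, toupper(s_genes), n_bins, n_ctrl_per_gene)
    g <- binned_control_score(dataset, toupper(g2m_genes), n_bins, n_ctrl_per_gene)
    list(s = s, g = g)
  })
  score <- pmax(res$s, res$g)
  structure(data.frame(cell_id = cell_ids(dataset),
                       s_score = res$s, g2m_score = res$g, score = score,
                       is_proliferative = score > 0,
                       stringsAsFactors = FALSE),
            class = c("ProliferationResult", "data.frame"))
}

#' Split a group into proliferative / non-proliferative sublists
#'
#' Partitions the cells of one group label by the proliferation call,
#' mirroring the PDL subgrouping convention (suffix "p" for proliferative
#' cells, "np" for arrested cells).
#'
#' @param dataset an `ExpressionDataset`.
#' @param group_label the group to split.
#' @param prolif a `ProliferationResult` covering the group's cells.
#' @return list with elements `p` and `np`, character vectors of cell ids
#'   (either may be empty).
#' @export
split_group <- function(dataset, group_label, prolif) {
  cells <- group_cells(dataset, group_label)
  idx <- match(cells, prolif$cell_id)
  if (anyNA(idx))
    stop_contract("proliferation result does not cover all cells of group '%s'",
                  group_label)
  flag <- prolif$is_proliferative[idx]
  list(p = cells[flag], np = cells[!flag])
}
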