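#' Score of one cell against one gene-set pair
#'
#' Mean z-score over the pair's up genes minus mean z-score over its down
#' genes, using only the genes present in the z matrix. A side with no
#' present genes contributes 0; if both sides are entirely absent the score
#' is undefined (`NA`). The fraction of the pair's genes present is
#' attached as attribute `coverage`.
#'
#' @param z_column named numeric vector: one cell's z-scores.
#' @param pair a `GeneSetPair`.
#' @return numeric score (or `NA` if no pair gene is present).
#' @export
pair_score <- function(z_column, pair) {
  up <- intersect(pair$up_genes, names(z_column))
  down <- intersect(pair$down_genes, names(z_column))
  n_total <- length(pair$up_genes) + length(pair$down_genes)
  coverage <- (length(up) + length(down)) / n_total
  if (length(up) + length(down) == 0) {
    out <- NA_real_
  } else {
    out <- (if (length(up)) mean(z_column[up]) else 0) -
      (if (length(down)) mean(z_column[down]) else 0)
  }
  attr(out, "coverage") <- coverage
  out
}

#' Signed-absolute-extremum aggregation of per-pair scores
#'
#' Returns the element of maximal absolute value with its sign preserved:
#' if the absolute maximum is attained by a positive score, the largest
#' positive score; otherwise the most negative score. On an exact tie in
#' absolute value between a positive and a negative element the positive
#' one is returned.
#'
#' @param per_pair_scores nonempty numeric vector (NAs ignored).
#' @return one element of the vector.
#' @export
#' @examples
#' aggregate_scores(c(1.0, -2.5, 2.0))  # -2.5
aggregate_scores <- function(per_pair_scores) {
  v <- per_pair_scores[!is.na(per_pair_scores)]
  if (length(v) == 0) stop_contract("cannot aggregate an empty score vector")
  m <- max(abs(v))
  max(v[abs(v) == m])
}

#' Score every cell of a dataset with an ensemble model
#'
#' Z-scores are computed with the model's stored reference statistics
#' (never recomputed from the scored data), each pair is scored as mean-z
#' up minus mean-z down over its genes present in the dataset, and the
#' per-cell ensemble score is the signed absolute extremum over pairs.
#' Pairs whose gene coverage in this dataset falls below
#' `params$coverage_min` are excluded.
#'
#' @param dataset an `ExpressionDataset`; log-normalized automatically if
#'   needed.
#' @param model an `EnsembleModel`.
#' @return an object of class `egs_scores`: data.frame with columns
#'   `cell_id`, `egs_score`, `argmax_pair`, `n_pairs_used`, carrying the
#'   per-pair score matrix (pairs x cells) as attribute `per_pair`.
#' @export
score_cells <- function(dataset, model) {
  if (is.null(dataset$lognorm))
    dataset <- lognormalize(dataset, model$params$scale_factor)
  pair_genes <- unique(unlist(lapply(model$pairs, function(p)
    c(p$up_genes, p$down_genes))))
  present <- intersect(pair_genes, gene_ids(dataset))
  present <- intersect(present, model$ref_stats$gene_ids)
  if (length(present) == 0)
    stop_contract("no ensemble gene present in dataset")
  z <- zscore_matrix(dataset, model$ref_stats, genes = present)

  labels <- vapply(model$pairs, pair_label, character(1))
  nc <- ncol(z)
  per_pair <- matrix(NA_real_, nrow = length(model$pairs), ncol = nc,
                     dimnames = list(labels, colnames(z)))
  kept <- logical(length(model$pairs))
  for (i in seq_along(model$pairs)) {
    p <- model$pairs[[i]]
    up <- intersect(p$up_genes, present)
    down <- intersect(p$down_genes, present)
    coverage <- (length(up) + length(down)) /
      (length(p$up_genes) + length(p$down_genes))
    if (coverage < model$params$coverage_min || coverage == 0) next
    kept[i] <- TRUE
    up_part <- if (length(up)) Matrix::colMeans(z[up, , drop = FALSE]) else 0
    down_part <- if (length(down)) Matrix::colMeans(z[down, , drop = FALSE]) else 0
    per_pair[i, ] <- up_part - down_part
  }
  if (!any(kept))
    stop_contract("all pairs excluded: gene coverage below %g",
                  model$params$coverage_min)
  if (any(!kept))
    message(sprintf("%d of %d pairs excluded for coverage < %g",
                    sum(!kept), length(kept), model$params$coverage_min))

  sub <- per_pair[kept, , drop = FALSE]
  egs <- apply(sub, 2, aggregate_scores)
  arg <- rownames(sub)[apply(sub, 2, function(v) {
    m <- max(abs(v))
    which(v == max(v[abs(v) == m]))[1]
  })]
  out <- data.frame(cell_id = colnames(z), egs_score = as.numeric(egs),
                    argmax_pair = arg, n_pairs_used = sum(kept),
                    stringsAsFactors = FALSE)
  attr(out, "per_pair") <- per_pair
  class(out) <- c("egs_scores", "data.frame")
  out
}

#' Bin-matched module score of a gene set
#'
#' Mean log-normalized expression of the set genes minus the mean of
#' expression-bin-matched randomly sampled control genes (the same binning
#' scheme as [proliferation_score()]); seeded and deterministic. This is
#' the conventional single-signature module score used as a baseline for
#' the ensemble score.
#'
#' @param dataset an `ExpressionDataset` with a lognorm layer.
#' @param gene_set character vector of gene symbols (>= 1 present).
#' @param n_bins expression bins; default 24.
#' @param n_ctrl_per_gene control genes per signature gene; default 100.
#' @param rng_seed seed; default 1.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(dataset, gene_set, n_bins = 24L,
                         n_ctrl_per_gene = 100L, rng_seed = 1L) {
  if (is.null(dataset$lognorm))
    stop_contract("lognormalize() the dataset before module scoring")
  s <- with_seed(rng_seed,
                 binned_control_score(dataset, toupper(gene_set),
                                      n_bins, n_ctrl_per_gene))
  setNames(s, cell_ids(dataset))
}
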