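#' Score a new tissue with a trained ensemble model
#'
#' Z-scores are computed against the model's stored reference statistics
#' and the signed-extremum ensemble score is evaluated exactly as at
#' training time, so scoring the training data reproduces the training
#' scores. Requires at least `coverage_floor` of the model's pair genes to
#' be present in the tissue panel; per-pair coverage below
#' `params$coverage_min` drops the pair with a message.
#'
#' @param tissue_dataset an `ExpressionDataset` (log-normalized
#'   automatically).
#' @param model an `EnsembleModel`.
#' @param coverage_floor minimum fraction of model genes that must be
#'   present; default 0.3.
#' @return an `egs_scores` data.frame (see [score_cells()]).
#' @export
transfer_scores <- function(tissue_dataset, model, coverage_floor = 0.3) {
  model_genes <- unique(unlist(lapply(model$pairs, function(p)
    c(p$up_genes, p$down_genes))))
  coverage <- mean(model_genes %in% gene_ids(tissue_dataset))
  if (coverage < coverage_floor)
    stop_contract("only %.1f%% of model genes present in tissue (floor %.0f%%)",
                  100 * coverage, 100 * coverage_floor)
  if (coverage < 1)
    message(sprintf("tissue panel covers %.1f%% of model genes", 100 * coverage))
  score_cells(tissue_dataset, model)
}

#' Derive tissue-specific senescence markers from confident extremes
#'
#' Wilcoxon DE of the confident senescent stratum against the confident
#' normal stratum, keeping only genes whose raw counts are nonzero in at
#' least `min_expr_frac` of the cells of at least one of the two strata
#' (robustly expressed biomarkers).
#'
#' @param tissue_dataset an `ExpressionDataset` with lognorm.
#' @param selection a `ConfidentSelection`.
#' @param logfc_threshold minimum |log2 fold change|; default 0.25.
#' @param min_expr_frac expression-fraction filter; default 0.9.
#' @param adj_p_max Bonferroni-adjusted p cutoff; default 0.05.
#' @return list with `tissue_up` and `tissue_down` character vectors.
#' @export
derive_tissue_markers <- function(tissue_dataset, selection,
                                  logfc_threshold = 0.25,
                                  min_expr_frac = 0.9,
                                  adj_p_max = 0.05) {
  high <- selection$high_cells
  low <- selection$low_cells
  frac_high <- Matrix::rowMeans(tissue_dataset$counts[, high, drop = FALSE] > 0)
  frac_low <- Matrix::rowMeans(tissue_dataset$counts[, low, drop = FALSE] > 0)
  expressed <- gene_ids(tissue_dataset)[pmax(frac_high, frac_low) >= min_expr_frac]
  if (length(expressed) == 0)
    stop_contract("no gene passes the %.0f%% expression filter", 100 * min_expr_frac)
  de <- wilcoxon_de(tissue_dataset, high, low,
                    logfc_threshold = logfc_threshold,
                    adj_p_max = adj_p_max, genes = expressed)
  up <- de$gene[de$direction == "up"]
  down <- de$gene[de$direction == "down"]
  if (length(up) + length(down) == 0)
    stop_contract("no tissue marker found; try a smaller logfc_threshold")
  list(tissue_up = up, tissue_down = down)
}

#' Tissue-internal gene-set score
#'
#' Z-scores computed within the tissue dataset itself (per-gene mean/sd
#' over all tissue cells, denominator n - 1, zero-sd genes contribute 0),
#' then mean z over the up set minus mean z over the down set per cell.
#' Used for the re-derived tissue marker sets, whose reference population
#' is the tissue, not the training cell line.
#'
#' @param tissue_dataset an `ExpressionDataset` with lognorm.
#' @param tissue_up,tissue_down marker gene sets (at least one nonempty).
#' @return named numeric vector of per-cell scores.
#' @export
tissue_set_score <- function(tissue_dataset, tissue_up, tissue_down) {
  if (length(tissue_up) + length(tissue_down) == 0)
    stop_contract("both marker sets empty")
  ref <- compute_reference_stats(tissue_dataset, cell_ids(tissue_dataset))
  genes <- intersect(unique(c(tissue_up, tissue_down)), gene_ids(tissue_dataset))
  z <- zscore_matrix(tissue_dataset, ref, genes = genes)
  up <- intersect(tissue_up, rownames(z))
  down <- intersect(tissue_down, rownames(z))
  up_part <- if (length(up)) colMeans(z[up, , drop = FALSE]) else 0
  down_part <- if (length(down)) colMeans(z[down, , drop = FALSE]) else 0
  out <- up_part - down_part
  if (length(out) == 1 && ncol(z) > 1) out <- rep(out, ncol(z))
  setNames(as.numeric(out), colnames(z))
}

#' Optimize the tissue-transfer parameters and classify a tissue
#'
#' For every combination of `n` (confident cells per stratum) and
#' `logfc_threshold` in the grids: select confident extremes by transfer
#' score with p21/p16 gating, derive tissue markers, score all cells with
#' the tissue-internal set score, and measure the separation between the
#' two selected strata as the pooled-SD standardized mean difference
#' `(mu_high - mu_low) / sqrt((sd_high^2 + sd_low^2) / 2)`. The winning
#' configuration (ties: larger n, then smaller logfc) supplies the
#' midpoint threshold `(mu_low + mu_high) / 2`, and every tissue cell is
#' classified by tissue score > midpoint.
#'
#' @param tissue_dataset an `ExpressionDataset` (log-normalized
#'   automatically with the model's scale factor).
#' @param model an `EnsembleModel`.
#' @param n_grid candidate stratum sizes; default c(50, 100, 150, 200).
#' @param logfc_grid candidate log-fold-change thresholds; default
#'   c(0.25, 0.5, 1).
#' @param min_expr_frac expression filter for marker derivation; default 0.9.
#' @return an object of class `TransferResult`: list with `tissue_scores`
#'   (EGS transfer scores), `selection`, `tissue_up`, `tissue_down`,
#'   `opt_n`, `opt_logfc`, `separation`, `midpoint_threshold`, `labels`,
#'   `set_scores`, and the full `grid` of configurations tried.
#' @export
optimize_transfer <- function(tissue_dataset, model,
                              n_grid = c(50L, 100L, 150L, 200L),
                              logfc_grid = c(0.25, 0.5, 1),
                              min_expr_frac = 0.9) {
  if (length(n_grid) == 0 || length(logfc_grid) == 0)
    stop_contract("parameter grids must be nonempty")
  if (is.null(tissue_dataset$lognorm))
    tissue_dataset <- lognormalize(tissue_dataset, model$params$scale_factor)
  scores <- transfer_scores(tissue_dataset, model)
  svec <- setNames(scores$egs_score, scores$cell_id)

  p21 <- as.numeric(tissue_dataset$counts["CDKN1A", scores$cell_id])
  p16 <- as.numeric(tissue_dataset$counts["CDKN2A", scores$cell_id])
  n_neg <- sum(p21 == 0 & p16 == 0)
  n_pos <- sum(p21 > 0 | p16 > 0)
  feasible <- n_grid[n_grid <= min(n_neg, n_pos)]
  if (length(feasible) < length(n_grid))
    warning(sprintf("dropping infeasible n values > %d (strata: %d negative, %d positive)",
                    min(n_neg, n_pos), n_neg, n_pos))
  if (length(feasible) == 0)
    stop_contract("no n in n_grid feasible (strata: %d negative, %d positive)",
                  n_neg, n_pos)

  grid <- expand.grid(n = feasible, logfc = logfc_grid)
  grid$separation <- NA_real_
  configs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- tryCatch({
      sel <- select_confident(svec, p21, p16, grid$n[i],
                              cell_ids = scores$cell_id)
      mk <- derive_tissue_markers(tissue_dataset, sel,
                                  logfc_threshold = grid$logfc[i],
                                  min_expr_frac = min_expr_frac)
      ts <- tissue_set_score(tissue_dataset, mk$tissue_up, mk$tissue_down)
      mu_h <- mean(ts[sel$high_cells]); sd_h <- sd(ts[sel$high_cells])
      mu_l <- mean(ts[sel$low_cells]);  sd_l <- sd(ts[sel$low_cells])
      sep <- (mu_h - mu_l) / sqrt((sd_h^2 + sd_l^2) / 2)
      list(sel = sel, mk = mk, ts = ts, mu_h = mu_h, mu_l = mu_l, sep = sep)
    }, error = function(e) {
      message(sprintf("config n=%d logfc=%.2g failed: %s",
                      grid$n[i], grid$logfc[i], conditionMessage(e)))
      NULL
    })
    configs[[i]] <- cfg
    if (!is.null(cfg)) grid$separation[i] <- cfg$sep
  }
  if (all(is.na(grid$separation)))
    stop_contract("every (n, logfc) configuration failed")

  ord <- order(-grid$separation, -grid$n, grid$logfc)
  best_i <- ord[1]
  best <- configs[[best_i]]
  midpoint <- (best$mu_l + best$mu_h) / 2
  labels <- classify_cells(best$ts, midpoint)
  names(labels) <- names(best$ts)

  structure(list(tissue_scores = scores,
                 selection = best$sel,
                 tissue_up = best$mk$tissue_up,
                 tissue_down = best$mk$tissue_down,
                 opt_n = as.integer(grid$n[best_i]),
                 opt_logfc = grid$logfc[best_i],
                 separation = grid$separation[best_i],
                 midpoint_threshold = midpoint,
                 labels = labels,
                 set_scores = best$ts,
                 grid = grid),
            class = "TransferResult")
}

#' @export
print.TransferResult <- function(x, ...) {
  cat(sprintf("TransferResult: n=%d, logfc=%.2g, separation %.3g, midpoint %.4g\n",
              x$opt_n, x$opt_logfc, x$separation, x$midpoint_threshold))
  cat(sprintf("  markers: %d up / %d down; %d/%d cells called senescent\n",
              length(x$tissue_up), length(x$tissue_down),
              sum(x$labels == "senescent"), length(x$labels)))
  invisible(x)
}

#' Audit predicted senescent cells against proliferation status
#'
#' Senescent cells are cell-cycle arrested, so a correct prediction should
#' contain (near) zero proliferative cells. Reports the count of
#' proliferative cells among the predicted-senescent set and among the
#' top-1% highest-scoring cells, where the top-1% size follows the
#' round-half-up convention of [top_pct_size()] (119 cells in an
#' 11,889-cell cohort).
#'
#' @param scores per-cell scores (named numeric vector or `egs_scores`).
#' @param labels per-cell classification aligned with `scores`.
#' @param prolif a `ProliferationResult` covering the cells.
#' @param top_frac fraction for the top selection; default 0.01.
#' @return list with `n_predicted_senescent`,
#'   `n_proliferative_in_predicted`, `top_size`,
#'   `n_proliferative_in_top`.
#' @export
audit_proliferation <- function(scores, labels, prolif, top_frac = 0.01) {
  if (inherits(scores, "egs_scores") || is.data.frame(scores))
    scores <- setNames(scores$egs_score, scores$cell_id)
  ids <- names(scores)
  if (is.null(ids)) stop_contract("scores must be named by cell id")
  idx <- match(ids, prolif$cell_id)
  if (anyNA(idx)) stop_contract("proliferation result does not cover all cells")
  is_prolif <- prolif$is_proliferative[idx]
  sen <- labels == "senescent"
  k <- top_pct_size(length(scores), top_frac)
  top <- order(-scores, seq_along(scores))[seq_len(k)]
  list(n_predicted_senescent = sum(sen),
       n_proliferative_in_predicted = sum(is_prolif & sen),
       top_size = k,
       n_proliferative_in_top = sum(is_prolif[top]))
}
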