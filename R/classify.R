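#' Fit a two-Gaussian decision threshold
#'
#' Fits a normal distribution to the control and to the senescent score
#' samples by moment estimates, then picks the threshold minimizing the
#' expected number of misclassifications
#' `FP(t) + FN(t) = w_ctrl * (1 - Phi_ctrl(t)) + w_sen * Phi_sen(t)`
#' over a 2001-point grid spanning `[mu_ctrl - 3 sd_ctrl, mu_sen + 3 sd_sen]`.
#' With `weighting = "counts"` (default) the weights are the observed
#' sample sizes, reading "sum of false positives and false negatives"
#' literally; `"equal"` uses equal priors. Ties are broken toward the
#' larger threshold, and the result is clamped to `[mu_ctrl, mu_sen]`.
#'
#' @param scores_ctrl numeric scores of control cells (>= 2, positive
#'   variance).
#' @param scores_sen numeric scores of senescent cells (>= 2, positive
#'   variance, larger mean than the controls).
#' @param weighting `"counts"` or `"equal"`.
#' @param n_grid grid resolution; default 2001.
#' @return an object of class `ClassifierFit`: list with `mu_ctrl`,
#'   `sd_ctrl`, `n_ctrl`, `mu_sen`, `sd_sen`, `n_sen`, `threshold`.
#' @export
fit_gaussian_threshold <- function(scores_ctrl, scores_sen,
                                   weighting = c("counts", "equal"),
                                   n_grid = 2001L) {
  weighting <- match.arg(weighting)
  if (length(scores_ctrl) < 2 || length(scores_sen) < 2)
    stop_contract("both score samples need >= 2 values")
  mu_c <- mean(scores_ctrl); sd_c <- sd(scores_ctrl)
  mu_s <- mean(scores_sen);  sd_s <- sd(scores_sen)
  if (!(sd_c > 0) || !(sd_s > 0))
    stop_contract("both score samples need positive variance")
  if (!(mu_s > mu_c))
    stop_contract("mean senescent score (%.3g) must exceed mean control score (%.3g); labels likely swapped",
                  mu_s, mu_c)
  w_c <- if (weighting == "counts") length(scores_ctrl) else 1
  w_s <- if (weighting == "counts") length(scores_sen) else 1
  grid <- seq(mu_c - 3 * sd_c, mu_s + 3 * sd_s, length.out = n_grid)
  obj <- w_c * (1 - pnorm(grid, mu_c, sd_c)) + w_s * pnorm(grid, mu_s, sd_s)
  best <- max(which(obj == min(obj)))          # ties toward larger t
  thr <- min(max(grid[best], mu_c), mu_s)      # clamp into [mu_ctrl, mu_sen]
  structure(list(mu_ctrl = mu_c, sd_ctrl = sd_c, n_ctrl = length(scores_ctrl),
                 mu_sen = mu_s, sd_sen = sd_s, n_sen = length(scores_sen),
                 threshold = thr, weighting = weighting),
            class = "ClassifierFit")
}

#' @export
print.ClassifierFit <- function(x, ...) {
  cat(sprintf("ClassifierFit: ctrl N(%.3g, %.3g^2) n=%d | sen N(%.3g, %.3g^2) n=%d | threshold %.4g\n",
              x$mu_ctrl, x$sd_ctrl, x$n_ctrl, x$mu_sen, x$sd_sen, x$n_sen,
              x$threshold))
  invisible(x)
}

#' Serialize / read a classifier fit
#' @param fit a `ClassifierFit`.
#' @param path JSON file path.
#' @return `path` (write) or a `ClassifierFit` (read).
#' @export
write_classifier_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier_fit
#' @export
read_classifier_fit <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ClassifierFit")
}

#' Classify cells by a score threshold
#'
#' A cell is senescent iff its score strictly exceeds the threshold
#' (a score exactly at the threshold is normal).
#'
#' @param scores numeric scores.
#' @param threshold decision boundary (a `ClassifierFit` or a number).
#' @return character vector, `"senescent"` or `"normal"`.
#' @export
classify_cells <- function(scores, threshold) {
  if (inherits(threshold, "ClassifierFit")) threshold <- threshold$threshold
  ifelse(scores > threshold, "senescent", "normal")
}

#' Stratified k-fold cross-validation of the ensemble classifier
#'
#' Cells are split into `params$k_folds` folds, stratified by group label
#' under `params$rng_seed`. Per fold, the ensemble (including its reference
#' statistics) is rebuilt from training cells only, the Gaussian threshold
#' is fitted on training scores, and the held-out cells are scored and
#' classified. Reported per fold: overall accuracy against group-derived
#' labels (control group = normal, every other group = senescent) and the
#' accuracy restricted to the `params$n_confident` lowest- and
#' highest-scoring test cells. A fold whose training data cannot support
#' the ensemble or the threshold fit is reported as degenerate rather than
#' silently skipped.
#'
#' @param dataset an `ExpressionDataset` (log-normalized automatically).
#' @param genes_of_interest candidate driver genes.
#' @param control_group control group label.
#' @param params an [egs_params()] object.
#' @return data.frame of class `egs_cv` with one row per fold: `fold`,
#'   `n_test`, `accuracy`, `extremes_accuracy`, `threshold`, `n_pairs`,
#'   `degenerate`.
#' @export
kfold_cv <- function(dataset, genes_of_interest, control_group,
                     params = egs_params()) {
  if (params$k_folds < 2) stop_contract("k_folds must be >= 2")
  if (is.null(dataset$lognorm))
    dataset <- lognormalize(dataset, params$scale_factor)
  meta <- dataset$cell_meta
  groups <- setdiff(unique(meta$group_label), control_group)
  if (!control_group %in% meta$group_label)
    stop_contract("unknown control group '%s'", control_group)

  fold_of <- with_seed(params$rng_seed, {
    f <- integer(nrow(meta))
    for (g in unique(meta$group_label)) {
      idx <- which(meta$group_label == g)
      f[idx] <- sample(rep_len(seq_len(params$k_folds), length(idx)))
    }
    setNames(f, meta$cell_id)
  })

  truth <- ifelse(meta$group_label == control_group, "normal", "senescent")
  names(truth) <- meta$cell_id

  rows <- lapply(seq_len(params$k_folds), function(k) {
    test_cells <- meta$cell_id[fold_of == k]
    train_cells <- meta$cell_id[fold_of != k]
    train <- subset_dataset(dataset, cells = train_cells)
    res <- tryCatch({
      model <- build_ensemble(train, genes_of_interest, groups,
                              control_group, params)
      train_scores <- score_cells(train, model)
      is_ctrl <- truth[train_scores$cell_id] == "normal"
      fit <- fit_gaussian_threshold(train_scores$egs_score[is_ctrl],
                                    train_scores$egs_score[!is_ctrl],
                                    weighting = params$threshold_weighting)
      test <- subset_dataset(dataset, cells = test_cells)
      test_scores <- score_cells(test, model)
      labels <- classify_cells(test_scores$egs_score, fit)
      acc <- mean(labels == truth[test_scores$cell_id])
      n <- min(params$n_confident, floor(length(test_cells) / 2))
      ord <- order(test_scores$egs_score, seq_along(test_scores$egs_score))
      extreme <- c(head(ord, n), tail(ord, n))
      ext_acc <- mean(labels[extreme] == truth[test_scores$cell_id][extreme])
      list(accuracy = acc, extremes_accuracy = ext_acc,
           threshold = fit$threshold, n_pairs = length(model$pairs),
           degenerate = FALSE)
    }, error = function(e) {
      message(sprintf("fold %d degenerate: %s", k, conditionMessage(e)))
      list(accuracy = NA_real_, extremes_accuracy = NA_real_,
           threshold = NA_real_, n_pairs = NA_integer_, degenerate = TRUE)
    })
    data.frame(fold = k, n_test = length(test_cells),
               accuracy = res$accuracy,
               extremes_accuracy = res$extremes_accuracy,
               threshold = res$threshold, n_pairs = res$n_pairs,
               degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("egs_cv", "data.frame")
  out
}

#' Select the most confident normal and senescent cells with p21/p16 gating
#'
#' `low_cells` are the `n` lowest-scoring cells among p21- AND p16- cells;
#' `high_cells` are the `n` highest-scoring cells among p21+ OR p16+ cells,
#' where "+" means a nonzero raw count of CDKN1A (p21) or CDKN2A (p16).
#' Ties are broken by cell index for determinism.
#'
#' @param scores numeric per-cell scores.
#' @param p21_counts,p16_counts raw counts of CDKN1A / CDKN2A, aligned with
#'   `scores`.
#' @param n cells per stratum.
#' @param cell_ids cell barcodes aligned with `scores` (default names of
#'   `scores`).
#' @return an object of class `ConfidentSelection`: list with `low_cells`,
#'   `high_cells`, `n`.
#' @export
select_confident <- function(scores, p21_counts, p16_counts, n,
                             cell_ids = names(scores)) {
  if (is.null(cell_ids))
    stop_contract("cell_ids required (or pass a named scores vector)")
  stopifnot(length(scores) == length(p21_counts),
            length(scores) == length(p16_counts),
            length(scores) == length(cell_ids))
  if (n < 1) stop_contract("n must be >= 1")
  neg <- which(p21_counts == 0 & p16_counts == 0)
  pos <- which(p21_counts > 0 | p16_counts > 0)
  if (length(neg) < n)
    stop_contract("p21-/p16- stratum has %d cells, need %d", length(neg), n)
  if (length(pos) < n)
    stop_contract("p21+ or p16+ stratum has %d cells, need %d", length(pos), n)
  low <- neg[order(scores[neg], neg)][seq_len(n)]
  high <- pos[order(-scores[pos], pos)][seq_len(n)]
  structure(list(low_cells = cell_ids[low], high_cells = cell_ids[high],
                 n = as.integer(n)),
            class = "ConfidentSelection")
}

#' Confident selection straight from a dataset
#'
#' Convenience wrapper around [select_confident()] that pulls the CDKN1A
#' and CDKN2A count rows from the dataset.
#'
#' @param dataset an `ExpressionDataset` containing CDKN1A and CDKN2A.
#' @param scores an `egs_scores` data.frame (or named numeric vector).
#' @param n cells per stratum.
#' @return a `ConfidentSelection`.
#' @export
select_confident_cells <- function(dataset, scores, n) {
  if (inherits(scores, "egs_scores") || is.data.frame(scores))
    scores <- setNames(scores$egs_score, scores$cell_id)
  for (g in c("CDKN1A", "CDKN2A"))
    if (!g %in% gene_ids(dataset))
      stop_contract("gene %s absent: p21/p16 gating impossible", g)
  ids <- names(scores)
  select_confident(scores,
                   p21_counts = as.numeric(dataset$counts["CDKN1A", ids]),
                   p16_counts = as.numeric(dataset$counts["CDKN2A", ids]),
                   n = n, cell_ids = ids)
}
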