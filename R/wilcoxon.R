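# Two-sided p-value of the Wilcoxon rank-sum statistic.
#
# For small groups (both <= RANKSUM_EXACT_MAX) the exact permutation
# distribution of the rank sum is computed by dynamic programming over the
# (doubled, hence integer) midranks, which handles ties exactly. Otherwise
# the normal approximation with midranks, tie correction and continuity
# correction is used (the large-sample convention of standard rank-sum
# implementations).

RANKSUM_EXACT_MAX <- 10L

# exact two-sided permutation p-value for observed rank-sum w of group A
# r: midranks of the pooled sample; na: size of group A
ranksum_exact_p <- function(r, na, w) {
  d <- as.integer(round(2 * r))        # doubled midranks are integers
  N <- length(d)
  smax <- sum(d)
  # ways[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  ways <- matrix(0, nrow = na + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (i in seq_len(N)) {
    di <- d[i]
    kmax <- min(i, na)
    for (k in kmax:1) {
      nz <- which(ways[k, ] > 0)
      if (length(nz))
        ways[k + 1, nz + di] <- ways[k + 1, nz + di] + ways[k, nz]
    }
  }
  counts <- ways[na + 1, ]
  sums <- seq(0, smax)
  total <- sum(counts)
  mu <- sum(counts * sums) / total
  obs_dev <- abs(2 * w - mu)
  sum(counts[abs(sums - mu) >= obs_dev - 1e-9]) / total
}

# normal-approximation two-sided p with tie and continuity correction
ranksum_normal_p <- function(r, na, w) {
  N <- length(r)
  nb <- N - na
  mu <- na * (N + 1) / 2
  ties <- rle(sort(r))$lengths
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  dev <- w - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# two-sided rank-sum p-value for values split as x (group A) vs y (group B)
ranksum_p <- function(x, y) {
  na <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(na)])
  if (na <= RANKSUM_EXACT_MAX && length(y) <= RANKSUM_EXACT_MAX)
    ranksum_exact_p(r, na, w)
  else
    ranksum_normal_p(r, na, w)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the log-normalized layer.
#' The log2 fold change is computed on de-logged means,
#' `log2((mean(expm1(a)) + eps) / (mean(expm1(b)) + eps))` with
#' `eps = 1e-9`; genes with `|log2fc| < logfc_threshold` are skipped before
#' testing, p-values are Bonferroni-adjusted over *all* candidate genes
#' (the convention of the standard single-cell marker tool — correcting
#' only over the genes passing the fold-change gate would leave the
#' family-wise error inflated, because the gate preselects genes
#' correlated with the test statistic), and only genes with
#' `adj_p <= adj_p_max` are returned. Direction is `"up"` when the fold
#' change favors group A.
#'
#' For group sizes of at most 10 cells each, the exact permutation
#' distribution of the rank sum (with midranks) is used; larger groups use
#' the normal approximation with tie and continuity correction.
#'
#' @param dataset an `ExpressionDataset` with a lognorm layer.
#' @param cells_a,cells_b disjoint cell-id vectors, each >= 3 cells.
#' @param logfc_threshold minimum |log2 fold change|; default 0.25.
#' @param adj_p_max maximum Bonferroni-adjusted p-value; default 0.05.
#' @param genes candidate genes (default all).
#' @return data.frame with columns `gene`, `log2fc`, `p_value`, `adj_p`,
#'   `direction`, sorted by `adj_p` then `gene`.
#' @export
wilcoxon_de <- function(dataset, cells_a, cells_b,
                        logfc_threshold = 0.25, adj_p_max = 0.05,
                        genes = NULL) {
  if (is.null(dataset$lognorm))
    stop_contract("lognormalize() the dataset before differential expression")
  if (length(intersect(cells_a, cells_b)))
    stop_contract("cell groups overlap (%d shared cells)",
                  length(intersect(cells_a, cells_b)))
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop_contract("both groups need >= 3 cells (got %d and %d)",
                  length(cells_a), length(cells_b))
  genes <- genes %||% gene_ids(dataset)

  eps <- 1e-9
  xa <- dataset$lognorm[genes, cells_a, drop = FALSE]
  xb <- dataset$lognorm[genes, cells_b, drop = FALSE]
  mean_a <- Matrix::rowMeans(expm1(xa))
  mean_b <- Matrix::rowMeans(expm1(xb))
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  tested <- which(abs(log2fc) >= logfc_threshold)
  if (length(tested) == 0)
    return(data.frame(gene = character(), log2fc = numeric(),
                      p_value = numeric(), adj_p = numeric(),
                      direction = character(), stringsAsFactors = FALSE))

  a_dense <- as.matrix(xa[tested, , drop = FALSE])
  b_dense <- as.matrix(xb[tested, , drop = FALSE])
  pvals <- vapply(seq_along(tested), function(i) {
    ranksum_p(a_dense[i, ], b_dense[i, ])
  }, numeric(1))
  adj <- pmin(1, pvals * length(genes))
  keep <- adj <= adj_p_max
  out <- data.frame(gene = genes[tested][keep],
                    log2fc = log2fc[tested][keep],
                    p_value = pvals[keep],
                    adj_p = adj[keep],
                    direction = ifelse(log2fc[tested][keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(out$adj_p, out$gene), , drop = FALSE]
}
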