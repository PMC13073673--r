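#' Cells over-expressing a driver gene
#'
#' Cells whose z-score for the driver gene strictly exceeds `z_high`
#' (high-expresser rule z > 1.5 by default). Order-stable by cell index.
#' A driver absent from the z matrix, or flagged unusable (zero reference
#' sd), yields an empty result with the reason attached as attribute
#' `reason`.
#'
#' @param z z-score matrix from [zscore_matrix()] (genes x cells).
#' @param driver_gene gene symbol.
#' @param z_high cutoff; default 1.5.
#' @return character vector of cell ids (possibly empty).
#' @export
select_high_expressers <- function(z, driver_gene, z_high = 1.5) {
  usable <- attr(z, "usable")
  if (!driver_gene %in% rownames(z)) {
    out <- character(0)
    attr(out, "reason") <- sprintf("driver '%s' absent from z matrix", driver_gene)
    return(out)
  }
  if (!is.null(usable) && !isTRUE(usable[[driver_gene]])) {
    out <- character(0)
    attr(out, "reason") <- sprintf("driver '%s' has zero reference sd", driver_gene)
    return(out)
  }
  colnames(z)[z[driver_gene, ] > z_high]
}

#' Gene-set pair constructor
#' @keywords internal
#' @noRd
gene_set_pair <- function(driver, group, up_genes, down_genes, n_driver_cells) {
  up_genes <- unique(up_genes)
  down_genes <- unique(down_genes)
  stopifnot(length(intersect(up_genes, down_genes)) == 0)
  if (length(up_genes) + length(down_genes) == 0) return(NULL)
  structure(list(driver = driver, group = group,
                 up_genes = up_genes, down_genes = down_genes,
                 n_driver_cells = as.integer(n_driver_cells)),
            class = "GeneSetPair")
}

#' @export
print.GeneSetPair <- function(x, ...) {
  cat(sprintf("GeneSetPair %s @ %s: %d up / %d down genes (%d driver cells)\n",
              x$driver, x$group, length(x$up_genes), length(x$down_genes),
              x$n_driver_cells))
  invisible(x)
}

#' Build one driver-conditioned gene-set pair
#'
#' High expressers of `driver_gene` within `group_label` are compared
#' against the control cells by Wilcoxon DE; significant genes become the
#' pair's up/down lists. The driver gene itself is excluded from the DE
#' candidates: its cells were selected on that gene, so its apparent
#' regulation is tautological — the pair represents the transcriptional
#' landscape *linked to* high driver expression. Returns `NULL` (with a
#' message) when fewer than `params$min_cells` high expressers exist or
#' when the DE yields no genes.
#'
#' @param dataset an `ExpressionDataset` with lognorm.
#' @param z z-score matrix covering the driver gene.
#' @param driver_gene driver gene symbol.
#' @param group_label group in which the subpopulation is sought.
#' @param control_cells control-group cell ids (comparison baseline).
#' @param params an [egs_params()] object.
#' @return a `GeneSetPair` or `NULL`.
#' @export
build_gene_set_pair <- function(dataset, z, driver_gene, group_label,
                                control_cells, params = egs_params()) {
  cells_grp <- group_cells(dataset, group_label)
  high <- select_high_expressers(z, driver_gene, params$z_high)
  high <- high[high %in% cells_grp]
  if (length(high) < params$min_cells) {
    message(sprintf("skipping %s @ %s: %d high-expresser cells < min_cells %d%s",
                    driver_gene, group_label, length(high), params$min_cells,
                    if (!is.null(attr(high, "reason")))
                      paste0(" (", attr(high, "reason"), ")") else ""))
    return(NULL)
  }
  de <- wilcoxon_de(dataset, high, setdiff(control_cells, high),
                    logfc_threshold = params$logfc_threshold,
                    adj_p_max = params$adj_p_max,
                    genes = setdiff(gene_ids(dataset), driver_gene))
  pair <- gene_set_pair(driver_gene, group_label,
                        de$gene[de$direction == "up"],
                        de$gene[de$direction == "down"],
                        length(high))
  if (is.null(pair))
    message(sprintf("skipping %s @ %s: no differential genes", driver_gene,
                    group_label))
  pair
}

# lowSASP candidate cells of a group: bottom quartile of the per-cell
# fraction of SASP genes detected (nonzero counts), and no SASP gene with
# z above z_high. The cell-cycle-arrest gating genes (CDKN1A/p21,
# CDKN2A/p16, TP53) are not SASP factors and are excluded: SASP-silent
# senescent cells are typically still p21-positive.
lowsasp_gating_genes <- c("CDKN1A", "CDKN2A", "TP53")

lowsasp_cells <- function(dataset, z, sasp_genes, group_label, params) {
  cells_grp <- group_cells(dataset, group_label)
  sasp <- setdiff(toupper(sasp_genes), lowsasp_gating_genes)
  sasp <- intersect(sasp, gene_ids(dataset))
  if (length(sasp) == 0) stop_contract("no SASP gene present in dataset")
  detected <- Matrix::colMeans(dataset$counts[sasp, cells_grp, drop = FALSE] > 0)
  q <- quantile(detected, params$lowsasp_quantile, names = FALSE, type = 7)
  zs <- z[intersect(sasp, rownames(z)), cells_grp, drop = FALSE]
  max_z <- if (nrow(zs)) apply(zs, 2, max) else rep(-Inf, length(cells_grp))
  cells_grp[detected <= q & max_z <= params$z_high]
}

#' Build the auxiliary lowSASP gene-set pair of a group
#'
#' Captures senescence without the SASP: cells of the group whose fraction
#' of detected SASP genes falls in the bottom quartile and that have no
#' SASP gene above the high-expresser cutoff are compared against the
#' control cells. The arrest gating genes CDKN1A, CDKN2A and TP53 are not
#' treated as SASP factors here — SASP-silent senescent cells are still
#' expected to be p21-positive.
#'
#' @inheritParams build_gene_set_pair
#' @param sasp_genes SASP gene symbols.
#' @return a `GeneSetPair` with `driver = "lowSASP"`, or `NULL` when fewer
#'   than `min_cells` candidates exist.
#' @export
build_lowsasp_pair <- function(dataset, z, sasp_genes, group_label,
                               control_cells, params = egs_params()) {
  low <- lowsasp_cells(dataset, z, sasp_genes, group_label, params)
  if (length(low) < params$min_cells) {
    message(sprintf("skipping lowSASP @ %s: %d candidate cells < min_cells %d",
                    group_label, length(low), params$min_cells))
    return(NULL)
  }
  de <- wilcoxon_de(dataset, low, setdiff(control_cells, low),
                    logfc_threshold = params$logfc_threshold,
                    adj_p_max = params$adj_p_max)
  pair <- gene_set_pair("lowSASP", group_label,
                        de$gene[de$direction == "up"],
                        de$gene[de$direction == "down"],
                        length(low))
  if (is.null(pair))
    message(sprintf("skipping lowSASP @ %s: no differential genes", group_label))
  pair
}

#' Build the ensemble of gene-set pairs
#'
#' Iterates every gene of interest over every senescent group (one pair per
#' driver x group subpopulation passing the min-cell rule) plus one lowSASP
#' attempt per group, against the control group. Reference statistics
#' (per-gene mean/sd over control cells) are computed once and stored in
#' the model; they are reused verbatim whenever the model scores new data.
#'
#' @param dataset an `ExpressionDataset`; log-normalized automatically if
#'   needed (using `params$scale_factor`).
#' @param genes_of_interest candidate driver genes (SASP and senescence
#'   genes); also used as the SASP list for the lowSASP rule.
#' @param groups group labels to scan (senescent groups).
#' @param control_group label of the control group.
#' @param params an [egs_params()] object.
#' @return an `EnsembleModel`: list with `pairs`, `ref_stats`, `params`,
#'   `control_group`, `schema_version`.
#' @export
build_ensemble <- function(dataset, genes_of_interest, groups, control_group,
                           params = egs_params()) {
  if (is.null(dataset$lognorm))
    dataset <- lognormalize(dataset, params$scale_factor)
  control_cells <- group_cells(dataset, control_group)
  ref <- compute_reference_stats(dataset, control_cells)
  genes_of_interest <- toupper(genes_of_interest)
  panel_goi <- intersect(genes_of_interest, gene_ids(dataset))
  z <- zscore_matrix(dataset, ref, genes = panel_goi)

  pairs <- list()
  for (grp in groups) {
    for (g in panel_goi) {
      pair <- build_gene_set_pair(dataset, z, g, grp, control_cells, params)
      if (!is.null(pair)) pairs[[length(pairs) + 1]] <- pair
    }
    lp <- build_lowsasp_pair(dataset, z, genes_of_interest, grp,
                             control_cells, params)
    if (!is.null(lp)) pairs[[length(pairs) + 1]] <- lp
  }
  if (length(pairs) == 0)
    stop_contract("ensemble unusable: zero gene-set pairs produced")
  structure(list(pairs = pairs, ref_stats = ref, params = params,
                 control_group = control_group,
                 schema_version = "1.0"),
            class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf("EnsembleModel: %d gene-set pairs (%d lowSASP), %d reference genes\n",
              length(x$pairs),
              sum(vapply(x$pairs, function(p) p$driver == "lowSASP", logical(1))),
              length(x$ref_stats$gene_ids)))
  invisible(x)
}

pair_label <- function(pair) paste0(pair$driver, "@", pair$group)

#' Serialize an ensemble model to JSON
#' @param model an `EnsembleModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_model <- function(model, path) {
  payload <- list(
    schema_version = model$schema_version,
    control_group = model$control_group,
    params = unclass(model$params),
    ref_stats = unclass(model$ref_stats),
    pairs = lapply(model$pairs, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an ensemble model written by [write_ensemble_model()]
#' @param path JSON file path.
#' @return an `EnsembleModel`.
#' @export
read_ensemble_model <- function(path) {
  if (!file.exists(path)) stop_contract("model file '%s' not found", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(egs_params, x$params)
  ref <- structure(list(gene_ids = as.character(x$ref_stats$gene_ids),
                        mean = as.numeric(x$ref_stats$mean),
                        sd = as.numeric(x$ref_stats$sd),
                        n_control_cells = as.integer(x$ref_stats$n_control_cells)),
                   class = "ReferenceStats")
  pairs <- lapply(seq_len(nrow(x$pairs)), function(i) {
    gene_set_pair(x$pairs$driver[i], x$pairs$group[i],
                  as.character(unlist(x$pairs$up_genes[i])),
                  as.character(unlist(x$pairs$down_genes[i])),
                  x$pairs$n_driver_cells[i])
  })
  structure(list(pairs = pairs, ref_stats = ref, params = params,
                 control_group = x$control_group,
                 schema_version = x$schema_version),
            class = "EnsembleModel")
}
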