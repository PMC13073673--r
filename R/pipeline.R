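#' Assemble a pipeline configuration
#'
#' Accepts a YAML file path or a list. Recognized fields: `counts_dir`
#' (Matrix Market directory) or `fixture` (name for [make_fixture()]) or
#' `sim` (a [sim_config()] field list); `genes_of_interest` (GMT path or
#' character vector; default the packaged 106-gene list); `control_group`;
#' `groups` (default: every non-control group); `params` ([egs_params()]
#' field list); `out_dir` (optional artifact directory); `run_cv` (stage
#' toggle for the cross-validation stage, default `TRUE`); `n_grid` /
#' `logfc_grid` (transfer optimization grids).
#'
#' @param config list or YAML path.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) return(config)
  cfg <- config
  cfg$params <- if (inherits(cfg$params, "egs_params")) cfg$params
    else do.call(egs_params, cfg$params %||% list())
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "sim_config"))
    cfg$sim <- do.call(sim_config, cfg$sim)
  if (is.null(cfg$genes_of_interest))
    cfg$genes_of_interest <- genes_of_interest_default()
  if (is.character(cfg$genes_of_interest) &&
      length(cfg$genes_of_interest) == 1 &&
      file.exists(cfg$genes_of_interest))
    cfg$genes_of_interest <- unlist(read_gmt(cfg$genes_of_interest),
                                    use.names = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

load_pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$counts_dir)) {
    list(dataset = read_matrix_market(cfg$counts_dir), truth = NULL)
  } else if (!is.null(cfg$fixture)) {
    make_fixture(cfg$fixture)
  } else if (!is.null(cfg$sim)) {
    simulate_dataset(cfg$sim)
  } else {
    stop_contract("config must provide counts_dir, fixture or sim")
  }
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the reference workflow: preprocess, build, score, fit, cross-validate
#'
#' Executes the full reference pipeline on a dataset (real or simulated):
#' log normalization, ensemble construction against the control group,
#' scoring of all cells, Gaussian threshold fit, and stratified k-fold
#' cross-validation. When `out_dir` is set, writes `model.json`,
#' `scores.tsv`, `fit.json`, `cv.tsv` and a `manifest.json` recording the
#' seed and every parameter needed to regenerate the artifacts.
#'
#' @param config a [pipeline_config()] (list or YAML path accepted).
#' @return list with `dataset`, `truth`, `model`, `scores`, `fit`, `cv`,
#'   `manifest`.
#' @export
run_reference_workflow <- function(config) {
  cfg <- pipeline_config(config)
  params <- cfg$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_contract("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  loaded <- stage("load", load_pipeline_dataset(cfg))
  dataset <- stage("preprocess", lognormalize(loaded$dataset, params$scale_factor))
  control_group <- cfg$control_group %||% "PDL_25p"
  groups <- cfg$groups %||%
    setdiff(unique(dataset$cell_meta$group_label), control_group)
  model <- stage("build_ensemble",
                 build_ensemble(dataset, cfg$genes_of_interest, groups,
                                control_group, params))
  scores <- stage("score", score_cells(dataset, model))
  is_ctrl <- dataset$cell_meta[scores$cell_id, "group_label"] == control_group
  fit <- stage("fit_threshold",
               fit_gaussian_threshold(scores$egs_score[is_ctrl],
                                      scores$egs_score[!is_ctrl],
                                      weighting = params$threshold_weighting))
  run_cv <- cfg$run_cv %||% TRUE
  cv <- if (run_cv) {
    cv_params <- params
    cv_params$rng_seed <- as.integer(derive_seed(params$rng_seed, 5))
    stage("cross_validate",
          kfold_cv(dataset, cfg$genes_of_interest, control_group, cv_params))
  }
  manifest <- list(
    stages = c("load", "preprocess", "build_ensemble", "fit_threshold",
               if (run_cv) "cross_validate"),
    seed = params$rng_seed,
    control_group = control_group,
    groups = groups,
    params = unclass(params),
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim)[setdiff(names(cfg$sim), "groups")],
    egscore_version = as.character(utils::packageVersion("egscore")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ensemble_model(model, file.path(cfg$out_dir, "model.json"))
    labels <- classify_cells(scores$egs_score, fit)
    write_scores_tsv(scores$cell_id, scores$egs_score, labels,
                     file.path(cfg$out_dir, "scores.tsv"))
    write_classifier_fit(fit, file.path(cfg$out_dir, "fit.json"))
    if (!is.null(cv))
      utils::write.table(cv, file.path(cfg$out_dir, "cv.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_json_artifact(manifest, file.path(cfg$out_dir, "manifest.json"))
  }
  list(dataset = dataset, truth = loaded$truth, model = model,
       scores = scores, fit = fit, cv = cv, manifest = manifest)
}

#' Run the tissue-transfer workflow
#'
#' Applies a trained ensemble model to a tissue dataset: transfer scoring
#' with stored reference statistics, confident-extreme selection with
#' p21/p16 gating, tissue-marker derivation with (n, logfc) optimization,
#' midpoint-threshold classification, and a proliferation audit of the
#' predictions. When `out_dir` is set, writes `transfer.json`,
#' `markers.gmt` and `labels.tsv`.
#'
#' @param config a [pipeline_config()] describing the tissue dataset (and
#'   optional `n_grid` / `logfc_grid` overrides).
#' @param model an `EnsembleModel` or path to a model JSON.
#' @return list with `tissue`, `truth`, `transfer` (a `TransferResult`),
#'   `prolif`, `audit`, `manifest`.
#' @export
run_transfer_workflow <- function(config, model) {
  cfg <- pipeline_config(config)
  if (is.character(model)) model <- read_ensemble_model(model)
  if (!inherits(model, "EnsembleModel"))
    stop_contract("model must be an EnsembleModel or a model JSON path")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_contract("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  loaded <- stage("load", load_pipeline_dataset(cfg))
  tissue <- stage("preprocess",
                  lognormalize(loaded$dataset, model$params$scale_factor))
  transfer <- stage("optimize_transfer",
                    optimize_transfer(tissue, model,
                                      n_grid = cfg$n_grid %||% c(50L, 100L, 150L, 200L),
                                      logfc_grid = cfg$logfc_grid %||% c(0.25, 0.5, 1)))
  cc <- cell_cycle_genes()
  prolif <- stage("proliferation",
                  proliferation_score(tissue, cc$s, cc$g2m,
                                      rng_seed = as.integer(
                                        derive_seed(model$params$rng_seed, 7))))
  audit <- stage("audit",
                 audit_proliferation(transfer$set_scores, transfer$labels,
                                     prolif))
  manifest <- list(
    stages = c("load", "preprocess", "optimize_transfer", "proliferation",
               "audit"),
    seed = model$params$rng_seed,
    opt_n = transfer$opt_n, opt_logfc = transfer$opt_logfc,
    egscore_version = as.character(utils::packageVersion("egscore")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- list(opt_n = transfer$opt_n, opt_logfc = transfer$opt_logfc,
                    separation = transfer$separation,
                    midpoint_threshold = transfer$midpoint_threshold,
                    n_senescent = sum(transfer$labels == "senescent"),
                    tissue_up = transfer$tissue_up,
                    tissue_down = transfer$tissue_down,
                    audit = audit, manifest = manifest)
    write_json_artifact(payload, file.path(cfg$out_dir, "transfer.json"))
    write_gmt(list(tissue_up = transfer$tissue_up,
                   tissue_down = transfer$tissue_down),
              file.path(cfg$out_dir, "markers.gmt"))
    write_scores_tsv(names(transfer$set_scores), transfer$set_scores,
                     transfer$labels, file.path(cfg$out_dir, "labels.tsv"))
  }
  list(tissue = tissue, truth = loaded$truth, transfer = transfer,
       prolif = prolif, audit = audit, manifest = manifest)
}
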