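tissue_fx <- function() fixture("tissue-like")

tissue_transfer_scores <- function() {
  cached("tissue_scores",
         suppressMessages(transfer_scores(tissue_fx()$dataset,
                                          default_model())))
}

test_that("transfer scoring on the training data reproduces training scores exactly", {
  fx <- fixture("default")
  sc_train <- default_scores()
  sc_transfer <- suppressMessages(transfer_scores(fx$dataset, default_model()))
  expect_identical(sc_transfer$egs_score, sc_train$egs_score)

  # scoring just the training control cells also matches
  ctrl <- group_cells(fx$dataset, "PDL_25p")
  sc_ctrl <- suppressMessages(
    transfer_scores(subset_dataset(fx$dataset, cells = ctrl), default_model()))
  expect_equal(setNames(sc_ctrl$egs_score, sc_ctrl$cell_id),
               setNames(sc_train$egs_score, sc_train$cell_id)[ctrl])
})

test_that("a degraded gene panel is scored with a coverage warning; a tiny one errors", {
  fx <- fixture("default")
  model <- default_model()
  model_genes <- unique(unlist(lapply(model$pairs, function(p)
    c(p$up_genes, p$down_genes))))
  set.seed(97)
  keep <- sample(gene_ids(fx$dataset),
                 round(0.6 * length(gene_ids(fx$dataset))))
  keep <- union(keep, c("CDKN1A", "CDKN2A"))
  degraded <- subset_dataset(fx$dataset, genes = keep)
  expect_message(sc <- transfer_scores(degraded, model), "covers")
  truth <- truth_class(fx)
  expect_gt(median(sc$egs_score[truth[sc$cell_id] == "senescent"]),
            median(sc$egs_score[truth[sc$cell_id] == "normal"]))

  few <- subset_dataset(fx$dataset,
                        genes = union(sample(model_genes, 20),
                                      setdiff(gene_ids(fx$dataset), model_genes)))
  expect_error(suppressMessages(transfer_scores(few, model)), "floor")
})

test_that("tissue senescent truth scores above normal truth under transfer", {
  fx <- tissue_fx()
  sc <- tissue_transfer_scores()
  truth <- truth_class(fx)
  expect_gt(median(sc$egs_score[truth[sc$cell_id] == "senescent"]),
            median(sc$egs_score[truth[sc$cell_id] == "normal"]))
})

test_that("tissue markers recover the planted senescence core program", {
  fx <- tissue_fx()
  sc <- tissue_transfer_scores()
  sel <- select_confident_cells(fx$dataset, sc, 100)
  mk <- derive_tissue_markers(fx$dataset, sel, logfc_threshold = 1.0)
  core <- fx$truth$core_program
  # the planted tissue senescence program: core program plus the p21/p16
  # gating markers (cell-cycle genes separate the strata too, but at
  # tissue sequencing depth they fail the robust-expression filter)
  planted_up <- union(core$up, c("CDKN1A", "CDKN2A"))
  expect_gte(jaccard(mk$tissue_up, planted_up), 0.7)
  expect_gte(jaccard(mk$tissue_down, core$down), 0.7)
  expect_length(intersect(mk$tissue_up, mk$tissue_down), 0)

  # dropping the expression filter can only add genes
  mk0 <- derive_tissue_markers(fx$dataset, sel, logfc_threshold = 1.0,
                               min_expr_frac = 0)
  expect_true(all(mk$tissue_up %in% mk0$tissue_up))
  expect_true(all(mk$tissue_down %in% mk0$tissue_down))
})

test_that("marker derivation on signal-free strata reports the error path", {
  fx <- fixture("default")
  ctrl <- group_cells(fx$dataset, "PDL_25p")
  sel <- structure(list(low_cells = ctrl[1:50], high_cells = ctrl[51:100],
                        n = 50L), class = "ConfidentSelection")
  expect_error(derive_tissue_markers(fx$dataset, sel, logfc_threshold = 1.0),
               "smaller logfc")
})

test_that("tissue_set_score matches its dense definition", {
  fx <- tissue_fx()
  ds <- fx$dataset
  genes <- gene_ids(ds)
  # up = down cancels exactly
  s0 <- tissue_set_score(ds, genes[1:10], genes[1:10])
  expect_equal(unname(s0), rep(0, ncol(ds$counts)))

  # a single up gene is that gene's tissue-internal z-score
  g <- fx$truth$core_program$up[1]
  s1 <- tissue_set_score(ds, g, character())
  x <- as.numeric(ds$lognorm[g, ])
  expect_equal(unname(s1), (x - mean(x)) / sd(x), tolerance = 1e-12)

  set.seed(101)
  up <- sample(genes, 12); down <- sample(setdiff(genes, up), 9)
  s <- tissue_set_score(ds, up, down)
  dense <- as.matrix(ds$lognorm[c(up, down), ])
  zz <- t(scale(t(dense)))
  expect_equal(unname(s), unname(colMeans(zz[up, ]) - colMeans(zz[down, ])),
               tolerance = 1e-10)
})

test_that("transfer optimization classifies the tissue with high balanced accuracy", {
  fx <- tissue_fx()
  tr <- cached("tissue_transfer", suppressMessages(suppressWarnings(
    optimize_transfer(tissue_fx()$dataset, default_model()))))
  truth <- truth_class(fx)[names(tr$labels)]
  sens <- mean(tr$labels[truth == "senescent"] == "senescent")
  spec <- mean(tr$labels[truth == "normal"] == "normal")
  expect_gte((sens + spec) / 2, 0.9)

  # midpoint invariant: threshold is the mean of the two stratum means
  mu_l <- mean(tr$set_scores[tr$selection$low_cells])
  mu_h <- mean(tr$set_scores[tr$selection$high_cells])
  expect_equal(tr$midpoint_threshold, (mu_l + mu_h) / 2, tolerance = 1e-12)
  expect_identical(unname(tr$labels),
                   unname(classify_cells(tr$set_scores, tr$midpoint_threshold)))
  expect_length(intersect(tr$tissue_up, tr$tissue_down), 0)
})

test_that("a single-point grid equals the direct pipeline with those parameters", {
  fx <- tissue_fx()
  tr <- suppressMessages(optimize_transfer(fx$dataset, default_model(),
                                           n_grid = 100L, logfc_grid = 1.0))
  sc <- tissue_transfer_scores()
  sel <- select_confident_cells(fx$dataset, sc, 100)
  mk <- derive_tissue_markers(fx$dataset, sel, logfc_threshold = 1.0)
  ts <- tissue_set_score(fx$dataset, mk$tissue_up, mk$tissue_down)
  mid <- (mean(ts[sel$low_cells]) + mean(ts[sel$high_cells])) / 2
  expect_identical(tr$opt_n, 100L)
  expect_equal(tr$opt_logfc, 1.0)
  expect_identical(tr$tissue_up, mk$tissue_up)
  expect_equal(tr$midpoint_threshold, mid, tolerance = 1e-12)
})

test_that("the proliferation audit counts top-percent selections correctly", {
  expect_equal(top_pct_size(11889), 119L)
  expect_equal(top_pct_size(100), 1L)

  fx <- tissue_fx()
  tr <- cached("tissue_transfer", suppressMessages(suppressWarnings(
    optimize_transfer(tissue_fx()$dataset, default_model()))))
  cc <- cell_cycle_genes()
  pr <- proliferation_score(fx$dataset, cc$s, cc$g2m, rng_seed = 103)
  audit <- audit_proliferation(tr$set_scores, tr$labels, pr)
  expect_equal(audit$top_size, top_pct_size(ncol(fx$dataset$counts)))
  expect_equal(audit$n_proliferative_in_top, 0)
  # the tissue cohort has a cycling normal minority; rare boundary
  # misclassifications may be proliferative, but only a trace
  expect_lte(audit$n_proliferative_in_predicted,
             ceiling(0.02 * audit$n_predicted_senescent))
})
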