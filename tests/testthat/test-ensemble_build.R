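test_that("high-expresser selection uses a strict cutoff and matches a linear scan", {
  z <- matrix(c(1.6, 1.5, 2.0,
                0.0, 3.0, -1.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("IL6", "MMP1"), c("c1", "c2", "c3")))
  attr(z, "usable") <- c(IL6 = TRUE, MMP1 = TRUE)
  expect_identical(select_high_expressers(z, "IL6", 1.5), c("c1", "c3"))

  set.seed(5)
  z2 <- matrix(rnorm(40 * 60), nrow = 40,
               dimnames = list(sprintf("G%02d", 1:40), sprintf("c%02d", 1:60)))
  attr(z2, "usable") <- setNames(rep(TRUE, 40), rownames(z2))
  for (g in c("G01", "G17", "G40")) {
    scan <- character()
    for (j in seq_len(ncol(z2)))
      if (z2[g, j] > 1.5) scan <- c(scan, colnames(z2)[j])
    expect_identical(select_high_expressers(z2, g, 1.5), scan)
  }

  # nothing above the cutoff
  zlow <- matrix(1.5, 1, 3, dimnames = list("IL6", c("c1", "c2", "c3")))
  attr(zlow, "usable") <- c(IL6 = TRUE)
  expect_length(select_high_expressers(zlow, "IL6", 1.5), 0)

  # absent or unusable drivers come back empty with a reason
  out <- select_high_expressers(z, "NOPE", 1.5)
  expect_length(out, 0)
  expect_match(attr(out, "reason"), "absent")
  attr(z, "usable") <- c(IL6 = FALSE, MMP1 = TRUE)
  out <- select_high_expressers(z, "IL6", 1.5)
  expect_length(out, 0)
  expect_match(attr(out, "reason"), "zero reference sd")
})

test_that("rank-sum p-values agree with exact permutation enumeration for small groups", {
  set.seed(9)
  sizes <- list(c(3, 3), c(5, 4), c(8, 6), c(10, 10))
  for (sz in sizes) {
    for (rep in 1:3) {
      # heavy ties on purpose: values drawn from a small integer support
      x <- sample(0:3, sz[1], replace = TRUE) + 0.5 * sample(0:1, sz[1], replace = TRUE)
      y <- sample(0:3, sz[2], replace = TRUE)
      p_impl <- egscore:::ranksum_p(x, y)
      p_oracle <- oracle_ranksum_p(x, y)
      expect_equal(p_impl, p_oracle, tolerance = 1e-9)
    }
  }
  # tie-free case cross-checked against the exact distribution in wilcox.test
  x <- c(1.1, 2.3, 3.7, 5.2, 6.9)
  y <- c(0.4, 1.9, 2.8, 4.4, 5.5, 8.1)
  expect_equal(egscore:::ranksum_p(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("complete separation at n=10 vs 10 gives the exact tail probability", {
  x <- 101:110  # every a-value exceeds every b-value
  y <- 1:10
  expect_equal(egscore:::ranksum_p(x, y), 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("wilcoxon_de returns nothing for identical groups and recovers a planted program", {
  vals <- matrix(rpois(20 * 12, 5), nrow = 20)  # same columns in both groups
  counts <- cbind(vals, vals)
  dimnames(counts) <- list(sprintf("G%02d", 1:20), sprintf("c%02d", 1:24))
  ds <- lognormalize(expression_dataset(
    counts, data.frame(cell_id = colnames(counts), group_label = "all")))
  de <- wilcoxon_de(ds, cell_ids(ds)[1:12], cell_ids(ds)[13:24])
  expect_equal(nrow(de), 0)

  # planted 20-gene program at log2FC = 1 with 100 cells per group
  set.seed(31)
  n_genes <- 200; n <- 200
  mu <- exp(rnorm(n_genes, 1, 0.5))
  base <- matrix(rnbinom(n_genes * n, mu = mu, size = 10), nrow = n_genes)
  planted <- sprintf("G%03d", 1:20)
  rownames(base) <- sprintf("G%03d", 1:n_genes)
  colnames(base) <- sprintf("c%03d", 1:n)
  grp_a <- colnames(base)[1:100]
  base[planted, grp_a] <- rnbinom(20 * 100, mu = 2 * mu[1:20], size = 10)
  ds2 <- lognormalize(expression_dataset(
    base, data.frame(cell_id = colnames(base), group_label = "all")))
  de2 <- wilcoxon_de(ds2, grp_a, setdiff(cell_ids(ds2), grp_a),
                     logfc_threshold = 0.25)
  up <- de2$gene[de2$direction == "up"]
  expect_gte(jaccard(up, planted), 0.8)
  # direction is consistent with the fold-change sign, adj_p >= p
  expect_true(all(de2$adj_p >= de2$p_value))
  expect_true(all((de2$log2fc > 0) == (de2$direction == "up")))

  expect_error(wilcoxon_de(ds2, grp_a, grp_a[1:50]), "overlap")
})

test_that("the min-cell rule gates pair construction at the exact boundary", {
  fx <- fixture("tiny-2group")
  model <- tiny_model()
  ref <- model$ref_stats
  driver <- fx$truth$drivers[1]
  z <- zscore_matrix(fx$dataset, ref, genes = driver)
  h <- length(intersect(select_high_expressers(z, driver, 1.5),
                        group_cells(fx$dataset, "PDL_50np")))
  ctrl <- group_cells(fx$dataset, "PDL_25p")

  expect_message(
    pair_at <- build_gene_set_pair(fx$dataset, z, driver, "PDL_50np", ctrl,
                                   tiny_params(min_cells = h + 1)),
    "min_cells")
  expect_null(pair_at)
  pair <- build_gene_set_pair(fx$dataset, z, driver, "PDL_50np", ctrl,
                              tiny_params(min_cells = h))
  expect_s3_class(pair, "GeneSetPair")
  expect_identical(pair$n_driver_cells, as.integer(h))
})

test_that("driver pairs recover at least 80% of their planted up-programs", {
  fx <- fixture("tiny-2group")
  model <- tiny_model()
  for (d in fx$truth$drivers) {
    pair <- Filter(function(p) p$driver == d, model$pairs)
    expect_length(pair, 1)
    planted_up <- fx$truth$programs[[d]]$up
    expect_gte(mean(planted_up %in% pair[[1]]$up_genes), 0.8)
  }
})

test_that("lowSASP selection targets SASP-silent senescent cells", {
  fx <- fixture("tiny-2group")
  model <- tiny_model()
  ref <- model$ref_stats
  goi <- genes_of_interest_default()
  z <- zscore_matrix(fx$dataset, ref,
                     genes = intersect(goi, gene_ids(fx$dataset)))
  low <- egscore:::lowsasp_cells(fx$dataset, z, goi, "PDL_50np", tiny_params())
  silent <- fx$truth$cells$cell_id[fx$truth$cells$silent &
                                     fx$truth$cells$group == "PDL_50np"]
  expect_gte(mean(silent %in% low), 0.8)
  # no selected cell carries a high-z SASP factor (the p21/p16/p53 gating
  # genes are not SASP factors and may well be high in silent cells)
  sasp_rows <- setdiff(rownames(z), c("CDKN1A", "CDKN2A", "TP53"))
  expect_true(all(apply(z[sasp_rows, low, drop = FALSE], 2, max) <= 1.5))
  # selection is invariant to the ordering of the SASP list
  low_rev <- egscore:::lowsasp_cells(fx$dataset, z, rev(goi), "PDL_50np",
                                     tiny_params())
  expect_setequal(low, low_rev)
})

test_that("build_ensemble matches a brute-force count of qualifying subpopulations", {
  fx <- fixture("tiny-2group")
  model <- tiny_model()
  params <- tiny_params()
  ctrl <- group_cells(fx$dataset, "PDL_25p")
  goi <- intersect(genes_of_interest_default(), gene_ids(fx$dataset))
  ref <- model$ref_stats
  z <- zscore_matrix(fx$dataset, ref, genes = goi)
  grp <- group_cells(fx$dataset, "PDL_50np")
  n_expected <- 0
  for (g in goi) {
    high <- intersect(select_high_expressers(z, g, params$z_high), grp)
    if (length(high) >= params$min_cells) n_expected <- n_expected + 1
  }
  low <- egscore:::lowsasp_cells(fx$dataset, z, genes_of_interest_default(),
                                 "PDL_50np", params)
  if (length(low) >= params$min_cells) n_expected <- n_expected + 1
  expect_equal(length(model$pairs), n_expected)
})

test_that("ensemble construction is deterministic and honors its invariants", {
  fx <- fixture("tiny-2group")
  m1 <- tiny_model()
  m2 <- suppressMessages(
    build_ensemble(fx$dataset, genes_of_interest_default(), "PDL_50np",
                   "PDL_25p", tiny_params()))
  expect_identical(m1$pairs, m2$pairs)
  expect_identical(m1$ref_stats, m2$ref_stats)

  for (p in m1$pairs) {
    expect_length(intersect(p$up_genes, p$down_genes), 0)
    expect_gte(length(p$up_genes) + length(p$down_genes), 1)
    if (p$driver != "lowSASP")
      expect_gte(p$n_driver_cells, tiny_params()$min_cells)
    expect_true(all(c(p$up_genes, p$down_genes) %in% m1$ref_stats$gene_ids))
  }

  expect_error(suppressMessages(
    build_ensemble(fx$dataset, genes_of_interest_default(), "PDL_50np",
                   "PDL_25p", egs_params(min_cells = 1000))),
    "zero gene-set pairs")
})

test_that("each driver pair is closest to its own planted program", {
  fx <- fixture("tiny-2group")
  model <- tiny_model()
  truth <- fx$truth
  for (d in truth$drivers) {
    pair <- Filter(function(p) p$driver == d, model$pairs)[[1]]
    pair_genes <- c(pair$up_genes, pair$down_genes)
    own <- jaccard(pair_genes, unlist(truth$programs[[d]]))
    for (other in setdiff(truth$drivers, d)) {
      expect_gt(own, jaccard(pair_genes, unlist(truth$programs[[other]])))
    }
  }
})

test_that("ensemble models survive a JSON round trip", {
  model <- tiny_model()
  path <- tmp_file()
  write_ensemble_model(model, path)
  back <- read_ensemble_model(path)
  expect_equal(length(back$pairs), length(model$pairs))
  expect_identical(back$pairs[[1]]$up_genes, model$pairs[[1]]$up_genes)
  expect_equal(back$ref_stats$mean, model$ref_stats$mean)
  expect_equal(back$ref_stats$sd, model$ref_stats$sd)
  expect_equal(unclass(back$params), unclass(model$params),
               ignore_attr = TRUE)

  # two writes of the same model are byte-identical
  path2 <- tmp_file()
  write_ensemble_model(model, path2)
  expect_identical(readLines(path), readLines(path2))
})
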