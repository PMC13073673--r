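test_that("simulation is deterministic given its seeds", {
  cfg <- sim_config(
    n_genes = 250L,
    groups = list(list(label = "ctrl", n_cells = 60L, class = "control"),
                  list(label = "sen", n_cells = 60L, class = "mature_senescent")),
    n_drivers = 2L, program_size = 8L, core_program_size = 8L,
    n_extra_sasp = 4L, n_cc_per_phase = 10L, subpop_frac = 0.3,
    seed = 71L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$truth$memberships, b$truth$memberships)
  # a different sampling seed changes counts but not the planted programs
  cfg2 <- sim_config(
    n_genes = 250L,
    groups = list(list(label = "ctrl", n_cells = 60L, class = "control"),
                  list(label = "sen", n_cells = 60L, class = "mature_senescent")),
    n_drivers = 2L, program_size = 8L, core_program_size = 8L,
    n_extra_sasp = 4L, n_cc_per_phase = 10L, subpop_frac = 0.3,
    seed = 72L)
  c_ <- simulate_dataset(cfg2)
  expect_false(identical(as.matrix(a$dataset$counts),
                         as.matrix(c_$dataset$counts)))
  expect_identical(a$truth$programs, c_$truth$programs)
})

test_that("marginal counts follow the negative binomial they were drawn from", {
  # constant library size and a control-only design so a filler gene's
  # marginal is exactly NB(mu, size = 1/dispersion)
  cfg <- sim_config(
    n_genes = 120L,
    groups = list(list(label = "ctrl", n_cells = 10000L, class = "control")),
    n_drivers = 1L, program_size = 3L, core_program_size = 3L,
    n_extra_sasp = 2L, n_cc_per_phase = 8L, subpop_frac = 0.2,
    libsize_sdlog = 0, nb_dispersion = 0.25, seed = 73L)
  sim <- simulate_dataset(cfg)
  st <- egscore:::sim_structure(cfg)
  g <- st$filler[1]
  x <- as.numeric(sim$dataset$counts[g, ])
  cp0 <- exp(st$loglam); cp0 <- cp0 / sum(cp0) * 1e4
  mu <- cp0[g] * exp(cfg$libsize_meanlog) / 1e4
  size <- 1 / cfg$nb_dispersion

  kmax <- max(qnbinom(0.999, mu = mu, size = size), max(x))
  probs <- dnbinom(0:kmax, mu = mu, size = size)
  probs[kmax + 1] <- probs[kmax + 1] + pnbinom(kmax, mu = mu, size = size,
                                               lower.tail = FALSE)
  expected <- probs * length(x)
  # pool bins with small expectation
  keep <- expected >= 5
  obs <- tabulate(x + 1, nbins = kmax + 1)
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    {
      o <- sum(obs[!keep]); e <- sum(expected[!keep])
      if (e > 0) (o - e)^2 / e else 0
    }
  df <- sum(keep)  # pooled tail adds one class, minus one constraint
  expect_lt(chi, qchisq(0.99, df))
})

test_that("a null simulation yields at most chance-level gene-set pairs", {
  cfg <- sim_config(
    n_genes = 400L,
    groups = list(list(label = "ctrl", n_cells = 400L, class = "control"),
                  list(label = "senA", n_cells = 400L, class = "early_senescent"),
                  list(label = "senB", n_cells = 400L, class = "mature_senescent")),
    n_drivers = 10L, program_size = 5L, core_program_size = 5L,
    n_extra_sasp = 10L, n_cc_per_phase = 10L, subpop_frac = 0.08,
    effect_lognorm = 0, core_effect_lognorm = 0, silent_shift = 0,
    sasp_silent_frac = 0,
    p21_frac_senescent = 0.15, p16_frac_senescent = 0.05,
    cycling_frac_senescent = 1,
    # constant library size: selecting high-z cells must not proxy-select
    # deeply sequenced cells, which would bias detection of sparse genes
    libsize_sdlog = 0, seed = 79L)
  sim <- simulate_dataset(cfg)
  ds <- lognormalize(sim$dataset)
  goi <- genes_of_interest_default()
  n_attempts <- (length(intersect(goi, gene_ids(ds))) + 1) * 2
  n_pairs <- tryCatch(
    length(suppressMessages(build_ensemble(ds, goi, c("senA", "senB"), "ctrl",
                                           egs_params(min_cells = 15)))$pairs),
    error = function(e) 0)
  # family-wise error 0.05 per attempt; allow generous binomial slack
  expect_lte(n_pairs, ceiling(0.05 * n_attempts) + 4)
})

test_that("planted subpopulations are recovered by high-expresser selection", {
  fx <- fixture("default")
  model <- default_model()
  z <- zscore_matrix(fx$dataset, model$ref_stats, genes = fx$truth$drivers)
  params <- egs_params()
  for (glab in names(fx$truth$memberships)) {
    for (d in fx$truth$drivers) {
      members <- fx$truth$memberships[[glab]][[d]]
      if (length(members) < params$min_cells) next
      high <- select_high_expressers(z, d, params$z_high)
      expect_gte(mean(members %in% high), 0.8)
    }
  }
})

test_that("stronger planted effects weakly increase the score separation", {
  # effect is the overall planted effect scale: the shared core program
  # keeps its default ratio (roughly half the driver-program effect)
  mk <- function(effect) sim_config(
    n_genes = 250L,
    groups = list(list(label = "ctrl", n_cells = 150L, class = "control"),
                  list(label = "sen", n_cells = 150L, class = "mature_senescent")),
    n_drivers = 2L, program_size = 10L, core_program_size = 10L,
    n_extra_sasp = 5L, n_cc_per_phase = 10L, subpop_frac = 0.3,
    effect_lognorm = effect, core_effect_lognorm = effect / 2, seed = 83L)
  seps <- vapply(c(0.5, 1.5), function(eff) {
    sim <- simulate_dataset(mk(eff))
    ds <- lognormalize(sim$dataset)
    model <- suppressMessages(build_ensemble(ds, genes_of_interest_default(),
                                             "sen", "ctrl",
                                             egs_params(min_cells = 25)))
    sc <- score_cells(ds, model)
    truth <- setNames(sim$truth$cells$class, sim$truth$cells$cell_id)
    mean(sc$egs_score[truth[sc$cell_id] != "control"]) -
      mean(sc$egs_score[truth[sc$cell_id] == "control"])
  }, numeric(1))
  expect_gte(seps[2], seps[1])
})

test_that("with universal p21 the confident high stratum is nearly pure senescent", {
  cfg <- sim_config(
    n_genes = 250L,
    groups = list(list(label = "ctrl", n_cells = 150L, class = "control"),
                  list(label = "sen", n_cells = 150L, class = "mature_senescent")),
    n_drivers = 2L, program_size = 10L, core_program_size = 10L,
    n_extra_sasp = 5L, n_cc_per_phase = 10L, subpop_frac = 0.3,
    p21_frac_senescent = 1, seed = 89L)
  sim <- simulate_dataset(cfg)
  ds <- lognormalize(sim$dataset)
  model <- suppressMessages(build_ensemble(ds, genes_of_interest_default(),
                                           "sen", "ctrl",
                                           egs_params(min_cells = 25)))
  sc <- score_cells(ds, model)
  sel <- select_confident_cells(ds, sc, 50)
  truth <- setNames(sim$truth$cells$class, sim$truth$cells$cell_id)
  expect_gte(mean(truth[sel$high_cells] != "control"), 0.95)
})

test_that("fixture registry contracts hold and infeasible configs error", {
  tiny <- fixture("tiny-2group")
  expect_equal(dim(tiny$dataset$counts), c(200, 300))
  expect_length(unique(tiny$dataset$cell_meta$group_label), 2)

  wi38 <- fixture("wi38-like")
  tab <- table(wi38$dataset$cell_meta$group_label)
  expect_equal(sum(tab), 4300)
  expect_equal(as.integer(tab[c("PDL_25p", "PDL_29np", "PDL_33np",
                                "PDL_46np", "PDL_50np")]),
               c(900, 573, 657, 1179, 991))

  expect_error(make_fixture("no-such-fixture"), "tiny-2group")
  expect_error(simulate_dataset(sim_config(n_genes = 50L)), "exceed")
  expect_error(sim_config(subpop_frac = 0.2, n_drivers = 8L,
                          sasp_silent_frac = 0.5), "<= 1")
})

test_that("every fixture round-trips through Matrix Market unchanged", {
  fx <- make_fixture("tiny-2group")
  dir <- tmp_dir()
  write_matrix_market(fx$dataset, dir)
  back <- read_matrix_market(dir)
  expect_equal(as.matrix(back$counts), as.matrix(fx$dataset$counts))
  expect_identical(back$cell_meta$truth_label, fx$dataset$cell_meta$truth_label)
})
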