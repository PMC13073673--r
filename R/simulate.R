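#' Configuration of the synthetic scRNA-seq generator
#'
#' Describes a negative-binomial count simulation with the statistical
#' structure the ensemble analysis assumes: a proliferating control group
#' plus early/mature senescent groups; within each senescent group,
#' mostly-disjoint subpopulations (one per planted driver gene) whose
#' driver and up-program genes are shifted up and down-program genes
#' shifted down in log-normalized space; a shared senescence core program
#' in every senescent cell; a SASP-silent senescent subpopulation with
#' suppressed SASP genes; cell-cycle genes active only in cycling cells;
#' and p21/p16 (CDKN1A/CDKN2A) modeled as zero-inflated presence, enriched
#' in senescent cells.
#'
#' The defaults are the generator's reference study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_genes panel size; default 1200.
#' @param groups list of `list(label, n_cells, class)` with class one of
#'   `"control"`, `"early_senescent"`, `"mature_senescent"`.
#' @param n_drivers planted driver genes; default 8.
#' @param program_size up and down genes per driver program; default 20.
#' @param subpop_frac fraction of a senescent group planted per driver
#'   subpopulation; default 0.10.
#' @param overlap_rate probability that a senescent cell additionally joins
#'   each other subpopulation; default 0.03.
#' @param sasp_silent_frac fraction of each senescent group with suppressed
#'   SASP expression (senescence without the SASP); default 0.10.
#' @param core_program_size up and down genes of the shared senescence core
#'   program; default 15.
#' @param core_effect_lognorm mean shift of the shared core program in
#'   senescent cells, lognorm units; default 0.8 — deliberately weaker
#'   than the driver programs so subpopulation identity stays visible on
#'   top of the common arrest-associated program.
#' @param n_extra_sasp SASP genes present in the panel without a planted
#'   program; default 10.
#' @param n_cc_per_phase cell-cycle genes per phase included in the panel;
#'   default 20 (keeps the cell-cycle program a realistic few percent of
#'   the library; `NULL` = all packaged genes).
#' @param effect_lognorm mean shift, in log-normalized units, applied to
#'   driver/program genes; default 1.5.
#' @param cc_up_shift,cc_down_shift shift of cell-cycle genes in cycling
#'   (+, applied per phase: each cycling cell is S-active, G2M-active or
#'   both, so the proliferating reference is heterogeneous in cycle genes
#'   as real cycling populations are) and arrested (-) cells, lognorm
#'   units; defaults 1.0 and 2.5.
#' @param silent_shift downward shift of SASP genes in SASP-silent cells;
#'   default 2.5.
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   default 0.1.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters;
#'   defaults log(1e4) and 0.25.
#' @param p21_frac_senescent,p16_frac_senescent fractions of senescent
#'   cells with nonzero CDKN1A / CDKN2A; defaults 0.8 and 0.3.
#' @param p21_frac_control,p16_frac_control control analogs; defaults 0.15
#'   and 0.05.
#' @param cc_active_in_control whether control cells cycle; default TRUE.
#' @param cycling_frac_control fraction of control cells cycling (when
#'   `cc_active_in_control`); default 1.
#' @param cycling_frac_senescent fraction of senescent cells cycling;
#'   default 0 (fully arrested).
#' @param seed RNG seed for cell-level sampling; default 1.
#' @param structure_seed RNG seed for the shared structure (baseline gene
#'   means, program gene assignment); datasets generated with equal
#'   structural parameters and `structure_seed` share gene programs, which
#'   is how tissue fixtures share biology with reference fixtures; default
#'   1234.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1200L,
                       groups = list(
                         list(label = "PDL_25p", n_cells = 900L, class = "control"),
                         list(label = "PDL_46np", n_cells = 900L, class = "early_senescent"),
                         list(label = "PDL_50np", n_cells = 900L, class = "mature_senescent")),
                       n_drivers = 8L,
                       program_size = 20L,
                       subpop_frac = 0.10,
                       overlap_rate = 0.03,
                       sasp_silent_frac = 0.10,
                       core_program_size = 15L,
                       core_effect_lognorm = 0.8,
                       n_extra_sasp = 10L,
                       n_cc_per_phase = 20L,
                       effect_lognorm = 1.5,
                       cc_up_shift = 1.0,
                       cc_down_shift = 2.5,
                       silent_shift = 2.5,
                       nb_dispersion = 0.1,
                       libsize_meanlog = log(1e4),
                       libsize_sdlog = 0.25,
                       p21_frac_senescent = 0.8,
                       p16_frac_senescent = 0.3,
                       p21_frac_control = 0.15,
                       p16_frac_control = 0.05,
                       cc_active_in_control = TRUE,
                       cycling_frac_control = 1.0,
                       cycling_frac_senescent = 0.0,
                       seed = 1L,
                       structure_seed = 1234L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$subpop_frac, cfg$overlap_rate, cfg$sasp_silent_frac,
             cfg$p21_frac_senescent, cfg$p16_frac_senescent,
             cfg$p21_frac_control, cfg$p16_frac_control,
             cfg$cycling_frac_control, cfg$cycling_frac_senescent)
  if (any(fracs < 0 | fracs > 1))
    stop_contract("all fractions must lie in [0, 1]")
  if (cfg$n_drivers < 1) stop_contract("need at least one driver")
  for (g in cfg$groups)
    if (!g$class %in% c("control", "early_senescent", "mature_senescent"))
      stop_contract("unknown group class '%s'", g$class)
  if (!any(vapply(cfg$groups, function(g) g$class == "control", logical(1))))
    stop_contract("config needs a control group")
  for (g in cfg$groups) {
    if (g$class != "control" &&
        cfg$sasp_silent_frac + cfg$n_drivers * cfg$subpop_frac > 1 + 1e-9)
      stop_contract("sasp_silent_frac + n_drivers * subpop_frac must be <= 1")
  }
  structure(cfg, class = "sim_config")
}

# layout of gene identities and baseline log-lambdas; depends only on the
# structural parameters, drawn under structure_seed
sim_structure <- function(cfg) {
  cc <- cell_cycle_genes()
  if (!is.null(cfg$n_cc_per_phase)) {
    cc$s <- head(cc$s, cfg$n_cc_per_phase)
    cc$g2m <- head(cc$g2m, cfg$n_cc_per_phase)
  }
  pool <- driver_gene_pool()
  if (cfg$n_drivers + cfg$n_extra_sasp > length(pool))
    stop_contract("n_drivers + n_extra_sasp exceeds the SASP driver pool (%d)",
                  length(pool))
  drivers <- pool[seq_len(cfg$n_drivers)]
  extra_sasp <- pool[cfg$n_drivers + seq_len(cfg$n_extra_sasp)]
  specials <- c("CDKN1A", "CDKN2A", "TP53")
  n_prog <- cfg$n_drivers * 2L * cfg$program_size
  n_core <- 2L * cfg$core_program_size
  n_named <- length(specials) + length(drivers) + length(extra_sasp) +
    length(cc$s) + length(cc$g2m)
  n_filler <- cfg$n_genes - n_named - n_prog - n_core
  if (n_filler < 0)
    stop_contract("program genes exceed n_genes: need %d named genes but n_genes is %d",
                  n_named + n_prog + n_core, cfg$n_genes)
  generic <- sprintf("G%04d", seq_len(n_prog + n_core + n_filler))
  programs <- list()
  k <- 0
  for (d in drivers) {
    programs[[d]] <- list(up = generic[k + seq_len(cfg$program_size)],
                          down = generic[k + cfg$program_size + seq_len(cfg$program_size)])
    k <- k + 2L * cfg$program_size
  }
  core <- list(up = generic[k + seq_len(cfg$core_program_size)],
               down = generic[k + cfg$core_program_size + seq_len(cfg$core_program_size)])
  filler <- generic[(n_prog + n_core) + seq_len(n_filler)]

  genes <- c(specials, drivers, extra_sasp, cc$s, cc$g2m,
             unlist(lapply(programs, unlist), use.names = FALSE),
             unlist(core, use.names = FALSE), filler)
  stopifnot(!anyDuplicated(genes), length(genes) == cfg$n_genes)

  with_seed(cfg$structure_seed, {
    loglam <- setNames(numeric(cfg$n_genes), genes)
    loglam[specials] <- c(-6, -6, rnorm(1, 0.5, 0.3))   # p21/p16 overridden later
    loglam[drivers] <- rnorm(length(drivers), 1.0, 0.3)
    loglam[extra_sasp] <- rnorm(length(extra_sasp), 0.5, 0.5)
    # cycle genes are sparsely detected at tissue depth (MKI67-like)
    loglam[c(cc$s, cc$g2m)] <- rnorm(length(cc$s) + length(cc$g2m), 0.0, 0.3)
    prog_genes <- setdiff(generic, filler)
    # program/core genes are marker-grade: well expressed, like the
    # abundant SASP markers real tissue analyses rely on
    loglam[prog_genes] <- rnorm(length(prog_genes), 1.4, 0.25)
    loglam[filler] <- rnorm(length(filler), 0, 1)
    list(genes = genes, loglam = loglam, drivers = drivers,
         extra_sasp = extra_sasp, specials = specials,
         s_genes = cc$s, g2m_genes = cc$g2m,
         programs = programs, core = core, filler = filler)
  })
}

# lognorm-space shift of an expected counts-per-10k value
shift_cp <- function(cp, delta) pmax(0, (1 + cp) * exp(delta) - 1)

#' Simulate a synthetic scRNA-seq dataset with planted ground truth
#'
#' Draws counts from a negative binomial around per-gene baseline means
#' (log-normal across genes) scaled by log-normal library sizes, then
#' plants the structure described in [sim_config()]. Deterministic given
#' the config seeds.
#'
#' @param config a [sim_config()] object.
#' @return list with `dataset` (an `ExpressionDataset`, `truth_label`
#'   column filled) and `truth` (per-cell assignments, per-driver planted
#'   programs, the core program, and the gene lists used).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  st <- sim_structure(config)
  G <- config$n_genes

  with_seed(config$seed, {
    # --- cells and truth assignments -----------------------------------
    cells <- list()
    for (g in config$groups) {
      ids <- sprintf("%s_c%04d", g$label, seq_len(g$n_cells))
      cells[[g$label]] <- data.frame(cell_id = ids, group = g$label,
                                     class = g$class, stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, cells)
    rownames(meta) <- meta$cell_id
    n_cells <- nrow(meta)
    is_sen <- meta$class != "control"

    meta$cycling <- FALSE
    ctrl_idx <- which(!is_sen)
    if (config$cc_active_in_control && length(ctrl_idx))
      meta$cycling[ctrl_idx] <-
        runif(length(ctrl_idx)) < config$cycling_frac_control
    sen_idx <- which(is_sen)
    if (length(sen_idx))
      meta$cycling[sen_idx] <-
        runif(length(sen_idx)) < config$cycling_frac_senescent

    meta$p21_pos <- runif(n_cells) <
      ifelse(is_sen, config$p21_frac_senescent, config$p21_frac_control)
    meta$p16_pos <- runif(n_cells) <
      ifelse(is_sen, config$p16_frac_senescent, config$p16_frac_control)

    meta$silent <- FALSE
    memberships <- list()
    for (g in config$groups) {
      if (g$class == "control") next
      ids <- cells[[g$label]]$cell_id
      shuffled <- sample(ids)
      n_silent <- floor(config$sasp_silent_frac * length(ids))
      silent <- head(shuffled, n_silent)
      meta[silent, "silent"] <- TRUE
      pool <- shuffled[(n_silent + 1):length(shuffled)]
      spn <- round(config$subpop_frac * length(ids))
      mem <- list()
      off <- 0
      for (d in st$drivers) {
        mem[[d]] <- pool[off + seq_len(min(spn, length(pool) - off))]
        off <- off + spn
      }
      # independent extra joins (overlapping subpopulations)
      nonsilent <- setdiff(ids, silent)
      for (d in st$drivers) {
        extra <- nonsilent[runif(length(nonsilent)) < config$overlap_rate]
        mem[[d]] <- union(mem[[d]], extra)
      }
      memberships[[g$label]] <- mem
    }

    # --- expected counts-per-10k with planted shifts -------------------
    cp0 <- exp(st$loglam)
    cp0 <- cp0 / sum(cp0) * 1e4
    CP <- matrix(cp0, nrow = G, ncol = n_cells,
                 dimnames = list(st$genes, meta$cell_id))
    eff <- config$effect_lognorm
    for (glab in names(memberships)) {
      for (d in st$drivers) {
        m <- memberships[[glab]][[d]]
        if (!length(m)) next
        up_rows <- c(d, st$programs[[d]]$up)
        CP[up_rows, m] <- shift_cp(CP[up_rows, m], eff)
        dn_rows <- st$programs[[d]]$down
        CP[dn_rows, m] <- shift_cp(CP[dn_rows, m], -eff)
      }
    }
    sen_cells <- meta$cell_id[is_sen]
    core_eff <- config$core_effect_lognorm
    if (length(sen_cells)) {
      CP[st$core$up, sen_cells] <- shift_cp(CP[st$core$up, sen_cells], core_eff)
      CP[st$core$down, sen_cells] <- shift_cp(CP[st$core$down, sen_cells], -core_eff)
    }
    silent_cells <- meta$cell_id[meta$silent]
    if (length(silent_cells)) {
      sasp_rows <- c(st$drivers, st$extra_sasp)
      CP[sasp_rows, silent_cells] <-
        shift_cp(CP[sasp_rows, silent_cells], -config$silent_shift)
    }
    cc_rows <- c(st$s_genes, st$g2m_genes)
    cyc <- meta$cell_id[meta$cycling]
    arr <- meta$cell_id[!meta$cycling]
    if (length(cyc)) {
      # cycling cells sit in different phases, so the proliferating
      # reference has heterogeneous cycle-gene expression
      phase <- sample(c("S", "G2M", "both"), length(cyc), replace = TRUE,
                      prob = c(0.45, 0.45, 0.1))
      s_on <- cyc[phase != "G2M"]
      g_on <- cyc[phase != "S"]
      if (length(s_on))
        CP[st$s_genes, s_on] <- shift_cp(CP[st$s_genes, s_on],
                                         config$cc_up_shift)
      if (length(g_on))
        CP[st$g2m_genes, g_on] <- shift_cp(CP[st$g2m_genes, g_on],
                                           config$cc_up_shift)
    }
    if (length(arr))
      CP[cc_rows, arr] <- shift_cp(CP[cc_rows, arr], -config$cc_down_shift)

    # --- negative-binomial sampling ------------------------------------
    libsize <- rlnorm(n_cells, config$libsize_meanlog, config$libsize_sdlog)
    mu <- sweep(CP, 2, libsize / 1e4, `*`)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     nrow = G, dimnames = dimnames(mu))

    # p21/p16 as zero-inflated presence
    counts["CDKN1A", ] <- 0
    counts["CDKN2A", ] <- 0
    p21c <- meta$p21_pos
    counts["CDKN1A", p21c] <- 1 + rpois(sum(p21c),
                                        ifelse(is_sen[p21c], 1.5, 0.3))
    p16c <- meta$p16_pos
    counts["CDKN2A", p16c] <- 1 + rpois(sum(p16c),
                                        ifelse(is_sen[p16c], 1.5, 0.3))

    meta_ds <- data.frame(cell_id = meta$cell_id, group_label = meta$group,
                          truth_label = meta$class,
                          stringsAsFactors = FALSE)
    dataset <- expression_dataset(Matrix::Matrix(counts, sparse = TRUE), meta_ds)
    truth <- structure(list(cells = meta, memberships = memberships,
                            programs = st$programs, core_program = st$core,
                            drivers = st$drivers, extra_sasp = st$extra_sasp,
                            s_genes = st$s_genes, g2m_genes = st$g2m_genes,
                            config = config),
                       class = "SimTruth")
    list(dataset = dataset, truth = truth)
  })
}

#' Named fixture datasets used by the test suite and documentation
#'
#' Deterministic synthetic datasets:
#' \describe{
#'   \item{tiny-2group}{200 genes x 300 cells, one control and one mature
#'     senescent group, 2 drivers; fast smoke-test scale.}
#'   \item{default}{the reference study conditions of [sim_config()]
#'     (1200 genes x 2700 cells, three groups, 8 drivers).}
#'   \item{wi38-like}{1500 genes x 4300 cells across five groups with the
#'     cell counts 900/573/657/1179/991 of the replicative-senescence
#'     time course the framework was developed on.}
#'   \item{tissue-like}{1200 genes x 2000 cells emulating a tissue
#'     cohort: mostly quiescent normal fibroblasts plus a 15% senescent
#'     subset that carries the shared senescence core program (and p21/p16
#'     enrichment and cycle arrest) but not the cell-line driver
#'     subpopulations — mirroring how cell-line SASP heterogeneity does
#'     not transfer wholesale to tissue. Shares the default fixture's
#'     structure seed, so the planted core program is the same.}
#' }
#'
#' @param name fixture name.
#' @param seed optional override of the fixture's sampling seed.
#' @return list with `dataset` and `truth` (see [simulate_dataset()]).
#' @export
make_fixture <- function(name, seed = NULL) {
  registry <- list(
    "tiny-2group" = function(s) sim_config(
      n_genes = 200L,
      groups = list(
        list(label = "PDL_25p", n_cells = 150L, class = "control"),
        list(label = "PDL_50np", n_cells = 150L, class = "mature_senescent")),
      n_drivers = 2L, program_size = 10L, subpop_frac = 0.3,
      core_program_size = 10L, n_extra_sasp = 5L, n_cc_per_phase = 12L,
      seed = s %||% 101L),
    "default" = function(s) sim_config(seed = s %||% 1L),
    "wi38-like" = function(s) sim_config(
      n_genes = 1500L,
      groups = list(
        list(label = "PDL_25p", n_cells = 900L, class = "control"),
        list(label = "PDL_29np", n_cells = 573L, class = "early_senescent"),
        list(label = "PDL_33np", n_cells = 657L, class = "early_senescent"),
        list(label = "PDL_46np", n_cells = 1179L, class = "early_senescent"),
        list(label = "PDL_50np", n_cells = 991L, class = "mature_senescent")),
      seed = s %||% 202L),
    "tissue-like" = function(s) sim_config(
      groups = list(
        list(label = "tissue_normal", n_cells = 1700L, class = "control"),
        list(label = "tissue_senescent", n_cells = 300L, class = "mature_senescent")),
      subpop_frac = 0,
      sasp_silent_frac = 0,
      cycling_frac_control = 0.1,
      libsize_meanlog = log(2500),
      libsize_sdlog = 0.35,
      seed = s %||% 303L))
  if (!name %in% names(registry))
    stop_contract("unknown fixture '%s'; registry: %s", name,
                  paste(names(registry), collapse = ", "))
  simulate_dataset(registry[[name]](seed))
}
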