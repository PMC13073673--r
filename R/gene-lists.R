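#' Packaged cell-cycle phase gene sets
#'
#' The canonical S-phase and G2/M signature gene lists used for
#' proliferation scoring, shipped as a GMT fixture.
#'
#' @return list with elements `s` and `g2m` (character vectors).
#' @export
cell_cycle_genes <- function() {
  sets <- read_gmt(system.file("extdata", "cell_cycle.gmt",
                               package = "egscore", mustWork = TRUE))
  list(s = sets$S_PHASE, g2m = sets$G2M_PHASE)
}

#' Packaged SASP / senescence genes of interest
#'
#' The 106 candidate driver genes (SASP factors, IGF-axis genes,
#' senescence cell-cycle inhibitors and related genes of interest) shipped
#' as a GMT fixture.
#'
#' @return character vector of gene symbols.
#' @export
genes_of_interest_default <- function() {
  read_gmt(system.file("extdata", "genes_of_interest.gmt",
                       package = "egscore", mustWork = TRUE))$GENES_OF_INTEREST
}

# SASP genes preferred as planted drivers in the synthetic generator,
# ordered by how prominently they mark fibroblast replicative senescence.
driver_gene_pool <- function() {
  c("IGFBP7", "SERPINE2", "IL6", "MMP1", "MMP3", "TIMP1", "IGFBP5", "CCL2",
    "MIF", "CXCL12", "HGF", "IL32", "CSF1", "IGFBP4", "CTSB", "TIMP2",
    "PAPPA", "IGFBP6", "WNT16", "CXCL8")
}
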