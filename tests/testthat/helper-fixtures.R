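# Memoized synthetic fixtures and models shared across test files. Every
# object is deterministic (fixture seeds live in the generator registry),
# so caching only saves time, never changes results.

.egs_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.egs_test_cache[[key]]))
    .egs_test_cache[[key]] <- force(expr)
  .egs_test_cache[[key]]
}

# fixture with lognorm layer attached
fixture <- function(name) {
  cached(paste0("fx_", name), {
    fx <- make_fixture(name)
    fx$dataset <- lognormalize(fx$dataset)
    fx
  })
}

# params sized for the tiny-2group fixture (45-cell subpopulations)
tiny_params <- function(...)
  do.call(egs_params, utils::modifyList(list(min_cells = 25L), list(...)))

tiny_model <- function() {
  cached("tiny_model", suppressMessages(
    build_ensemble(fixture("tiny-2group")$dataset, genes_of_interest_default(),
                   "PDL_50np", "PDL_25p", tiny_params())))
}

default_model <- function() {
  cached("default_model", suppressMessages(
    build_ensemble(fixture("default")$dataset, genes_of_interest_default(),
                   c("PDL_46np", "PDL_50np"), "PDL_25p", egs_params())))
}

default_scores <- function() {
  cached("default_scores",
         suppressMessages(score_cells(fixture("default")$dataset,
                                      default_model())))
}

truth_class <- function(fx) {
  setNames(ifelse(fx$truth$cells$class == "control", "normal", "senescent"),
           fx$truth$cells$cell_id)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

tmp_dir <- function() {
  d <- tempfile("egs")
  dir.create(d)
  d
}

tmp_file <- function() tempfile("egs", fileext = ".tsv")
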