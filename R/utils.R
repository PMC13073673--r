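#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers (module scores,
#' fold assignment, simulation) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Size of a top-percent selection
#'
#' Number of cells in the top `frac` of a cohort, using the round-half-up
#' convention: a cohort of 11,889 cells has a top-1% of 119 cells.
#'
#' @param n_cells integer cohort size.
#' @param frac fraction in (0, 1]; default 0.01.
#' @return integer selection size (at least 1 for nonempty cohorts).
#' @export
#' @examples
#' top_pct_size(11889)      # 119
#' top_pct_size(100, 0.01)  # 1
top_pct_size <- function(n_cells, frac = 0.01) {
  stopifnot(is.numeric(n_cells), n_cells >= 0, frac > 0, frac <= 1)
  as.integer(floor(n_cells * frac + 0.5))
}

#' Derive a child seed from a base seed and a stage index
#'
#' Splittable scheme used to fan one pipeline seed out to per-stage seeds so
#' partial reruns stay reproducible. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stage) {
  (as.double(seed) * 1009 + 97 * stage) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce any matrix-like to numeric dgCMatrix
as_dgc <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

stop_contract <- function(...) stop(sprintf(...), call. = FALSE)
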