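# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards. All generators in the package route
#' their randomness through this helper, which is what makes every
#' synthetic fixture replayable from a single integer.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed for a string id, derived from a corpus-level seed.
# Keeps per-protein sampling stable when the corpus composition changes.
derive_seed <- function(seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Euclidean distance matrix between rows of an N x 3 coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
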