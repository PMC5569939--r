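# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
    stopf("'%s' must be numeric with all entries finite", name)
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators in the package route their randomness through this so that
# every synthetic artefact is a pure function of (config, seed).
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Flattening convention used for basis matrices: flat index 3*(v-1)+c holds
# coordinate c (1=x, 2=y, 3=z) of vertex v.  A 3 x m vertex matrix flattens
# column-major to exactly this layout, so both directions are one call.
#' @noRd
flatten_vertices <- function(v) as.numeric(v)

#' @noRd
unflatten_vertices <- function(x, m) {
  if (length(x) != 3L * m) stopf("flattened length %d does not match m = %d", length(x), m)
  matrix(x, nrow = 3L, ncol = m)
}

# Deterministic numeric formatting: 17 significant digits round-trip IEEE
# doubles exactly through as.numeric().
#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)
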