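# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
# afterwards so seeded sub-computations (fixture generation, model init,
# perturbation noise) do not disturb the training stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Coerce an H x W x C (or H x W) array to the H x W x C x B batch layout.
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stopf("expected an array, got a vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stopf("expected a 2-4 dimensional array")
  x
}

is_binary <- function(m, tol = 0) {
  all(abs(m) <= tol | abs(m - 1) <= tol)
}
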