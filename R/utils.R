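## Internal helpers shared across modules.

## Run code with a local RNG seed, restoring the caller's RNG state afterwards.
## Every stochastic operation in the package routes its randomness through this
## so that no function mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("'seed' must be a single finite number", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("monomix_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'", name, "' must be a single finite number")
  as.numeric(x)
}

## Minimum-image separation along one periodic axis.
min_image <- function(d, L) d - L * round(d / L)

## All periodic xy pairwise distances between two coordinate sets (matrices
## with columns x, y). Returns a length(nrow(a)) x nrow(b) matrix.
pairwise_xy_dist <- function(a, b, Lx, Ly) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), Lx)
  dy <- min_image(outer(a[, 2], b[, 2], "-"), Ly)
  sqrt(dx * dx + dy * dy)
}

## log(sum(exp(x))) guarded against overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Column-wise logsumexp of a matrix.
logsumexp_cols <- function(X) {
  m <- apply(X, 2, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok))
    out[ok] <- m[ok] + log(colSums(exp(sweep(X[, ok, drop = FALSE], 2, m[ok]))))
  out
}
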