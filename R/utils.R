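## Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All engine/simulator randomness goes through this so results are
# reproducible and independent of the ambient RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- .checkSeed(seed)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.checkSeed <- function(seed) {
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed))
    stop("seed must be a single integer", call. = FALSE)
  as.integer(seed)
}

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.values <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  SummarizedExperiment::assay(m, "values")
}

.frobRSS <- function(X, Tm, A) sum((X - Tm %*% A)^2)

.componentNames <- function(K) paste0("C", seq_len(K))

# Columns of a random K x n matrix drawn uniformly from the simplex
# (normalized exponentials, i.e. Dirichlet(1,...,1)).
.runifSimplex <- function(K, n) {
  E <- matrix(-log(runif(K * n)), nrow = K)
  sweep(E, 2L, colSums(E), "/")
}
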