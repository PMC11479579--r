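## Multi-right-hand-side constrained least squares.
##
## Every alternating step of the factorization engines solves, for many
## responses b sharing one small design C (n x K, K = number of components):
##
##   min_theta || C theta - b ||^2   subject to
##     theta >= 0                                (non-negative profiles / T)
##     0 <= theta <= 1                           (beta-value profiles)
##     theta >= 0, sum(theta) = 1                (proportion simplex / A)
##
## Strategy: solve the unconstrained (or equality-constrained) problem for
## all columns at once with one linear solve; columns whose solution already
## satisfies the constraints are done (it is then the constrained optimum).
## For the remainder, guess the active set by clipping, solve the KKT system
## per active-set pattern (columns grouped by pattern, one small solve per
## group), verify KKT conditions, and fall back to quadprog::solve.QP for any
## column still unresolved. Exact in all cases; the fallback is rarely hit.

.KKT_TOL <- 1e-9

# Cholesky-safe Gram matrix: escalating ridge if C is (numerically) singular.
.gram <- function(C) {
  G <- crossprod(C)
  ridge <- 0
  for (i in 0:8) {
    ok <- tryCatch({ chol(G + diag(ridge, ncol(G))); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    ridge <- max(ridge * 10, 1e-12 * max(diag(G), 1))
  }
  G + diag(ridge, ncol(G))
}

.qpSolve <- function(G, h, Amat, bvec, meq = 0L) {
  sc <- max(abs(G))  # objective scaling: same argmin, tames quadprog
  if (!is.finite(sc) || sc <= 0) sc <- 1
  quadprog::solve.QP(G / sc, h / sc, Amat, bvec, meq = meq)$solution
}

# min ||C theta - b||^2 s.t. theta >= 0, for each column b of B. Returns K x m.
.lsNonneg <- function(C, B, G = .gram(C)) {
  K <- ncol(C)
  H <- crossprod(C, B)
  Theta <- solve(G, H)
  viol <- which(apply(Theta, 2L, min) < -.KKT_TOL)
  if (length(viol)) {
    sub <- .nnActiveSet(G, H[, viol, drop = FALSE])
    Theta[, viol] <- sub
  }
  Theta[Theta < 0] <- 0
  Theta
}

# Grouped active-set solve for theta >= 0 columns; QP fallback.
.nnActiveSet <- function(G, H) {
  K <- nrow(G)
  m <- ncol(H)
  Theta <- matrix(0, K, m)
  unresolved <- seq_len(m)
  free <- matrix(TRUE, K, m)   # current passive-set guess
  for (round in seq_len(K + 1L)) {
    if (!length(unresolved)) break
    pat <- apply(free[, unresolved, drop = FALSE], 2L,
                 function(z) paste(as.integer(z), collapse = ""))
    done <- integer()
    for (p in unique(pat)) {
      cols <- unresolved[pat == p]
      F <- which(free[, cols[1L]])
      th <- matrix(0, K, length(cols))
      if (length(F))
        th[F, ] <- solve(G[F, F, drop = FALSE], H[F, cols, drop = FALSE])
      grad <- G %*% th - H[, cols, drop = FALSE]
      okPrimal <- apply(th, 2L, min) >= -.KKT_TOL
      okDual <- vapply(seq_along(cols), function(j) {
        act <- !free[, cols[j]]
        !any(act) || all(grad[act, j] >= -.KKT_TOL)
      }, logical(1))
      ok <- okPrimal & okDual
      Theta[, cols[ok]] <- th[, ok, drop = FALSE]
      done <- c(done, cols[ok])
      # refine guess: clamp negative passive coordinates, free active ones
      # whose KKT multiplier has the wrong sign
      for (j in which(!ok)) {
        cj <- cols[j]
        neg <- th[, j] < -.KKT_TOL & free[, cj]
        wrongDual <- grad[, j] < -.KKT_TOL & !free[, cj]
        free[neg, cj] <- FALSE
        free[wrongDual, cj] <- TRUE
      }
    }
    unresolved <- setdiff(unresolved, done)
  }
  for (j in unresolved)  # exact fallback
    Theta[, j] <- .qpSolve(G, H[, j], diag(K), rep(0, K))
  Theta
}

# min ||C theta - b||^2 s.t. lo <= theta <= hi, per column of B.
.lsBox <- function(C, B, lo = 0, hi = 1, G = .gram(C)) {
  K <- ncol(C)
  H <- crossprod(C, B)
  Theta <- solve(G, H)
  bad <- which(apply(Theta, 2L, function(z) any(z < lo - .KKT_TOL | z > hi + .KKT_TOL)))
  if (length(bad)) {
    Hb <- H[, bad, drop = FALSE]
    Th <- Theta[, bad, drop = FALSE]
    res <- .boxActiveSet(G, Hb, Th, lo, hi)
    Theta[, bad] <- res
  }
  Theta[Theta < lo] <- lo
  Theta[Theta > hi] <- hi
  Theta
}

.boxActiveSet <- function(G, H, Theta0, lo, hi) {
  K <- nrow(G)
  m <- ncol(H)
  Theta <- Theta0
  state <- matrix(0L, K, m)  # -1 at lo, +1 at hi, 0 free (current guess)
  state[Theta0 < lo] <- -1L
  state[Theta0 > hi] <- 1L
  resolved <- rep(FALSE, m)
  for (round in seq_len(K + 1L)) {
    idx <- which(!resolved)
    if (!length(idx)) break
    pat <- apply(state[, idx, drop = FALSE], 2L, paste, collapse = ",")
    for (p in unique(pat)) {
      cols <- idx[pat == p]
      st <- state[, cols[1L]]
      F <- which(st == 0L)
      th <- matrix(0, K, length(cols))
      th[st == -1L, ] <- lo
      th[st == 1L, ] <- hi
      rhs <- H[, cols, drop = FALSE] -
        G[, st != 0L, drop = FALSE] %*% th[st != 0L, , drop = FALSE]
      if (length(F))
        th[F, ] <- solve(G[F, F, drop = FALSE], rhs[F, , drop = FALSE])
      grad <- G %*% th - H[, cols, drop = FALSE]
      for (j in seq_along(cols)) {
        cj <- cols[j]
        okP <- all(th[F, j] >= lo - .KKT_TOL) && all(th[F, j] <= hi + .KKT_TOL)
        okD <- all(grad[st == -1L, j] >= -.KKT_TOL) &&
               all(grad[st == 1L, j] <= .KKT_TOL)
        if (okP && okD) {
          Theta[, cj] <- th[, j]
          resolved[cj] <- TRUE
        } else {
          ns <- st
          ns[th[, j] < lo - .KKT_TOL & st == 0L] <- -1L
          ns[th[, j] > hi + .KKT_TOL & st == 0L] <- 1L
          ns[st == -1L & grad[, j] < -.KKT_TOL] <- 0L
          ns[st == 1L & grad[, j] > .KKT_TOL] <- 0L
          if (identical(ns, st)) { resolved[cj] <- TRUE; Theta[, cj] <- NA }
          state[, cj] <- ns
        }
      }
    }
  }
  fallback <- which(!resolved | is.na(Theta[1L, ]))
  for (j in fallback)
    Theta[, j] <- .qpSolve(G, H[, j], cbind(diag(K), -diag(K)),
                           c(rep(lo, K), rep(-hi, K)))
  Theta
}

# min ||C theta - b||^2 s.t. theta >= 0, sum(theta) = 1, per column of B.
.lsSimplex <- function(C, B, G = .gram(C)) {
  K <- ncol(C)
  H <- crossprod(C, B)
  Ginv <- solve(G)
  ones <- rep(1, K)
  u <- Ginv %*% ones
  base <- Ginv %*% H
  lambda <- (1 - colSums(base)) / sum(u)
  Theta <- base + outer(drop(u), lambda)
  viol <- which(apply(Theta, 2L, min) < -.KKT_TOL)
  for (j in viol)
    Theta[, j] <- .qpSolve(G, H[, j], cbind(ones, diag(K)),
                           c(1, rep(0, K)), meq = 1L)
  Theta[Theta < 0] <- 0
  sweep(Theta, 2L, colSums(Theta), "/")
}
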