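#' Solve a bounded linear program by the two-phase primal simplex method
#'
#' Solves `max (or min) obj'v  subject to  A v = rhs,  lb <= v <= ub`.
#' This is the exact LP core underneath [fba()], [pfba()] and [fva()].
#' Variables with one-sided or two-sided infinite bounds are supported;
#' unboundedness and infeasibility are detected and reported rather than
#' raised. Bland's anti-cycling rule is used throughout, so the method
#' terminates on every input (at the cost of speed on large problems —
#' the intended problem scale is the desk-scale networks this package
#' analyses and generates).
#'
#' @param obj numeric objective vector, length `n`.
#' @param A constraint matrix (`m x n`), dense numeric.
#' @param rhs right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; `-Inf`/`Inf` allowed.
#' @param maximize if `TRUE` (default) maximize `obj'v`, else minimize.
#' @param tol pivot/feasibility tolerance at the solver.
#' @param maxit iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objval` and the solution vector `x` (length `n`, `NA` unless optimal).
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE,
                     tol = 1e-9, maxit = 20000L) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }

  d <- if (maximize) -obj else obj   # internal sense: minimize

  ## --- substitute out fixed variables (lb == ub) ---------------------------
  fixed <- lb == ub
  rhs2 <- rhs - if (any(fixed)) A[, fixed, drop = FALSE] %*% lb[fixed] else 0
  rhs2 <- as.numeric(rhs2)
  const <- sum(d[fixed] * lb[fixed])
  keep <- which(!fixed)
  if (length(keep) == 0L) {
    feas <- m == 0L || max(abs(rhs2)) <= 1e-7
    v <- lb
    return(list(status = if (feas) "optimal" else "infeasible",
                objval = if (feas) unname(if (maximize) -const else const) else NA_real_,
                x = if (feas) unname(v) else rep(NA_real_, n)))
  }

  ## --- shift/negate/split so every working variable is >= 0 ----------------
  ## type 1: v = lb + x          (lb finite)
  ## type 2: v = ub - x          (lb = -Inf, ub finite)
  ## type 3: v = xp - xn         (both infinite)
  cols <- list(); dstd <- numeric(0); ustd <- numeric(0)
  map <- vector("list", length(keep))
  shift_rhs <- rhs2
  for (ii in seq_along(keep)) {
    j <- keep[ii]
    aj <- A[, j]
    if (is.finite(lb[j])) {
      cols[[length(cols) + 1L]] <- aj
      dstd <- c(dstd, d[j]); ustd <- c(ustd, ub[j] - lb[j])
      shift_rhs <- shift_rhs - aj * lb[j]
      const <- const + d[j] * lb[j]
      map[[ii]] <- list(type = 1L, col = length(cols), base = lb[j])
    } else if (is.finite(ub[j])) {
      cols[[length(cols) + 1L]] <- -aj
      dstd <- c(dstd, -d[j]); ustd <- c(ustd, Inf)
      shift_rhs <- shift_rhs - aj * ub[j]
      const <- const + d[j] * ub[j]
      map[[ii]] <- list(type = 2L, col = length(cols), base = ub[j])
    } else {
      cols[[length(cols) + 1L]] <- aj
      cols[[length(cols) + 1L]] <- -aj
      dstd <- c(dstd, d[j], -d[j]); ustd <- c(ustd, Inf, Inf)
      map[[ii]] <- list(type = 3L, col = length(cols) - 1L)
    }
  }
  B <- do.call(cbind, cols)
  N <- ncol(B)

  ## --- upper-bound rows x_j + s_j = u_j ------------------------------------
  ub_idx <- which(is.finite(ustd))
  K <- length(ub_idx)
  M <- rbind(cbind(B, matrix(0, m, K)),
             cbind(matrix(0, K, N), diag(1, K)))
  if (K > 0L) for (kk in seq_len(K)) M[m + kk, ub_idx[kk]] <- 1
  bvec <- c(shift_rhs, ustd[ub_idx])
  cost <- c(dstd, rep(0, K))
  neg <- bvec < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; bvec[neg] <- -bvec[neg] }
  nr <- length(bvec); nc <- ncol(M)

  ## --- phase 1 -------------------------------------------------------------
  Tb <- cbind(M, diag(1, nr), bvec)
  basis <- nc + seq_len(nr)
  crow <- c(rep(0, nc), rep(1, nr), 0)
  for (i in seq_len(nr)) crow <- crow - Tb[i, ]   # price out artificial basis
  res <- simplex_iterate(Tb, crow, basis, tol, maxit)
  if (res$status != "optimal") {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  if (-res$crow[ncol(res$T)] > 1e-7) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  Tb <- res$T; basis <- res$basis
  ## drive artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] > nc) {
      piv <- which(abs(Tb[i, seq_len(nc)]) > tol)
      if (length(piv) == 0L) {
        drop_rows <- c(drop_rows, i)
      } else {
        q <- piv[1L]
        Tb[i, ] <- Tb[i, ] / Tb[i, q]
        for (r2 in seq_len(nrow(Tb))) {
          if (r2 != i && abs(Tb[r2, q]) > 0) Tb[r2, ] <- Tb[r2, ] - Tb[r2, q] * Tb[i, ]
        }
        basis[i] <- q
      }
    }
  }
  if (length(drop_rows) > 0L) { Tb <- Tb[-drop_rows, , drop = FALSE]; basis <- basis[-drop_rows] }
  Tb <- Tb[, c(seq_len(nc), ncol(Tb)), drop = FALSE]   # drop artificial columns

  ## --- phase 2 -------------------------------------------------------------
  crow <- c(cost, 0)
  for (i in seq_along(basis)) {
    cb <- cost[basis[i]]
    if (cb != 0) crow <- crow - cb * Tb[i, ]
  }
  res <- simplex_iterate(Tb, crow, basis, tol, maxit)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
  }
  Tb <- res$T; basis <- res$basis
  xstd <- numeric(nc)
  xstd[basis] <- Tb[, ncol(Tb)]
  zmin <- sum(cost * xstd) + const

  v <- lb  # fixed variables already at their value
  for (ii in seq_along(keep)) {
    j <- keep[ii]; mp <- map[[ii]]
    v[j] <- switch(mp$type,
                   mp$base + xstd[mp$col],
                   mp$base - xstd[mp$col],
                   xstd[mp$col] - xstd[mp$col + 1L])
  }
  list(status = "optimal",
       objval = unname(if (maximize) -zmin else zmin),
       x = unname(v))
}

## One pass of simplex pivoting on an explicit tableau with Bland's rule.
## Tb: nr x (nc+1) tableau (RHS in the last column); crow: reduced-cost row.
simplex_iterate <- function(Tb, crow, basis, tol, maxit) {
  nr <- nrow(Tb); ncp1 <- ncol(Tb)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("simplex iteration limit reached")
    ent <- which(crow[-ncp1] < -tol)
    if (length(ent) == 0L) {
      return(list(status = "optimal", T = Tb, crow = crow, basis = basis))
    }
    q <- ent[1L]                                   # Bland: smallest index
    col <- Tb[, q]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "unbounded", T = Tb, crow = crow, basis = basis))
    }
    ratio <- Tb[pos, ncp1] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + 1e-12]
    p <- cand[which.min(basis[cand])]              # Bland: smallest basic index
    prow <- Tb[p, ] / Tb[p, q]
    Tb <- Tb - outer(Tb[, q], prow)
    Tb[p, ] <- prow
    crow <- crow - crow[q] * prow
    basis[p] <- q
  }
}
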