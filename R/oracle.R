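#' Enumerate the vertices of a model's flux polytope
#'
#' Brute-force enumeration of the vertices of
#' `P = { v : S v = 0, lb <= v <= ub }`, intended as an independent test
#' oracle for [fba()] and [fva()] on small networks (a handful of
#' reactions). A vertex is a basic feasible point: with `d = n - rank(S)`
#' degrees of freedom, every vertex fixes some `d` fluxes at a finite
#' bound such that the combined equality system is uniquely solvable.
#' All `choose(n, d) * 2^d` candidate active sets are tried.
#'
#' @param model a [metabolic_model()]; all bounds must be finite.
#' @param tol feasibility tolerance for accepting a candidate vertex.
#' @return numeric matrix, one row per distinct vertex, columns named by
#'   reaction id (zero rows if the polytope is empty).
#' @export
enumerate_flux_vertices <- function(model, tol = 1e-7) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- model_lb(model); ub <- model_ub(model)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("vertex enumeration requires finite bounds")
  if (n > 12L) stop("vertex enumeration is intended for small models (<= 12 reactions)")

  r <- qr(S)$rank
  d <- n - r
  verts <- list()
  add_vertex <- function(v) {
    for (w in verts) if (max(abs(w - v)) < 1e-6) return(invisible(NULL))
    verts[[length(verts) + 1L]] <<- v
    invisible(NULL)
  }
  subsets <- if (d == 0L) list(integer(0)) else
    asplit(utils::combn(n, d), 2L)
  for (sub in subsets) {
    sub <- as.integer(sub)
    nfix <- length(sub)
    choices <- if (nfix == 0L) list(logical(0)) else
      asplit(as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nfix))), 1L)
    for (at_ub in choices) {
      fixval <- ifelse(as.logical(at_ub), ub[sub], lb[sub])
      E <- matrix(0, nfix, n)
      if (nfix > 0L) E[cbind(seq_len(nfix), sub)] <- 1
      Afull <- rbind(S, E)
      bfull <- c(rep(0, nrow(S)), fixval)
      if (qr(Afull)$rank < n) next
      v <- tryCatch(qr.solve(Afull, bfull), error = function(e) NULL)
      if (is.null(v)) next
      if (max(abs(Afull %*% v - bfull)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      add_vertex(pmin(pmax(v, lb), ub))
    }
  }
  if (length(verts) == 0L)
    return(matrix(numeric(0), 0, n, dimnames = list(NULL, colnames(S))))
  out <- do.call(rbind, verts)
  colnames(out) <- colnames(S)
  out
}

#' FBA optimum by vertex enumeration
#'
#' Independent oracle: maximum of `c'v` over the enumerated vertices of
#' the (bounded) flux polytope.
#'
#' @param model a small [metabolic_model()] with finite bounds.
#' @return list with `objective_value` and the matrix of `optimal_vertices`
#'   (rows attaining the maximum), or status `"infeasible"`.
#' @export
fba_oracle <- function(model) {
  V <- enumerate_flux_vertices(model)
  if (nrow(V) == 0L) return(list(status = "infeasible",
                                 objective_value = NA_real_))
  z <- as.numeric(V %*% model_obj(model))
  zmax <- max(z)
  list(status = "optimal", objective_value = zmax,
       optimal_vertices = V[z >= zmax - 1e-7, , drop = FALSE])
}

#' FVA ranges by vertex enumeration
#'
#' Independent oracle at `fraction_of_optimum = 1`: the optimal set of the
#' FBA LP is a face of the flux polytope, so its vertices are polytope
#' vertices; per-reaction flux ranges are the min/max of each coordinate
#' over the vertices attaining the optimum.
#'
#' @param model a small [metabolic_model()] with finite bounds.
#' @return a `flux_ranges` data.frame as from [fva()].
#' @export
fva_oracle <- function(model) {
  opt <- fba_oracle(model)
  if (opt$status != "optimal") stop("fva_oracle: infeasible model")
  V <- opt$optimal_vertices
  structure(data.frame(reaction_id = colnames(V),
                       min_flux = apply(V, 2, min),
                       max_flux = apply(V, 2, max),
                       row.names = colnames(V), stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))
}
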