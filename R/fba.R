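#' Flux balance analysis
#'
#' Maximizes the model objective `Z = c'v` subject to the steady-state
#' constraint `S v = 0` and the flux bounds `lb_i <= v_i <= ub_i`, the
#' standard constraint-based LP for genome-scale metabolic models.
#'
#' @param model a [metabolic_model()].
#' @param tol solver pivot/feasibility tolerance.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` (`Z`) and
#'   `fluxes` (named vector `v`).
#' @export
fba <- function(model, tol = 1e-9) {
  S <- stoich_matrix(model)
  res <- solve_lp(model_obj(model), S, rep(0, nrow(S)),
                  model_lb(model), model_ub(model),
                  maximize = TRUE, tol = tol)
  flux_solution(res$status, res$objval,
                stats::setNames(res$x, names(model$reactions)))
}

flux_solution <- function(status, objective_value, fluxes) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (identical(x$status, "optimal"))
    cat("   Z = ", format(x$objective_value, digits = 8), sep = "")
  cat("\n")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Among all flux vectors attaining (a fraction of) the FBA optimum,
#' returns one minimizing the total absolute flux `sum_i |v_i|`. The
#' absolute values are linearized by splitting each flux into nonnegative
#' forward and reverse parts, so the problem stays an exact LP. Ties on
#' the minimal-total-flux face are broken by the solver; downstream
#' metrics must not depend on the particular vertex beyond stated
#' tolerances.
#'
#' @param model a [metabolic_model()].
#' @param fraction_of_optimum required fraction of the FBA optimum `Z*`
#'   (the constraint is `c'v >= fraction * Z*`); default 1.
#' @param tol solver tolerance.
#' @return a `flux_solution`; `objective_value` reports `c'v` (not the
#'   flux sum); the minimized `sum_i |v_i|` is in attribute `total_flux`.
#' @export
pfba <- function(model, fraction_of_optimum = 1.0, tol = 1e-9) {
  base <- fba(model, tol = tol)
  if (base$status != "optimal") return(base)
  zstar <- base$objective_value

  S <- stoich_matrix(model)
  n <- ncol(S); m <- nrow(S)
  lb <- model_lb(model); ub <- model_ub(model)
  cvec <- model_obj(model)

  ## v = f - r with f, r >= 0
  lbf <- pmax(lb, 0); ubf <- pmax(ub, 0)
  lbr <- pmax(-ub, 0); ubr <- pmax(-lb, 0)
  ## objective-maintenance row: c'v - s = fraction * Z*, s >= 0
  A <- rbind(cbind(S, -S), c(cvec, -cvec))
  A <- cbind(A, c(rep(0, m), -1))
  rhs <- c(rep(0, m), fraction_of_optimum * zstar)
  res <- solve_lp(obj = c(rep(1, 2 * n), 0), A = A, rhs = rhs,
                  lb = c(lbf, lbr, 0), ub = c(ubf, ubr, Inf),
                  maximize = FALSE, tol = tol)
  if (res$status != "optimal")
    return(flux_solution(res$status, NA_real_,
                         stats::setNames(rep(NA_real_, n), names(model$reactions))))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  v <- stats::setNames(v, names(model$reactions))
  out <- flux_solution("optimal", sum(cvec * v), v)
  attr(out, "total_flux") <- res$objval
  out
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum flux it can carry over the
#' set of flux vectors satisfying steady state, the bounds, and
#' `c'v >= fraction_of_optimum * Z*` where `Z*` is the FBA optimum. At
#' `fraction_of_optimum = 1` this is the span of each flux over the
#' optimal face of the flux polytope (well defined under degenerate
#' optima).
#'
#' @param model a [metabolic_model()].
#' @param fraction_of_optimum fraction of the optimum to enforce
#'   (default 1; values slightly below 1 can be numerically gentler for
#'   highly degenerate models).
#' @param reactions reaction ids to analyse (default: all).
#' @param tol solver tolerance.
#' @return a `flux_ranges` data.frame with columns `reaction_id`,
#'   `min_flux`, `max_flux` (row names = reaction ids).
#' @export
fva <- function(model, fraction_of_optimum = 1.0, reactions = NULL,
                tol = 1e-9) {
  base <- fba(model, tol = tol)
  if (base$status != "optimal")
    stop("fva: base FBA problem is ", base$status)
  zstar <- base$objective_value

  S <- stoich_matrix(model)
  n <- ncol(S); m <- nrow(S)
  lb <- model_lb(model); ub <- model_ub(model)
  cvec <- model_obj(model)
  ## c'v - s = fraction * Z*, s >= 0
  A <- rbind(S, cvec)
  A <- cbind(A, c(rep(0, m), -1))
  rhs <- c(rep(0, m), fraction_of_optimum * zstar)
  lbx <- c(lb, 0); ubx <- c(ub, Inf)

  ids <- if (is.null(reactions)) names(model$reactions) else reactions
  bad <- setdiff(ids, names(model$reactions))
  if (length(bad) > 0L) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  idx <- match(ids, names(model$reactions))

  mn <- mx <- numeric(length(ids))
  for (k in seq_along(ids)) {
    e <- numeric(n + 1L); e[idx[k]] <- 1
    lo <- solve_lp(e, A, rhs, lbx, ubx, maximize = FALSE, tol = tol)
    hi <- solve_lp(e, A, rhs, lbx, ubx, maximize = TRUE, tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("fva: subproblem for '", ids[k], "' returned ", lo$status, "/", hi$status)
    mn[k] <- lo$objval; mx[k] <- hi$objval
  }
  structure(data.frame(reaction_id = ids, min_flux = mn, max_flux = mx,
                       row.names = ids, stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))
}

#' Verify a flux solution against the steady-state and bound invariants
#'
#' @param model the model the solution was computed on.
#' @param sol a `flux_solution` with status `"optimal"`.
#' @param tol assertion tolerance (looser than the solver tolerance).
#' @return `TRUE` invisibly; errors describing the violated invariant
#'   otherwise.
#' @export
check_flux_solution <- function(model, sol, tol = 1e-6) {
  stopifnot(identical(sol$status, "optimal"))
  S <- stoich_matrix(model)
  resid <- max(abs(S %*% sol$fluxes))
  if (resid > tol) stop("steady-state violation: max |Sv| = ", resid)
  lb <- model_lb(model); ub <- model_ub(model)
  if (any(sol$fluxes < lb - tol) || any(sol$fluxes > ub + tol))
    stop("bound violation in flux solution")
  invisible(TRUE)
}
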