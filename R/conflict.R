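## Host-MGE conflict statistics: FVA range-overlap conflict reactions and
## pFBA subsystem demand fold-changes.

#' Find high-conflict reactions from two FVA range sets
#'
#' A reaction is in conflict between the host-optimized and MGE-optimized
#' states when its two FVA flux ranges share no value: the intervals are
#' treated as closed, so ranges meeting at a single endpoint are *not* in
#' conflict. Conflict reactions have, by definition, no flux solution
#' satisfying both optimization states.
#'
#' @param fva_host,fva_mge `flux_ranges` from [fva()] on the
#'   host-optimized and MGE-optimized model; must cover identical
#'   reaction sets.
#' @param model the model the ranges came from (supplies the subsystem
#'   labels for the per-subsystem tallies).
#' @param tol overlap tolerance: conflict requires a gap larger than
#'   `tol` between the intervals.
#' @return a `conflict_report`: list with `conflict_reactions` (character),
#'   `per_subsystem` (data.frame: `subsystem`, `n_conflict`, `n_total`,
#'   `fraction`), `total_reactions` and `fraction_of_total`.
#' @export
find_conflicts <- function(fva_host, fva_mge, model, tol = 1e-6) {
  if (!setequal(fva_host$reaction_id, fva_mge$reaction_id))
    stop("FVA range sets cover different reactions")
  ids <- fva_host$reaction_id
  h <- fva_host[ids, ]; g <- fva_mge[ids, ]
  conflict <- (h$max_flux < g$min_flux - tol) |
              (g$max_flux < h$min_flux - tol)
  conflict_ids <- ids[conflict]

  subs <- reaction_subsystems(model)[ids]
  per <- do.call(rbind, lapply(split(seq_along(ids), subs), function(i) {
    data.frame(subsystem = subs[i[1]], n_conflict = sum(conflict[i]),
               n_total = length(i), stringsAsFactors = FALSE)
  }))
  per$fraction <- per$n_conflict / per$n_total
  per <- per[order(per$subsystem), ]
  rownames(per) <- NULL

  structure(list(conflict_reactions = conflict_ids,
                 per_subsystem = per,
                 total_reactions = length(ids),
                 fraction_of_total = length(conflict_ids) / length(ids)),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat("<conflict_report> ", length(x$conflict_reactions), " / ",
      x$total_reactions, " reactions in conflict (",
      sprintf("%.1f%%", 100 * x$fraction_of_total), ")\n", sep = "")
  invisible(x)
}

#' Per-subsystem conflict fractions
#'
#' Fraction of each cellular subprocess's reactions that are in conflict;
#' subsystems with no reactions are omitted.
#'
#' @param report a `conflict_report` from [find_conflicts()].
#' @return named numeric vector, subsystem -> fraction in `[0, 1]`.
#' @export
subsystem_conflict_fraction <- function(report) {
  stopifnot(inherits(report, "conflict_report"))
  per <- report$per_subsystem[report$per_subsystem$n_total > 0, ]
  stats::setNames(per$fraction, per$subsystem)
}

#' Subsystem demand fold-changes between two parsimonious flux states
#'
#' For each cellular subprocess, computes
#' `log2( (sum_i |F_i^P| / sum_k |F_k^P|) / (sum_i |F_i^H| / sum_k |F_k^H|) )`
#' where `F^P` are parsimonious fluxes in the MGE-optimized state, `F^H`
#' in the host-optimized state, `i` runs over the subsystem's reactions
#' and `k` over all (non-dropped) reactions of the model. Absolute values
#' capture magnitude of demand; reactions whose flux *direction* changed
#' between the states (sign flip with both magnitudes above `zero_tol`)
#' are dropped from both numerators and denominators and reported.
#' A positive value means more demand for the subprocess when MGE biomass
#' is optimized.
#'
#' @param pfba_mge,pfba_host `flux_solution`s from [pfba()] on the
#'   MGE-optimized and host-optimized configurations of the same model.
#' @param model the common model (subsystem labels).
#' @param zero_tol fluxes with `|v| <= zero_tol` in a state count as zero
#'   there and never as direction changes.
#' @param exclude_exchanges drop exchange reactions from the denominator
#'   scope (default `FALSE`: all reactions of the model are in scope).
#' @return a `subsystem_demand`: list with `per_subsystem` (data.frame:
#'   `subsystem`, `sum_mge`, `sum_host`, `share_mge`, `share_host`,
#'   `log2_fold_change`, `defined`), `dropped_reactions`, `total_mge`,
#'   `total_host`. Fold changes are `NA` with `defined = FALSE` where a
#'   subsystem sum is zero in exactly one state; identically-zero
#'   subsystems get a fold change of 0.
#' @export
subsystem_demand_fold_change <- function(pfba_mge, pfba_host, model,
                                         zero_tol = 1e-9,
                                         exclude_exchanges = FALSE) {
  vm <- pfba_mge$fluxes; vh <- pfba_host$fluxes
  if (!setequal(names(vm), names(vh)))
    stop("flux solutions cover different reaction sets")
  ids <- names(model$reactions)
  if (!setequal(ids, names(vm)))
    stop("flux solutions do not match the model's reactions")
  vm <- vm[ids]; vh <- vh[ids]

  live_m <- abs(vm) > zero_tol
  live_h <- abs(vh) > zero_tol
  vm[!live_m] <- 0            # sub-tolerance fluxes contribute exactly 0
  vh[!live_h] <- 0
  dropped <- ids[live_m & live_h & (sign(vm) != sign(vh))]
  keep <- setdiff(ids, dropped)
  if (exclude_exchanges) {
    is_ex <- vapply(model$reactions, `[[`, TRUE, "is_exchange")
    keep <- keep[!is_ex[keep]]
  }

  am <- abs(vm[keep]); ah <- abs(vh[keep])
  tot_m <- sum(am); tot_h <- sum(ah)
  subs <- reaction_subsystems(model)[keep]
  sum_m <- tapply(am, subs, sum)
  sum_h <- tapply(ah, subs, sum)
  share_m <- if (tot_m > 0) sum_m / tot_m else sum_m * NA_real_
  share_h <- if (tot_h > 0) sum_h / tot_h else sum_h * NA_real_

  lfc <- rep(NA_real_, length(sum_m))
  both_zero <- sum_m == 0 & sum_h == 0
  both_pos <- sum_m > 0 & sum_h > 0
  lfc[both_zero] <- 0
  lfc[both_pos] <- log2((share_m / share_h)[both_pos])
  defined <- both_zero | both_pos

  per <- data.frame(subsystem = names(sum_m),
                    sum_mge = as.numeric(sum_m),
                    sum_host = as.numeric(sum_h),
                    share_mge = as.numeric(share_m),
                    share_host = as.numeric(share_h),
                    log2_fold_change = lfc,
                    defined = defined,
                    stringsAsFactors = FALSE)
  per <- per[order(per$subsystem), ]
  rownames(per) <- NULL
  structure(list(per_subsystem = per, dropped_reactions = dropped,
                 total_mge = tot_m, total_host = tot_h),
            class = "subsystem_demand")
}

#' @export
print.subsystem_demand <- function(x, ...) {
  cat("<subsystem_demand> ", nrow(x$per_subsystem), " subsystems, ",
      length(x$dropped_reactions), " direction-change reaction(s) dropped\n",
      sep = "")
  print(x$per_subsystem[, c("subsystem", "log2_fold_change")])
  invisible(x)
}
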