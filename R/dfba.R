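## Batch dynamic FBA: one to three species sharing a well-mixed media pool.
##
## Per cycle, each species' exchange uptake bounds are capped by what the
## pool can supply over the timestep, min(vmax, amount / (X * dt)); each
## species' FBA is solved against the start-of-cycle environment (no
## update-order bias), biomass follows a forward-Euler update
## X <- X * (1 + mu * dt), and the pool is updated from the exchange
## fluxes. Competing overdraws are resolved by proportionally tightening
## every consumer's cap on the offending metabolite and re-solving, which
## conserves mass and is order-independent.

#' A species in a dynamic FBA simulation
#'
#' @param species_id identifier.
#' @param model the species' [metabolic_model()], with carriage state /
#'   edits already applied; its objective is the growth reaction.
#' @param biomass initial biomass in gDW.
#' @param vmax default maximum uptake rate per exchange,
#'   mmol gDW^-1 hr^-1.
#' @return a `species_state` list.
#' @export
species_state <- function(species_id, model, biomass = 1e-8, vmax = 10) {
  stopifnot(biomass >= 0, vmax > 0)
  structure(list(species_id = species_id, model = model,
                 biomass = biomass, vmax = vmax),
            class = "species_state")
}

#' Configuration of a batch dFBA simulation
#'
#' @param species list of [species_state()] objects.
#' @param media named numeric vector: extracellular metabolite id ->
#'   mmol in the shared pool. Nutrients "in excess" are represented as
#'   large finite amounts (e.g. 1000 mmol) so depletion stays
#'   representable.
#' @param dt timestep in hours (default 1).
#' @param n_cycles number of cycles (default 200).
#' @param cell_dry_weight grams dry weight per cell, for cell-count
#'   conversion (default 3e-13 g, an E. coli estimate).
#' @return a `dfba_config` list.
#' @export
dfba_config <- function(species, media, dt = 1, n_cycles = 200,
                        cell_dry_weight = 3e-13) {
  stopifnot(dt > 0, n_cycles >= 0)
  if (any(media < 0)) stop("media amounts must be >= 0")
  if (is.null(names(media)) && length(media) > 0)
    stop("media must be a named vector")
  ids <- vapply(species, `[[`, "", "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids")
  names(species) <- ids
  structure(list(species = species, media = media, dt = dt,
                 n_cycles = as.integer(n_cycles),
                 cell_dry_weight = cell_dry_weight),
            class = "dfba_config")
}

## exchange bookkeeping for one model: for each exchange reaction, the
## extracellular metabolite and the signed coefficient (environment gain
## per unit flux is -coef * v).
exchange_info <- function(model) {
  ex <- Filter(function(r) r$is_exchange, model$reactions)
  data.frame(reaction_id = vapply(ex, `[[`, "", "id"),
             metabolite_id = vapply(ex, function(r) names(r$stoichiometry), ""),
             coef = vapply(ex, function(r) unname(r$stoichiometry), 0),
             stringsAsFactors = FALSE)
}

## solve one species against a pool snapshot with caps on uptake;
## cap_scale: named per-metabolite factor in (0,1] tightening the cap.
solve_species_cycle <- function(sp, amounts, dt, cap_scale = NULL) {
  model <- sp$model
  info <- exchange_info(model)
  X <- sp$biomass
  for (i in seq_len(nrow(info))) {
    mid <- info$metabolite_id[i]
    amt <- if (mid %in% names(amounts)) amounts[[mid]] else 0
    cap <- if (X > 0) min(sp$vmax, amt / (X * dt)) else sp$vmax
    if (!is.null(cap_scale) && mid %in% names(cap_scale))
      cap <- cap * cap_scale[[mid]]
    rid <- info$reaction_id[i]
    r <- model$reactions[[rid]]
    ## uptake direction: flux with -coef * v < 0, i.e. sign(coef) direction
    if (info$coef[i] < 0) {
      model$reactions[[rid]]$lb <- max(r$lb, -cap)
      if (model$reactions[[rid]]$lb > r$ub) model$reactions[[rid]]$lb <- r$ub
    } else {
      model$reactions[[rid]]$ub <- min(r$ub, cap)
      if (model$reactions[[rid]]$ub < r$lb) model$reactions[[rid]]$ub <- r$lb
    }
  }
  sol <- fba(model)
  if (sol$status != "optimal") {
    return(list(feasible = FALSE, mu = 0,
                exchange = stats::setNames(numeric(nrow(info)),
                                           info$metabolite_id)))
  }
  v <- sol$fluxes[info$reaction_id]
  gain <- -info$coef * v            # mmol gDW^-1 hr^-1 added to the pool
  list(feasible = TRUE, mu = sol$objective_value,
       exchange = stats::setNames(gain, info$metabolite_id))
}

#' One dynamic FBA cycle
#'
#' @param amounts named numeric pool (mmol).
#' @param species list of [species_state()] objects.
#' @param dt timestep (hours).
#' @param max_rescale iterations allowed for resolving competing
#'   overdraws of a metabolite.
#' @return list with updated `amounts`, `species`, and per-species `mu`
#'   and pool-gain rates (`exchange`, mmol gDW^-1 hr^-1).
#' @export
dfba_step <- function(amounts, species, dt, max_rescale = 50L) {
  cap_scale <- lapply(species, function(sp) stats::setNames(numeric(0), character(0)))
  names(cap_scale) <- names(species)

  for (iter in seq_len(max_rescale)) {
    sols <- lapply(seq_along(species), function(i)
      solve_species_cycle(species[[i]], amounts, dt, cap_scale[[i]]))
    ## net pool change
    delta <- stats::setNames(numeric(length(amounts)), names(amounts))
    for (i in seq_along(species)) {
      g <- sols[[i]]$exchange * species[[i]]$biomass * dt
      g <- g[names(g) %in% names(delta)]
      if (length(g) > 0) delta[names(g)] <- delta[names(g)] + g
    }
    newamt <- amounts + delta
    viol <- names(newamt)[newamt < -1e-9]
    if (length(viol) == 0L) break
    ## tighten every consumer of the most-violated metabolite
    mid <- viol[which.min(newamt[viol])]
    cons <- 0; prod <- 0
    for (i in seq_along(species)) {
      g <- sols[[i]]$exchange
      if (mid %in% names(g)) {
        flow <- g[[mid]] * species[[i]]$biomass * dt
        if (flow < 0) cons <- cons - flow else prod <- prod + flow
      }
    }
    theta <- if (cons > 0) max((amounts[[mid]] + prod) / cons, 0) else 0
    theta <- min(theta * (1 - 1e-12), 1)
    for (i in seq_along(species)) {
      g <- sols[[i]]$exchange
      if (mid %in% names(g) && g[[mid]] < 0) {
        old <- if (mid %in% names(cap_scale[[i]])) cap_scale[[i]][[mid]] else 1
        cap_scale[[i]][mid] <- old * theta
      }
    }
  }

  newamt[newamt < 0] <- 0
  mus <- vapply(sols, `[[`, 0, "mu")
  for (i in seq_along(species)) {
    species[[i]]$biomass <- species[[i]]$biomass * (1 + mus[i] * dt)
  }
  list(amounts = newamt, species = species, mu = mus,
       exchange = lapply(sols, `[[`, "exchange"))
}

#' Run a batch dynamic FBA simulation
#'
#' Iterates [dfba_step()] for `n_cycles` cycles and records biomasses,
#' growth rates, pool amounts and per-species exchange rates at every
#' cycle. The simulation is fully deterministic.
#'
#' @param config a [dfba_config()].
#' @return a `dfba_trajectory`: list with `biomass` (matrix,
#'   `(n_cycles+1) x n_species`, gDW), `mu` (same shape; growth rate
#'   applied on the step leaving each time point, 0 in the final row),
#'   `media` (matrix, `(n_cycles+1) x n_metabolites`, mmol), `secretion`
#'   (list per species: matrix of pool-gain rates, mmol gDW^-1 hr^-1),
#'   `dt`, `cell_dry_weight`.
#' @export
run_dfba <- function(config) {
  stopifnot(inherits(config, "dfba_config"))
  species <- config$species
  amounts <- config$media
  nc <- config$n_cycles
  nsp <- length(species)
  sp_ids <- names(species)

  bio <- matrix(0, nc + 1L, nsp, dimnames = list(NULL, sp_ids))
  mus <- matrix(0, nc + 1L, nsp, dimnames = list(NULL, sp_ids))
  med <- matrix(0, nc + 1L, length(amounts),
                dimnames = list(NULL, names(amounts)))
  secr <- lapply(species, function(sp) {
    mids <- exchange_info(sp$model)$metabolite_id
    matrix(0, nc + 1L, length(mids), dimnames = list(NULL, mids))
  })

  bio[1L, ] <- vapply(species, `[[`, 0, "biomass")
  med[1L, ] <- amounts
  if (nc > 0) for (cyc in seq_len(nc)) {
    st <- dfba_step(amounts, species, config$dt)
    amounts <- st$amounts
    species <- st$species
    bio[cyc + 1L, ] <- vapply(species, `[[`, 0, "biomass")
    mus[cyc, ] <- st$mu
    med[cyc + 1L, ] <- amounts
    for (i in seq_len(nsp)) secr[[i]][cyc, ] <- st$exchange[[i]]
  }
  structure(list(biomass = bio, mu = mus, media = med, secretion = secr,
                 dt = config$dt, cell_dry_weight = config$cell_dry_weight),
            class = "dfba_trajectory")
}

#' Biomass-normalized cumulative secretion of a metabolite by a species
#'
#' Cumulative net amount of a metabolite a species has exported to the
#' pool, divided by the species' current biomass — the mmol gDW^-1
#' series used to compare excretion profiles across carriage states.
#'
#' @param traj a `dfba_trajectory` from [run_dfba()].
#' @param metabolite_id extracellular metabolite id.
#' @param species_id species id.
#' @return numeric series of length `n_cycles + 1` (0 at t0); `NA` at
#'   cycles where the species' biomass is 0.
#' @export
biomass_normalized_secretion <- function(traj, metabolite_id, species_id) {
  stopifnot(inherits(traj, "dfba_trajectory"))
  if (!species_id %in% colnames(traj$biomass)) stop("unknown species")
  S <- traj$secretion[[species_id]]
  if (!metabolite_id %in% colnames(S))
    stop("metabolite '", metabolite_id, "' not exchanged by '", species_id, "'")
  ncyc <- nrow(traj$biomass) - 1L
  X <- traj$biomass[, species_id]
  rate <- S[, metabolite_id]
  cum <- c(0, cumsum(rate[seq_len(ncyc)] * X[seq_len(ncyc)] * traj$dt))
  out <- cum / X
  out[X <= 0] <- NA_real_
  out
}

#' Convert biomass to cell count
#'
#' @param X biomass in gDW (>= 0).
#' @param cell_dry_weight grams dry weight per cell (> 0); 3e-13 g is a
#'   standard E. coli estimate.
#' @return cell count `X / cell_dry_weight`.
#' @export
cells_from_biomass <- function(X, cell_dry_weight = 3e-13) {
  if (cell_dry_weight <= 0) stop("cell_dry_weight must be > 0")
  if (any(X < 0)) stop("biomass must be >= 0")
  X / cell_dry_weight
}

#' Tidy data.frame view of a trajectory
#'
#' @param x a `dfba_trajectory`.
#' @param ... unused.
#' @return data.frame with columns `cycle`, `species`, `biomass`, `mu`
#'   plus one block of `metabolite`, `amount` rows per pool metabolite
#'   (species `NA` for pool rows).
#' @export
as.data.frame.dfba_trajectory <- function(x, ...) {
  ncyc <- nrow(x$biomass)
  sp <- rep(colnames(x$biomass), each = ncyc)
  d1 <- data.frame(cycle = rep(seq_len(ncyc) - 1L, ncol(x$biomass)),
                   species = sp, metabolite = NA_character_,
                   biomass = as.numeric(x$biomass),
                   mu = as.numeric(x$mu), amount = NA_real_,
                   stringsAsFactors = FALSE)
  d2 <- data.frame(cycle = rep(seq_len(ncyc) - 1L, ncol(x$media)),
                   species = NA_character_,
                   metabolite = rep(colnames(x$media), each = ncyc),
                   biomass = NA_real_, mu = NA_real_,
                   amount = as.numeric(x$media),
                   stringsAsFactors = FALSE)
  out <- rbind(d1, d2)
  out[order(out$cycle, out$species, out$metabolite, na.last = TRUE), ]
}
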