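## Species-specific model edits and MGE carriage-state configuration.

#' Make a methionine auxotroph by knocking out metB
#'
#' Disables cystathionine gamma-synthase (the metB gene product) so the
#' model cannot synthesize methionine and must take it up from the
#' medium — the basis of the engineered cross-feeding dependency.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id looked up in the model's gene rules
#'   (default `"metB"`).
#' @param reaction_id reaction id to block directly when the model
#'   carries no gene rule for `gene` (model dialects differ in gene
#'   annotation).
#' @return the knocked-out model.
#' @export
make_metB_knockout <- function(model, gene = "metB", reaction_id = NULL) {
  if (gene %in% names(model$gene_rules)) return(knock_out(model, gene))
  if (!is.null(reaction_id)) return(knock_out(model, reaction_id))
  stop("model has no gene rule for '", gene,
       "'; supply reaction_id explicitly")
}

#' Make a methionine-secreting model
#'
#' Couples methionine export to growth: the biomass reaction is edited to
#' produce `ratio` mmol of extracellular methionine per unit of biomass
#' flux, and methionine transport is made unidirectional (export only) so
#' the secreted methionine cannot be reused.
#'
#' @param model a [metabolic_model()].
#' @param ratio mmol methionine per gram of biomass growth (default 0.5).
#' @param met_ext extracellular methionine metabolite id.
#' @param biomass_id biomass reaction id; defaults to the (single)
#'   objective reaction.
#' @return the edited model.
#' @export
make_methionine_secretor <- function(model, ratio = 0.5,
                                     met_ext = "met__L_e",
                                     biomass_id = NULL) {
  if (!met_ext %in% names(model$metabolites))
    stop("model lacks extracellular methionine species '", met_ext, "'")
  if (is.null(biomass_id)) {
    if (length(model$objective) != 1L)
      stop("cannot infer biomass reaction; supply biomass_id")
    biomass_id <- names(model$objective)
  }
  if (!biomass_id %in% names(model$reactions))
    stop("unknown biomass reaction: ", biomass_id)

  st <- model$reactions[[biomass_id]]$stoichiometry
  st[met_ext] <- if (met_ext %in% names(st)) st[met_ext] + ratio else ratio
  model$reactions[[biomass_id]]$stoichiometry <- st

  ## block the uptake direction of every non-exchange reaction that moves
  ## methionine out of the extracellular pool
  for (id in names(model$reactions)) {
    r <- model$reactions[[id]]
    if (id == biomass_id || r$is_exchange) next
    s <- r$stoichiometry[met_ext]
    if (is.na(s) || s == 0) next
    if (s < 0) {          # forward flux consumes met_ext: forbid forward
      model$reactions[[id]]$ub <- min(r$ub, 0)
    } else {              # reverse flux would consume met_ext: forbid reverse
      model$reactions[[id]]$lb <- max(r$lb, 0)
    }
    if (model$reactions[[id]]$lb > model$reactions[[id]]$ub)
      model$reactions[[id]]$lb <- model$reactions[[id]]$ub
  }
  model
}

#' Define an MGE carriage state
#'
#' A carriage state is a model configuration: which reaction is
#' optimized, and the constant lower bounds forced on the plasmid and
#' phage pseudoreactions.
#'
#' @param label free-form label (e.g. `"WT"`, `"F128_plus"`,
#'   `"F128_M13_plus"`, `"plasmid_optimized"`).
#' @param objective_target reaction id to optimize (host biomass, or an
#'   MGE pseudoreaction).
#' @param plasmid_id,phage_id pseudoreaction ids (`NULL` if absent).
#' @param plasmid_lb,phage_lb forced lower bounds, mmol gDW^-1 hr^-1.
#' @return a `carriage_state` list.
#' @export
carriage_state <- function(label, objective_target,
                           plasmid_id = NULL, phage_id = NULL,
                           plasmid_lb = 0, phage_lb = 0) {
  if (plasmid_lb < 0 || phage_lb < 0) stop("MGE lower bounds must be >= 0")
  structure(list(label = label, objective_target = objective_target,
                 plasmid_id = plasmid_id, phage_id = phage_id,
                 plasmid_lb = plasmid_lb, phage_lb = phage_lb),
            class = "carriage_state")
}

#' The standard carriage states of a host carrying a plasmid and a phage
#'
#' Returns the five canonical configurations: host-optimized wild type
#' (no MGE production), the two intermediate states (host biomass
#' optimized with plasmid production forced at `plasmid_lb`, plus phage
#' production forced at `phage_lb` when both elements are carried), and
#' the two MGE-optimized extremes (plasmid-optimized with phage free at
#' 0; phage-optimized with the plasmid bound still in force).
#'
#' @param biomass_id host biomass reaction id.
#' @param plasmid_id,phage_id pseudoreaction ids.
#' @param plasmid_lb forced plasmid production (default 0.9
#'   mmol gDW^-1 hr^-1).
#' @param phage_lb forced phage production in the double-carriage
#'   intermediate state (default 0.06 mmol gDW^-1 hr^-1).
#' @return named list of [carriage_state()] objects: `WT`, `F128_plus`,
#'   `F128_M13_plus`, `plasmid_optimized`, `phage_optimized`.
#' @export
standard_carriage_states <- function(biomass_id, plasmid_id, phage_id,
                                     plasmid_lb = 0.9, phage_lb = 0.06) {
  list(
    WT = carriage_state("WT", biomass_id, plasmid_id, phage_id, 0, 0),
    F128_plus = carriage_state("F128_plus", biomass_id, plasmid_id,
                               phage_id, plasmid_lb, 0),
    F128_M13_plus = carriage_state("F128_M13_plus", biomass_id, plasmid_id,
                                   phage_id, plasmid_lb, phage_lb),
    plasmid_optimized = carriage_state("plasmid_optimized", plasmid_id,
                                       plasmid_id, phage_id, 0, 0),
    phage_optimized = carriage_state("phage_optimized", phage_id,
                                     plasmid_id, phage_id, plasmid_lb, 0)
  )
}

#' Apply a carriage state to a model
#'
#' Sets the objective to the state's target reaction and forces the
#' plasmid/phage pseudoreaction lower bounds.
#'
#' @param model a [metabolic_model()] with the referenced pseudoreactions
#'   attached.
#' @param state a [carriage_state()].
#' @return the configured model.
#' @export
set_carriage_state <- function(model, state) {
  stopifnot(inherits(state, "carriage_state"))
  needed <- c(state$objective_target,
              if (state$plasmid_lb > 0) state$plasmid_id,
              if (state$phage_lb > 0) state$phage_id)
  missing <- setdiff(needed, names(model$reactions))
  if (length(missing) > 0L)
    stop("carriage state '", state$label, "' references reaction(s) ",
         "absent from the model: ", paste(missing, collapse = ", "))
  model <- set_objective(model, state$objective_target)
  if (!is.null(state$plasmid_id) && state$plasmid_id %in% names(model$reactions))
    model <- set_bounds(model, state$plasmid_id, lb = state$plasmid_lb)
  if (!is.null(state$phage_id) && state$phage_id %in% names(model$reactions))
    model <- set_bounds(model, state$phage_id, lb = state$phage_lb)
  model
}
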