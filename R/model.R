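#' Construct a metabolite
#'
#' @param id unique metabolite identifier (e.g. `"glc__D_e"`).
#' @param name human-readable name.
#' @param compartment compartment label, e.g. `"c"` (cytosol) or `"e"`
#'   (extracellular); must be non-empty.
#' @param molar_mass optional molar mass in g/mol.
#' @return a `metabolite` list.
#' @export
metabolite <- function(id, name = id, compartment = "c", molar_mass = NA_real_) {
  stopifnot(is.character(id), nzchar(id), nzchar(compartment))
  structure(list(id = id, name = name, compartment = compartment,
                 molar_mass = molar_mass),
            class = "metabolite")
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed, positive =
#' produced. Flux bounds are in mmol gDW^-1 hr^-1. An exchange reaction
#' touches exactly one (boundary) metabolite; a pseudoreaction is an
#' artificial demand such as a biomass or MGE-production reaction.
#'
#' @param id unique reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lb,ub lower/upper flux bounds; `lb <= ub` required.
#' @param subsystem cellular-subprocess label used by the conflict metrics.
#' @param is_exchange,is_pseudoreaction flags; `is_exchange` defaults to
#'   "touches exactly one metabolite".
#' @param gene_rule optional gene association (free-form string).
#' @return a `reaction` list.
#' @export
reaction <- function(id, stoichiometry, lb = 0, ub = 1000,
                     subsystem = "", is_exchange = NULL,
                     is_pseudoreaction = FALSE, gene_rule = "") {
  stopifnot(is.character(id), nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)))
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  if (lb > ub) stop("reaction '", id, "': lb > ub")
  if (is.null(is_exchange)) is_exchange <- length(stoichiometry) == 1L
  if (is_exchange && length(stoichiometry) != 1L)
    stop("reaction '", id, "': exchange reactions touch exactly one metabolite")
  structure(list(id = id, stoichiometry = stoichiometry,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 subsystem = subsystem, is_exchange = is_exchange,
                 is_pseudoreaction = is_pseudoreaction, gene_rule = gene_rule),
            class = "reaction")
}

#' Construct a genome-scale (or toy) metabolic model
#'
#' The model induces the stoichiometric matrix `S` (metabolites x reactions)
#' used by the steady-state constraint `S v = 0` of flux balance analysis.
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective named numeric vector of objective weights `c`
#'   (reaction id -> weight); the analyses maximize `Z = c'v`.
#' @param gene_rules optional named list, gene id -> character vector of
#'   reaction ids (used by [knock_out()]).
#' @param id model identifier.
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            gene_rules = list(), id = "model") {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing) > 0L)
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  if (length(objective) == 0L || is.null(names(objective)))
    stop("objective must be a named numeric vector")
  bad <- setdiff(names(objective), rxn_ids)
  if (length(bad) > 0L)
    stop("objective references unknown reaction(s): ", paste(bad, collapse = ", "))
  for (g in names(gene_rules)) {
    bad <- setdiff(gene_rules[[g]], rxn_ids)
    if (length(bad) > 0L)
      stop("gene rule '", g, "' references unknown reaction(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 objective = objective, gene_rules = gene_rules),
            class = "metabolic_model")
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites (rows) x reactions (columns).
#' @export
stoich_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "   reactions: ", length(x$reactions), "\n", sep = "")
  cat("  objective:   ", paste(names(x$objective), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## bounds / objective vectors in reaction order
model_lb <- function(model) vapply(model$reactions, `[[`, 0, "lb")
model_ub <- function(model) vapply(model$reactions, `[[`, 0, "ub")
model_obj <- function(model) {
  cvec <- stats::setNames(numeric(length(model$reactions)), names(model$reactions))
  cvec[names(model$objective)] <- model$objective
  cvec
}

#' Subsystem label of every reaction
#' @param model a `metabolic_model`.
#' @return named character vector, reaction id -> subsystem.
#' @export
reaction_subsystems <- function(model) {
  vapply(model$reactions, `[[`, "", "subsystem")
}

#' Modify reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model (the input is untouched).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  if (!is.null(lb)) model$reactions[[id]]$lb <- as.numeric(lb)
  if (!is.null(ub)) model$reactions[[id]]$ub <- as.numeric(ub)
  if (model$reactions[[id]]$lb > model$reactions[[id]]$ub)
    stop("reaction '", id, "': lb > ub after edit")
  model
}

#' Replace the model objective
#'
#' @param model a `metabolic_model`.
#' @param id reaction id to maximize (weight 1), or a named numeric vector.
#' @return the modified model.
#' @export
set_objective <- function(model, id) {
  obj <- if (is.character(id)) stats::setNames(1, id) else id
  bad <- setdiff(names(obj), names(model$reactions))
  if (length(bad) > 0L) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  model$objective <- obj
  model
}

#' Knock out a gene or reaction
#'
#' Sets the bounds of all affected reactions to `[0, 0]`, following the
#' convention that a gene deletion disables every reaction it is mapped to
#' via the model's gene rules. The input model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param target a gene id present in `model$gene_rules`, or a reaction id.
#' @return a copy of the model with the affected reactions blocked.
#' @export
knock_out <- function(model, target) {
  if (target %in% names(model$gene_rules)) {
    rxns <- model$gene_rules[[target]]
  } else if (target %in% names(model$reactions)) {
    rxns <- target
  } else {
    stop("unknown gene or reaction: ", target)
  }
  for (id in rxns) {
    model$reactions[[id]]$lb <- 0
    model$reactions[[id]]$ub <- 0
  }
  model
}
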