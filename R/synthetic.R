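## Generators for desk-scale test inputs: seeded toy host networks with
## subsystem labels, toy MGE composition specs, an analytic conflict
## fixture certified by vertex enumeration, and cross-feeding fixtures
## for the dynamic FBA engine. Everything is deterministic under a fixed
## seed and small enough for the brute-force oracle to be exact.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy host model
#'
#' A small (~13 reaction) stand-in for a genome-scale host network:
#' carbon uptake, a respiration/fermentation branch with a capacity cap
#' on respiration (so overflow byproduct export becomes optimal under
#' high energy demand), methionine, amino-acid, nucleotide and lipid
#' biosynthesis subsystems, and a biomass reaction consuming all of them.
#' Yields and biomass coefficients vary with the seed; the generated
#' model is checked feasible (positive biomass optimum on default media)
#' before it is returned.
#'
#' @param seed RNG seed (default 1729).
#' @param carbon_uptake maximum carbon uptake, mmol gDW^-1 hr^-1.
#' @param methionine_uptake maximum methionine uptake (0 = methionine-free
#'   medium; the metB knockout then needs a positive value to grow).
#' @return a `metabolic_model` with gene rule `metB -> METSYN` and
#'   objective `BIOMASS`.
#' @export
make_toy_host <- function(seed = 1729, carbon_uptake = 10,
                          methionine_uptake = 0) {
  p <- with_seed(seed, list(
    y_resp = stats::runif(1, 8, 12),
    y_ferm = stats::runif(1, 1.5, 3),
    ## respiration capacity is scarce relative to energy demand, so
    ## overflow through the fermentation branch is part of the optimal
    ## operating regime (as in fast-growing E. coli)
    resp_cap = stats::runif(1, 0.6, 1.2),
    e_aa = stats::runif(1, 0.5, 2),
    e_met = stats::runif(1, 0.5, 2),
    e_nt = stats::runif(1, 0.5, 2),
    e_lip = stats::runif(1, 0.5, 2),
    b_aa = stats::runif(1, 0.5, 1.5),
    b_met = stats::runif(1, 0.1, 0.3),
    b_nt = stats::runif(1, 0.5, 1.5),
    b_lip = stats::runif(1, 0.5, 1.5),
    b_e = stats::runif(1, 1, 3)))

  mets <- lapply(c("carb_e", "carb_c", "e_c", "aa_c", "nt_c", "lip_c",
                   "met_e", "met_c", "byp_c", "byp_e"),
                 function(id) metabolite(id, compartment =
                   if (endsWith(id, "_e")) "e" else "c"))
  rxns <- list(
    reaction("EX_carb", c(carb_e = -1), lb = -carbon_uptake, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_met", c(met_e = -1), lb = -methionine_uptake, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_byp", c(byp_e = -1), lb = 0, ub = 1000,
             subsystem = "Exchange"),
    reaction("T_CARB", c(carb_e = -1, carb_c = 1), 0, 1000,
             subsystem = "Transport"),
    reaction("T_MET", c(met_e = -1, met_c = 1), -1000, 1000,
             subsystem = "Transport"),
    reaction("T_BYP", c(byp_c = -1, byp_e = 1), 0, 1000,
             subsystem = "Transport"),
    reaction("RESP", stats::setNames(c(-1, p$y_resp), c("carb_c", "e_c")),
             0, p$resp_cap, subsystem = "Energy metabolism"),
    reaction("FERM", stats::setNames(c(-1, p$y_ferm, 2),
                                     c("carb_c", "e_c", "byp_c")),
             0, 1000, subsystem = "Energy metabolism"),
    reaction("AASYN", stats::setNames(c(-1, -p$e_aa, 1),
                                      c("carb_c", "e_c", "aa_c")),
             0, 1000, subsystem = "Amino acid biosynthesis"),
    reaction("METSYN", stats::setNames(c(-1, -p$e_met, 1),
                                       c("carb_c", "e_c", "met_c")),
             0, 1000, subsystem = "Methionine metabolism",
             gene_rule = "metB"),
    reaction("NTSYN", stats::setNames(c(-1, -p$e_nt, 1),
                                      c("carb_c", "e_c", "nt_c")),
             0, 1000, subsystem = "Nucleotide biosynthesis"),
    reaction("LIPSYN", stats::setNames(c(-1, -p$e_lip, 1),
                                       c("carb_c", "e_c", "lip_c")),
             0, 1000, subsystem = "Lipid biosynthesis"),
    reaction("BIOMASS", stats::setNames(
      c(-p$b_aa, -p$b_met, -p$b_nt, -p$b_lip, -p$b_e),
      c("aa_c", "met_c", "nt_c", "lip_c", "e_c")),
      0, 1000, subsystem = "Biomass", is_pseudoreaction = TRUE))

  model <- metabolic_model(mets, rxns, c(BIOMASS = 1),
                           gene_rules = list(metB = "METSYN"),
                           id = sprintf("toy_host_seed%d", seed))
  if (carbon_uptake > 0) {
    sol <- fba(model)
    if (sol$status != "optimal" || sol$objective_value <= 1e-9)
      stop("degenerate toy host spec: no path to biomass")
  }
  model
}

#' Monomer table for toy hosts
#'
#' Maps every deoxynucleotide to the toy nucleotide pool `nt_c`, every
#' amino acid to `aa_c`, ATP to the toy energy carrier `e_c`, and omits
#' the remaining bookkeeping species (ids `NA`), so MGE pseudoreactions
#' built with [build_pseudoreaction()] attach to [make_toy_host()]
#' models. Masses are the defaults, so mass normalization is unchanged.
#'
#' @return a `monomer_table` data.frame.
#' @export
toy_monomer_table <- function() {
  tab <- default_monomer_table()
  tab$model_metabolite_id[tab$class == "nt"] <- "nt_c"
  tab$model_metabolite_id[tab$class == "aa"] <- "aa_c"
  tab$model_metabolite_id[tab$monomer == "atp"] <- "e_c"
  tab$model_metabolite_id[tab$class == "cofactor" & tab$monomer != "atp"] <- NA
  tab
}

#' The canonical hand-checkable toy MGE
#'
#' A 4-nucleotide ssDNA genome (`"ACGT"`, one copy, no replication
#' intermediates) plus one protein (`"MK"`, two copies) — small enough
#' that every pseudoreaction coefficient can be recomputed by hand, and
#' used as the shared oracle fixture across modules.
#'
#' @return list with `genome` ([mge_genome()]) and `proteome`.
#' @export
toy_mge_fixture <- function() {
  list(genome = mge_genome("ACGT", strandedness = "ssDNA", copy_number = 1L),
       proteome = list(protein_spec("toyP1", "MK", copy_number = 2L)))
}

#' Generate a random toy MGE composition
#'
#' Random nucleotide/protein sequences over the proper alphabets with
#' copy numbers in `[1, 100]`, reproducible by seed. The parameter combo
#' `genome_length = 4, n_proteins = 1` returns the canonical
#' [toy_mge_fixture()] so the hand-oracle instance is reachable through
#' the generator.
#'
#' @param seed RNG seed.
#' @param genome_length nucleotides in the (single-sequence) genome.
#' @param n_proteins number of proteins (0 allowed).
#' @param strandedness `"dsDNA"` or `"ssDNA"`.
#' @param max_protein_length longest protein sequence generated.
#' @return list with `genome` and `proteome` (as [toy_mge_fixture()]).
#' @export
make_toy_mge <- function(seed = 1729, genome_length = 30, n_proteins = 3,
                         strandedness = "dsDNA", max_protein_length = 30) {
  stopifnot(genome_length >= 1)
  if (genome_length == 4 && n_proteins == 1) return(toy_mge_fixture())
  with_seed(seed, {
    genome <- paste(sample(NT_ALPHABET, genome_length, replace = TRUE),
                    collapse = "")
    proteome <- lapply(seq_len(n_proteins), function(k) {
      len <- sample(2:max_protein_length, 1)
      protein_spec(sprintf("P%02d", k),
                   paste(sample(AA_ALPHABET, len, replace = TRUE),
                         collapse = ""),
                   copy_number = sample(1:100, 1))
    })
    list(genome = mge_genome(genome, strandedness = strandedness,
                             copy_number = 1L),
         proteome = proteome)
  })
}

#' Analytic conflict fixture
#'
#' A branch-point network in which the host objective and the MGE
#' pseudoreaction objective provably force disjoint flux ranges on a
#' known reaction set: a limited precursor feeds either a host
#' biosynthesis branch (ending in biomass) or an MGE precursor branch
#' (ending in the pseudoreaction), so at either optimum the entire
#' supply runs through one branch and the other is pinned at zero.
#' The certified ground truth (re-verifiable with [fva_oracle()]) is the
#' four branch/sink reactions; the shared uptake and transport reactions
#' carry identical ranges in both states.
#'
#' @param supply precursor uptake bound (default 10).
#' @param identical_objectives if `TRUE`, the "MGE" state optimizes the
#'   host biomass reaction itself (an element whose demands coincide
#'   with biomass), so the two states — and their FVA ranges — are
#'   identical and the expected conflict set is empty.
#' @return list with `model` (pseudoreaction attached), `host_objective`,
#'   `mge_objective`, `expected_conflicts` (character vector) and
#'   `expected_fractions` (named numeric, subsystem -> conflict
#'   fraction).
#' @export
make_conflict_fixture <- function(supply = 10, identical_objectives = FALSE) {
  mets <- list(metabolite("p_e", compartment = "e"), metabolite("p_c"),
               metabolite("hpre_c"), metabolite("mpre_c"))
  rxns <- list(
    reaction("EX_P", c(p_e = -1), lb = -supply, ub = 1000,
             subsystem = "Exchange"),
    reaction("T_P", c(p_e = -1, p_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("HOSTSYN", c(p_c = -1, hpre_c = 1), 0, 1000,
             subsystem = "Host biosynthesis"),
    reaction("MGESYN", c(p_c = -1, mpre_c = 1), 0, 1000,
             subsystem = "MGE precursor synthesis"),
    reaction("BIOMASS", c(hpre_c = -1), 0, 1000, subsystem = "Biomass",
             is_pseudoreaction = TRUE))
  model <- metabolic_model(mets, rxns, c(BIOMASS = 1), id = "conflict_fixture")
  mge_rxn <- reaction("MGE", c(mpre_c = -1), 0, 1000,
                      subsystem = "MGE production", is_pseudoreaction = TRUE)
  model <- attach_pseudoreaction(model, mge_rxn)

  if (identical_objectives) {
    expected <- character(0)
    fractions <- c("Biomass" = 0, "Exchange" = 0, "Host biosynthesis" = 0,
                   "MGE precursor synthesis" = 0, "MGE production" = 0,
                   "Transport" = 0)
    mge_obj <- "BIOMASS"
  } else {
    expected <- c("BIOMASS", "HOSTSYN", "MGE", "MGESYN")
    fractions <- c("Biomass" = 1, "Exchange" = 0, "Host biosynthesis" = 1,
                   "MGE precursor synthesis" = 1, "MGE production" = 1,
                   "Transport" = 0)
    mge_obj <- "MGE"
  }
  list(model = model, host_objective = "BIOMASS", mge_objective = mge_obj,
       expected_conflicts = expected, expected_fractions = fractions)
}

#' Single-species monoculture fixture with a closed-form yield
#'
#' One species growing on one carbon source with a fixed stoichiometric
#' yield `Y` gDW per mmol: once the carbon is exhausted the final biomass
#' is exactly `X0 + Y * C0` by mass balance, independent of step size —
#' the analytic check for the dynamic FBA bookkeeping.
#'
#' @param yield `Y`, gDW per mmol carbon.
#' @param carbon_mmol initial carbon `C0` in the pool.
#' @param x0 inoculum, gDW.
#' @param vmax uptake cap, mmol gDW^-1 hr^-1.
#' @param dt,n_cycles simulation schedule.
#' @return a [dfba_config()] with a single species `"mono"`.
#' @export
make_monoculture_fixture <- function(yield = 0.1, carbon_mmol = 2.78e-4,
                                     x0 = 1e-8, vmax = 10, dt = 1,
                                     n_cycles = 200) {
  mets <- list(metabolite("carb_e", compartment = "e"),
               metabolite("carb_c"))
  rxns <- list(
    reaction("EX_carb", c(carb_e = -1), lb = -1000, ub = 1000,
             subsystem = "Exchange"),
    reaction("T_CARB", c(carb_e = -1, carb_c = 1), 0, 1000,
             subsystem = "Transport"),
    reaction("BIOMASS", stats::setNames(-1 / yield, "carb_c"), 0, 1000,
             subsystem = "Biomass", is_pseudoreaction = TRUE))
  model <- metabolic_model(mets, rxns, c(BIOMASS = 1), id = "monoculture")
  dfba_config(list(species_state("mono", model, biomass = x0, vmax = vmax)),
              media = c(carb_e = carbon_mmol), dt = dt, n_cycles = n_cycles)
}

## internal: the two partner models of the mutualism fixture
mutualism_models <- function() {
  ## E: methionine auxotroph; consumes carbon, obligately exports an
  ## overflow byproduct (its only energy route), cannot make methionine.
  mets_e <- list(metabolite("carb_e", compartment = "e"), metabolite("carb_c"),
                 metabolite("met_e", compartment = "e"), metabolite("met_c"),
                 metabolite("byp_e", compartment = "e"), metabolite("byp_c"),
                 metabolite("e_c"), metabolite("min_e", compartment = "e"),
                 metabolite("min_c"))
  rxns_e <- list(
    reaction("EX_carb", c(carb_e = -1), -1000, 1000, subsystem = "Exchange"),
    reaction("EX_met", c(met_e = -1), -1000, 1000, subsystem = "Exchange"),
    reaction("EX_byp", c(byp_e = -1), 0, 1000, subsystem = "Exchange"),
    reaction("EX_min", c(min_e = -1), -1000, 1000, subsystem = "Exchange"),
    reaction("T_CARB", c(carb_e = -1, carb_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("T_MET", c(met_e = -1, met_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("T_BYP", c(byp_c = -1, byp_e = 1), 0, 1000, subsystem = "Transport"),
    reaction("T_MIN", c(min_e = -1, min_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("FERM", c(carb_c = -1, e_c = 1, byp_c = 2), 0, 1000,
             subsystem = "Energy metabolism"),
    reaction("BIOMASS_E", c(carb_c = -5, met_c = -0.01, e_c = -2,
                            min_c = -0.01),
             0, 1000, subsystem = "Biomass", is_pseudoreaction = TRUE))
  E <- metabolic_model(mets_e, rxns_e, c(BIOMASS_E = 1), id = "auxotroph_E")

  ## S: methionine secretor; grows on the byproduct (cannot use the
  ## primary carbon source at all) and exports 0.5 mmol methionine per
  ## gram of biomass, with methionine reuptake blocked.
  mets_s <- list(metabolite("byp_e", compartment = "e"), metabolite("byp_c"),
                 metabolite("met_e", compartment = "e"), metabolite("e_c"),
                 metabolite("min_e", compartment = "e"), metabolite("min_c"))
  rxns_s <- list(
    reaction("EX_byp", c(byp_e = -1), -1000, 1000, subsystem = "Exchange"),
    reaction("EX_met", c(met_e = -1), 0, 1000, subsystem = "Exchange"),
    reaction("EX_min", c(min_e = -1), -1000, 1000, subsystem = "Exchange"),
    reaction("T_BYP", c(byp_e = -1, byp_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("T_MIN", c(min_e = -1, min_c = 1), 0, 1000, subsystem = "Transport"),
    reaction("RESP", c(byp_c = -1, e_c = 1), 0, 1000,
             subsystem = "Energy metabolism"),
    reaction("BIOMASS_S", c(byp_c = -3, e_c = -1, min_c = -0.01, met_e = 0.5),
             0, 1000, subsystem = "Biomass", is_pseudoreaction = TRUE))
  S <- metabolic_model(mets_s, rxns_s, c(BIOMASS_S = 1), id = "secretor_S")
  list(E = E, S = S)
}

#' Two-species cross-feeding mutualism fixture
#'
#' A methionine auxotroph ("E", consumes the carbon source, obligately
#' excretes an overflow byproduct) and a methionine secretor ("S", grows
#' only on that byproduct and exports 0.5 mmol methionine per gram of
#' biomass, reuptake blocked). The media carry the carbon source, excess
#' mineral nutrient, and a vanishing trace of methionine (5e-13 mmol) to
#' seed the cross-feeding loop: neither species can grow appreciably
#' alone, together both grow by orders of magnitude.
#'
#' An optional MGE burden on the auxotroph is expressed by attaching the
#' canonical toy-element pseudoreaction (mapped onto the auxotroph's
#' carbon and energy pools) with a forced lower bound.
#'
#' @param mge_lb forced MGE production by the auxotroph,
#'   mmol gDW^-1 hr^-1 (0 = no burden).
#' @param carbon_mmol carbon in the pool (default 2.78e-4 mmol).
#' @param x0 per-species inoculum (default 1e-8 gDW).
#' @param dt,n_cycles simulation schedule (defaults 1 h, 200 cycles).
#' @param species `"both"`, `"E"` or `"S"` — which species to inoculate
#'   (solo configs for the no-growth-alone checks).
#' @return a [dfba_config()].
#' @export
make_mutualism_fixture <- function(mge_lb = 0, carbon_mmol = 2.78e-4,
                                   x0 = 1e-8, dt = 1, n_cycles = 200,
                                   species = c("both", "E", "S")) {
  species <- match.arg(species)
  mod <- mutualism_models()
  E <- mod$E
  if (mge_lb > 0) {
    tab <- toy_monomer_table()
    tab$model_metabolite_id[tab$class %in% c("nt", "aa")] <- "carb_c"
    fix <- toy_mge_fixture()
    pr <- build_pseudoreaction(fix$genome, fix$proteome, tab, id = "MGE")
    E <- attach_pseudoreaction(E, pr$reaction, lower_bound = mge_lb)
  }
  sp <- switch(species,
    both = list(species_state("E", E, biomass = x0),
                species_state("S", mod$S, biomass = x0)),
    E = list(species_state("E", E, biomass = x0)),
    S = list(species_state("S", mod$S, biomass = x0)))
  media <- c(carb_e = carbon_mmol, met_e = 5e-13, byp_e = 0, min_e = 1000)
  dfba_config(sp, media, dt = dt, n_cycles = n_cycles)
}
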