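#' Reproduce the genome-scale host-MGE conflict analysis
#'
#' End-to-end recipe for the full-size analysis on a real host model
#' (E. coli iJO1366 with the metB knockout) and MGE compositions derived
#' from public sequence records: builds the plasmid and phage biomass
#' pseudoreactions from user-supplied FASTA/TSV composition inputs,
#' attaches both to the host, runs FVA in the host-optimized,
#' plasmid-optimized and phage-optimized carriage states, and reports the
#' conflict counts plus the number of pFBA direction-change drops.
#'
#' The required inputs are large public downloads and are deliberately
#' not bundled; place them under `input_dir`:
#' \describe{
#'   \item{`model.json`}{host model in the JSON dialect (e.g. iJO1366
#'     from BiGG).}
#'   \item{`plasmid_genome.fasta`, `plasmid_proteins.fasta`,
#'     `plasmid_copies.tsv`}{conjugative plasmid composition (genome,
#'     per-protein sequences, copy numbers — e.g. F128 with the Tn10
#'     tetracycline genes; pilus protein copies from
#'     [pilin_copy_number()] scaling or an explicit table).}
#'   \item{`phage_genome.fasta`, `phage_proteins.fasta`,
#'     `phage_copies.tsv`}{filamentous phage composition (e.g. M13; the
#'     ssDNA genome gets its double-stranded replicative form as the
#'     replication intermediate).}
#' }
#'
#' Expect roughly 2,585 reactions after attaching both pseudoreactions
#' to iJO1366, and a runtime of minutes-to-hours for FVA over all
#' reactions x 2 state comparisons with the pure-R solver.
#'
#' @param input_dir directory holding the inputs above.
#' @param biomass_id host biomass reaction id.
#' @param plasmid_lb,phage_lb carriage-state bounds
#'   (defaults 0.9 and 0.06 mmol gDW^-1 hr^-1).
#' @param fraction_of_optimum FVA fraction of optimum.
#' @return list with `total_reactions`, `n_conflict_plasmid`,
#'   `n_conflict_both`, `n_unique_both` (conflicts present only in the
#'   double-carriage state), `n_direction_drops`, and the underlying
#'   `conflict_plasmid`/`conflict_both` reports.
#' @export
reproduce_genome_scale_conflicts <- function(input_dir,
                                             biomass_id = "BIOMASS_Ec_iJO1366_core_53p95M",
                                             plasmid_lb = 0.9,
                                             phage_lb = 0.06,
                                             fraction_of_optimum = 1.0) {
  need <- c("model.json", "plasmid_genome.fasta", "plasmid_proteins.fasta",
            "plasmid_copies.tsv", "phage_genome.fasta",
            "phage_proteins.fasta", "phage_copies.tsv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("genome-scale reproduction inputs missing from '", input_dir,
         "': ", paste(missing, collapse = ", "),
         " (these are public downloads; see ?reproduce_genome_scale_conflicts)")

  host <- read_model(file.path(input_dir, "model.json"))
  ## metB is locus b3939 in iJO1366's gene namespace
  kn <- intersect(c("b3939", "metB"), names(host$gene_rules))
  if (length(kn) == 0L)
    stop("host model carries no metB/b3939 gene rule; knock the ",
         "cystathionine gamma-synthase reaction out manually")
  host <- knock_out(host, kn[1L])
  plasmid <- read_mge_spec(file.path(input_dir, "plasmid_genome.fasta"),
                           file.path(input_dir, "plasmid_proteins.fasta"),
                           file.path(input_dir, "plasmid_copies.tsv"),
                           strandedness = "dsDNA")
  phage <- read_mge_spec(file.path(input_dir, "phage_genome.fasta"),
                         file.path(input_dir, "phage_proteins.fasta"),
                         file.path(input_dir, "phage_copies.tsv"),
                         strandedness = "ssDNA", replicative_form = TRUE)
  pl <- build_pseudoreaction(plasmid$genome, plasmid$proteome,
                             id = "F128_biomass")
  ph <- build_pseudoreaction(phage$genome, phage$proteome,
                             id = "M13_biomass")
  model <- attach_pseudoreaction(host, pl$reaction)
  model <- attach_pseudoreaction(model, ph$reaction)

  states <- standard_carriage_states(biomass_id, "F128_biomass",
                                     "M13_biomass", plasmid_lb, phage_lb)
  m_host <- set_carriage_state(model, states$WT)
  m_plas <- set_carriage_state(model, states$plasmid_optimized)
  m_phag <- set_carriage_state(model, states$phage_optimized)

  fva_host <- fva(m_host, fraction_of_optimum)
  fva_plas <- fva(m_plas, fraction_of_optimum)
  fva_phag <- fva(m_phag, fraction_of_optimum)
  rep_plas <- find_conflicts(fva_host, fva_plas, model)
  rep_both <- find_conflicts(fva_host, fva_phag, model)
  unique_both <- setdiff(rep_both$conflict_reactions,
                         rep_plas$conflict_reactions)

  demand <- subsystem_demand_fold_change(pfba(m_phag), pfba(m_host), model)

  list(total_reactions = length(model$reactions),
       n_conflict_plasmid = length(rep_plas$conflict_reactions),
       n_conflict_both = length(rep_both$conflict_reactions),
       n_unique_both = length(unique_both),
       n_direction_drops = length(demand$dropped_reactions),
       conflict_plasmid = rep_plas, conflict_both = rep_both,
       demand = demand)
}
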