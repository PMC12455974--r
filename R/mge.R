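## Composition -> biomass pseudoreaction for a mobile genetic element.
##
## The stoichiometry follows the intracellular-parasite integration scheme:
## total monomer counts per particle are converted to grams via monomer
## molar masses, then normalized by the particle's total molar mass and
## scaled by 1000, giving coefficients in mmol per gram of MGE. One unit
## of pseudoreaction flux therefore drains exactly one gram of MGE worth
## of monomers (mmol gDW^-1 hr^-1 flux units, like any other reaction).

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
                 "M","F","P","S","T","W","Y","V")
NT_ALPHABET <- c("A","C","G","T")

#' Genome composition of a mobile genetic element
#'
#' @param sequences character vector of primary genome nucleotide
#'   sequences (5'->3', alphabet ACGT).
#' @param strandedness `"dsDNA"` (e.g. a conjugative plasmid) or
#'   `"ssDNA"` (e.g. a filamentous phage). dsDNA sequences contribute
#'   both strands to the nucleotide counts.
#' @param copy_number genome copies per MGE particle (`C_g >= 1`).
#' @param intermediates nucleotide sequences of replication intermediates
#'   counted in addition to the genome, as written (no automatic
#'   complementing). For ssDNA phage, `replicative_form = TRUE` is the
#'   usual way to add the double-stranded replicative form instead.
#' @param replicative_form if `TRUE` and `strandedness == "ssDNA"`, one
#'   complementary-strand copy of each primary sequence is added as a
#'   replication intermediate.
#' @return an `mge_genome` list.
#' @export
mge_genome <- function(sequences, strandedness = c("dsDNA", "ssDNA"),
                       copy_number = 1L, intermediates = character(0),
                       replicative_form = FALSE) {
  strandedness <- match.arg(strandedness)
  sequences <- toupper(sequences)
  intermediates <- toupper(intermediates)
  check_alphabet(c(sequences, intermediates), NT_ALPHABET, "nucleotide")
  if (copy_number < 1) stop("copy_number (C_g) must be >= 1")
  if (replicative_form) {
    if (strandedness != "ssDNA")
      stop("replicative_form applies to ssDNA genomes only")
    intermediates <- c(intermediates, vapply(sequences, revcomp, ""))
  }
  structure(list(sequences = sequences, strandedness = strandedness,
                 copy_number = as.integer(copy_number),
                 intermediates = intermediates),
            class = "mge_genome")
}

#' A protein of an MGE proteome
#'
#' @param protein_id identifier.
#' @param sequence amino-acid sequence (20-letter alphabet).
#' @param copy_number copies per MGE particle (`C_k >= 0`).
#' @return a `protein_spec` list.
#' @export
protein_spec <- function(protein_id, sequence, copy_number = 1L) {
  sequence <- toupper(sequence)
  if (copy_number < 0) stop("copy_number (C_k) must be >= 0")
  if (copy_number > 0 && !nzchar(sequence))
    stop("protein '", protein_id, "': empty sequence with positive copy number")
  check_alphabet(sequence, AA_ALPHABET, "amino-acid")
  structure(list(protein_id = protein_id, sequence = sequence,
                 copy_number = as.numeric(copy_number)),
            class = "protein_spec")
}

check_alphabet <- function(seqs, alphabet, what) {
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(ch), alphabet)
    if (length(bad) > 0L)
      stop("invalid ", what, " character(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

count_chars <- function(seqs, alphabet) {
  counts <- stats::setNames(numeric(length(alphabet)), alphabet)
  for (s in seqs) {
    if (!nzchar(s)) next
    tab <- table(strsplit(s, "")[[1]])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts
}

#' Total nucleotide counts of an MGE particle
#'
#' Computes `N_i_tot = C_g * (N_i_genome + N_i_intermediates)` for each of
#' the four deoxynucleotides. dsDNA primary sequences contribute both the
#' given strand and its complement; intermediates are counted as written.
#'
#' @param genome an [mge_genome()].
#' @return named numeric vector over `A, C, G, T`.
#' @export
count_nucleotides <- function(genome) {
  stopifnot(inherits(genome, "mge_genome"))
  primary <- count_chars(genome$sequences, NT_ALPHABET)
  if (genome$strandedness == "dsDNA") {
    comp <- count_chars(vapply(genome$sequences, revcomp, ""), NT_ALPHABET)
    primary <- primary + comp
  }
  inter <- count_chars(genome$intermediates, NT_ALPHABET)
  genome$copy_number * (primary + inter)
}

#' Total amino-acid counts of an MGE particle
#'
#' `AA_j_tot = sum_k C_k * AA_j_k`: residue counts of each protein scaled
#' by its per-particle copy number and summed over the proteome.
#'
#' @param proteome list of [protein_spec()] objects (may be empty).
#' @return named numeric vector over the 20 amino acids.
#' @export
count_amino_acids <- function(proteome) {
  counts <- stats::setNames(numeric(20L), AA_ALPHABET)
  for (p in proteome) {
    stopifnot(inherits(p, "protein_spec"))
    if (p$copy_number == 0) next
    counts <- counts + p$copy_number * count_chars(p$sequence, AA_ALPHABET)
  }
  counts
}

#' Polymerization energy and byproduct counts
#'
#' ATP demand is `atp_per_aa` (default 4, the expected ATP per peptide
#' bond) times the *total* amino-acid count; pyrophosphate release is
#' `ppi_per_nt` (default 1) per incorporated nucleotide, replication
#' intermediates included.
#'
#' @param nt_counts,aa_counts outputs of [count_nucleotides()] and
#'   [count_amino_acids()].
#' @param atp_per_aa ATP molecules per amino acid polymerized.
#' @param ppi_per_nt PPi molecules per nucleotide polymerized.
#' @return list with `atp` and `ppi` counts per MGE particle.
#' @export
polymerization_costs <- function(nt_counts, aa_counts,
                                 atp_per_aa = 4, ppi_per_nt = 1) {
  if (any(nt_counts < 0) || any(aa_counts < 0))
    stop("monomer counts must be nonnegative")
  list(atp = atp_per_aa * sum(aa_counts),
       ppi = ppi_per_nt * sum(nt_counts))
}

#' Default monomer table (BiGG-style identifiers, free-monomer masses)
#'
#' Maps the 4 deoxynucleotides and 20 amino acids, plus the energy
#' bookkeeping species (ATP, ADP, Pi, PPi, H2O, H+), to model metabolite
#' ids and molar masses (g/mol). Masses are those of the consumed free
#' monomers (dNTPs and free amino acids), applied consistently in both
#' the gram conversion and the total molar mass so the mass-normalization
#' identity holds exactly. Every field can be overridden, or individual
#' ids set to `NA` to omit that species when attaching to a reduced model.
#'
#' @return a `monomer_table` data.frame with columns `monomer`, `class`
#'   (`"nt"`, `"aa"`, `"cofactor"`), `molar_mass`, `model_metabolite_id`.
#' @export
default_monomer_table <- function() {
  nt <- data.frame(
    monomer = NT_ALPHABET, class = "nt",
    molar_mass = c(491.18, 467.16, 507.18, 482.17),
    model_metabolite_id = c("datp_c", "dctp_c", "dgtp_c", "dttp_c"),
    stringsAsFactors = FALSE)
  aa_mass <- c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
               Q = 146.15, E = 147.13, G = 75.07, H = 155.15, I = 131.17,
               L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
               S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15)
  aa_id <- c(A = "ala__L_c", R = "arg__L_c", N = "asn__L_c", D = "asp__L_c",
             C = "cys__L_c", Q = "gln__L_c", E = "glu__L_c", G = "gly_c",
             H = "his__L_c", I = "ile__L_c", L = "leu__L_c", K = "lys__L_c",
             M = "met__L_c", F = "phe__L_c", P = "pro__L_c", S = "ser__L_c",
             T = "thr__L_c", W = "trp__L_c", Y = "tyr__L_c", V = "val__L_c")
  aa <- data.frame(monomer = AA_ALPHABET, class = "aa",
                   molar_mass = unname(aa_mass[AA_ALPHABET]),
                   model_metabolite_id = unname(aa_id[AA_ALPHABET]),
                   stringsAsFactors = FALSE)
  cof <- data.frame(
    monomer = c("atp", "adp", "pi", "ppi", "h2o", "h"), class = "cofactor",
    molar_mass = NA_real_,
    model_metabolite_id = c("atp_c", "adp_c", "pi_c", "ppi_c", "h2o_c", "h_c"),
    stringsAsFactors = FALSE)
  structure(rbind(nt, aa, cof), class = c("monomer_table", "data.frame"))
}

## one-letter monomer codes collide across classes (A is both dATP and
## alanine), so every lookup is class-scoped
monomer_mass <- function(table, monomers, class) {
  sub <- table[table$class == class, ]
  i <- match(monomers, sub$monomer)
  if (anyNA(i)) stop("monomer table is missing ", class, " entries: ",
                     paste(monomers[is.na(i)], collapse = ", "))
  m <- sub$molar_mass[i]
  if (anyNA(m) || any(m <= 0)) stop("missing or nonpositive monomer mass")
  stats::setNames(m, monomers)
}

monomer_id <- function(table, monomers, class) {
  sub <- table[table$class == class, ]
  i <- match(monomers, sub$monomer)
  if (anyNA(i)) stop("monomer table is missing ", class, " entries: ",
                     paste(monomers[is.na(i)], collapse = ", "))
  stats::setNames(sub$model_metabolite_id[i], monomers)
}

#' Total molar mass of an MGE particle
#'
#' Sum of monomer counts times monomer molar masses over the genome and
#' proteome components, in g per mol of MGE particle.
#'
#' @param nt_counts,aa_counts monomer counts per particle.
#' @param table a [default_monomer_table()]-shaped monomer table.
#' @return scalar, g/mol.
#' @export
total_molar_mass <- function(nt_counts, aa_counts, table = default_monomer_table()) {
  sum(nt_counts * monomer_mass(table, names(nt_counts), "nt")) +
    sum(aa_counts * monomer_mass(table, names(aa_counts), "aa"))
}

#' Build the biomass pseudoreaction of a mobile genetic element
#'
#' Converts per-particle monomer counts into stoichiometric coefficients
#' in mmol per gram of MGE (`count / total_molar_mass * 1000`) and
#' assembles the irreversible pseudoreaction: dNTPs, amino acids, ATP and
#' H2O are consumed; ADP, H+, Pi (one each per ATP hydrolysed) and PPi
#' (one per nucleotide) are produced. One unit of flux through the
#' reaction produces one gram of MGE per gram dry weight per hour.
#'
#' @param genome an [mge_genome()].
#' @param proteome list of [protein_spec()] objects.
#' @param table monomer table mapping monomers to model metabolite ids
#'   and masses; ids that are `NA` are omitted from the reaction.
#' @param id reaction id for the pseudoreaction.
#' @param atp_per_aa ATP per amino acid; default 4. With
#'   `atp_per_bond = TRUE` the cost is instead `atp_per_aa * (len_k - 1)`
#'   per protein k (peptide-bond counting, for sensitivity analysis).
#' @param atp_per_bond see above; default `FALSE`.
#' @param lb,ub bounds of the pseudoreaction (default `[0, 1000]`).
#' @param subsystem subsystem label for the pseudoreaction.
#' @return list with `spec` (a `pseudoreaction_spec`: all coefficients in
#'   mmol/g plus `total_molar_mass` in g/mol) and `reaction` (a
#'   [reaction()] ready for [attach_pseudoreaction()]).
#' @export
build_pseudoreaction <- function(genome, proteome,
                                 table = default_monomer_table(),
                                 id = "MGE_biomass",
                                 atp_per_aa = 4, atp_per_bond = FALSE,
                                 lb = 0, ub = 1000,
                                 subsystem = "MGE production") {
  nt <- count_nucleotides(genome)
  aa <- count_amino_acids(proteome)
  if (sum(nt) + sum(aa) == 0) stop("empty MGE composition")
  atp_count <- if (atp_per_bond) {
    sum(vapply(proteome, function(p)
      p$copy_number * atp_per_aa * max(nchar(p$sequence) - 1L, 0L), 0))
  } else {
    polymerization_costs(nt, aa, atp_per_aa = atp_per_aa)$atp
  }
  ppi_count <- polymerization_costs(nt, aa)$ppi
  M <- total_molar_mass(nt, aa, table)

  to_mmol_per_g <- function(count) count / M * 1000
  spec <- structure(list(
    nucleotide_coeffs = to_mmol_per_g(nt),
    aa_coeffs = to_mmol_per_g(aa),
    atp_coeff = to_mmol_per_g(atp_count),
    h2o_coeff = to_mmol_per_g(atp_count),   # ATP + H2O -> ADP + Pi + H+
    adp_coeff = to_mmol_per_g(atp_count),
    pi_coeff = to_mmol_per_g(atp_count),
    h_coeff = to_mmol_per_g(atp_count),
    ppi_coeff = to_mmol_per_g(ppi_count),
    total_molar_mass = M), class = "pseudoreaction_spec")

  ids <- c(monomer_id(table, names(nt), "nt"),
           monomer_id(table, names(aa), "aa"),
           monomer_id(table, c("atp", "h2o", "adp", "pi", "h", "ppi"),
                      "cofactor"))
  coef <- c(-spec$nucleotide_coeffs, -spec$aa_coeffs,
            -spec$atp_coeff, -spec$h2o_coeff,
            spec$adp_coeff, spec$pi_coeff, spec$h_coeff, spec$ppi_coeff)
  keep <- !is.na(ids) & coef != 0
  stoich <- tapply(coef[keep], ids[keep], sum)   # merge monomers sharing an id
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  if (length(stoich) == 0L) stop("no monomer maps to a model metabolite id")
  rxn <- reaction(id, stoich, lb = lb, ub = ub, subsystem = subsystem,
                  is_exchange = FALSE, is_pseudoreaction = TRUE)
  list(spec = spec, reaction = rxn)
}

#' Pilin copy number from pilus geometry
#'
#' The conjugative pilus is a 5-start helix with a fixed number of
#' propilin (traA) subunits per helical turn; given a total pilus length
#' and the axial pitch per turn, the subunit copy number is
#' `round(length_um * 1000 / pitch_per_turn_nm * subunits_per_turn)`.
#' Copy numbers of the other pilus proteins are conventionally scaled
#' from this value via a user-supplied ratio table.
#'
#' @param total_length_um total pilus length in micrometers (>= 0).
#' @param subunits_per_turn propilin subunits per helical turn
#'   (default 12.8).
#' @param pitch_per_turn_nm axial rise per helical turn in nm (> 0); not
#'   a universal constant — supply the value for the pilus at hand.
#' @return integer copy number.
#' @export
pilin_copy_number <- function(total_length_um, subunits_per_turn = 12.8,
                              pitch_per_turn_nm) {
  if (pitch_per_turn_nm <= 0) stop("pitch_per_turn_nm must be > 0")
  if (total_length_um < 0) stop("total_length_um must be >= 0")
  as.integer(round(total_length_um * 1000 / pitch_per_turn_nm * subunits_per_turn))
}

#' Attach an MGE pseudoreaction to a host model
#'
#' @param model a [metabolic_model()].
#' @param rxn the pseudoreaction from [build_pseudoreaction()].
#' @param lower_bound,upper_bound bounds applied on attachment
#'   (default `[0, 1000]`).
#' @return a copy of the model with the reaction added
#'   (`is_pseudoreaction = TRUE`); errors on id collision or on
#'   metabolites absent from the model.
#' @export
attach_pseudoreaction <- function(model, rxn, lower_bound = 0,
                                  upper_bound = 1000) {
  stopifnot(inherits(rxn, "reaction"))
  if (rxn$id %in% names(model$reactions))
    stop("reaction id '", rxn$id, "' already present in model")
  missing <- setdiff(names(rxn$stoichiometry), names(model$metabolites))
  if (length(missing) > 0L)
    stop("model lacks metabolite(s): ", paste(missing, collapse = ", "))
  rxn$lb <- lower_bound; rxn$ub <- upper_bound
  rxn$is_pseudoreaction <- TRUE
  model$reactions[[rxn$id]] <- rxn
  model
}
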