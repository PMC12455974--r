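## Readers and writers: the community constraint-based JSON model dialect
## (BiGG-style, so genome-scale models such as iJO1366 load unchanged),
## FASTA/TSV/YAML composition inputs, media tables, and TSV reports.

#' Read a metabolic model
#'
#' The JSON dialect mirrors the community constraint-based schema
#' (`metabolites`/`reactions` with `lower_bound`, `upper_bound`,
#' `subsystem`, `objective_coefficient`, gene rules), so models
#' distributed by BiGG load unchanged. `dialect = "sbml"` converts
#' through the COBRApy Python library when a `python` with `cobra` is on
#' the PATH, and errors informatively otherwise.
#'
#' @param path model file.
#' @param dialect `"json"` (default) or `"sbml"`.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("json", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "sbml") {
    json <- tempfile(fileext = ".json")
    on.exit(unlink(json))
    code <- sprintf(
      "import cobra, cobra.io; cobra.io.save_json_model(cobra.io.read_sbml_model(%s), %s)",
      deparse(path), deparse(json))
    ok <- tryCatch(system2("python", c("-c", shQuote(code))) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(json))
      stop("SBML conversion requires a 'python' with the cobra package on the PATH; ",
           "convert the model to the JSON dialect instead")
    path <- json
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("'", path, "': not a constraint-based model JSON (missing ",
         "metabolites/reactions)")
  mets <- lapply(doc$metabolites, function(m)
    metabolite(m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c"))
  objective <- numeric(0)
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    reaction(r$id, st,
             lb = r$lower_bound %||% 0, ub = r$upper_bound %||% 1000,
             subsystem = r$subsystem %||% "",
             is_exchange = if (!is.null(r$is_exchange)) r$is_exchange else NULL,
             is_pseudoreaction = isTRUE(r$is_pseudoreaction),
             gene_rule = r$gene_reaction_rule %||% "")
  })
  for (r in doc$reactions) {
    oc <- r$objective_coefficient %||% 0
    if (oc != 0) objective[r$id] <- oc
  }
  if (length(objective) == 0L)
    stop("'", path, "': model declares no objective reaction")
  gene_rules <- list()
  for (r in doc$reactions) {
    gr <- r$gene_reaction_rule %||% ""
    if (nzchar(gr)) {
      genes <- unique(unlist(strsplit(gr, "[^A-Za-z0-9_.-]+")))
      genes <- setdiff(genes, c("and", "or", ""))
      for (g in genes) gene_rules[[g]] <- c(gene_rules[[g]], r$id)
    }
  }
  metabolic_model(mets, rxns, objective, gene_rules = gene_rules,
                  id = doc$id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to the JSON dialect
#'
#' Inverse of [read_model()]: `read_model(write_model(m, path))` is
#' structurally identical to `m` (bounds, subsystems, objective, flags).
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, name = m$name, compartment = m$compartment)),
    reactions = lapply(unname(model$reactions), function(r) {
      oc <- if (r$id %in% names(model$objective))
        unname(model$objective[r$id]) else 0
      list(id = r$id, metabolites = as.list(r$stoichiometry),
           lower_bound = r$lb, upper_bound = r$ub,
           subsystem = r$subsystem, gene_reaction_rule = r$gene_rule,
           objective_coefficient = oc, is_exchange = r$is_exchange,
           is_pseudoreaction = r$is_pseudoreaction)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))   # first token of header
  seqs
}

#' Read an MGE composition spec from FASTA + TSV files
#'
#' @param genome_fasta FASTA with the genome nucleotide sequence(s).
#' @param protein_fasta FASTA with the per-protein amino-acid sequences
#'   (record ids must match the copy-number table); may be omitted
#'   together with `copy_tsv` for a protein-free element.
#' @param copy_tsv TSV with columns `protein_id`, `copy_number`; every
#'   protein in the FASTA must appear here.
#' @param strandedness,copy_number,replicative_form passed to
#'   [mge_genome()].
#' @return list with `genome` and `proteome`, ready for
#'   [build_pseudoreaction()].
#' @export
read_mge_spec <- function(genome_fasta, protein_fasta = NULL,
                          copy_tsv = NULL,
                          strandedness = c("dsDNA", "ssDNA"),
                          copy_number = 1L, replicative_form = FALSE) {
  strandedness <- match.arg(strandedness)
  genome <- mge_genome(unname(read_fasta(genome_fasta, "DNA")),
                       strandedness = strandedness,
                       copy_number = copy_number,
                       replicative_form = replicative_form)
  proteome <- list()
  if (!is.null(protein_fasta)) {
    seqs <- read_fasta(protein_fasta, "AA")
    if (is.null(copy_tsv)) stop("protein FASTA given without a copy-number TSV")
    tab <- utils::read.delim(copy_tsv, stringsAsFactors = FALSE)
    if (!all(c("protein_id", "copy_number") %in% names(tab)))
      stop("copy-number TSV must have columns protein_id, copy_number")
    missing <- setdiff(names(seqs), tab$protein_id)
    if (length(missing) > 0L)
      stop("protein(s) missing from copy-number table: ",
           paste(missing, collapse = ", "))
    proteome <- lapply(names(seqs), function(id)
      protein_spec(id, seqs[[id]],
                   tab$copy_number[match(id, tab$protein_id)]))
  }
  list(genome = genome, proteome = proteome)
}

#' Read an MGE composition spec from a single YAML file
#'
#' Schema: top-level `genome` (`sequences`, `strandedness`,
#' `copy_number`, optional `intermediates`, `replicative_form`) and
#' `proteins` (list of `id`/`sequence`/`copy_number` entries).
#'
#' @param path YAML file.
#' @return list with `genome` and `proteome`.
#' @export
read_mge_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$genome)) stop("'", path, "': no genome section")
  g <- doc$genome
  genome <- mge_genome(unlist(g$sequences),
                       strandedness = g$strandedness %||% "dsDNA",
                       copy_number = g$copy_number %||% 1L,
                       intermediates = unlist(g$intermediates) %||% character(0),
                       replicative_form = isTRUE(g$replicative_form))
  proteome <- lapply(doc$proteins %||% list(), function(p)
    protein_spec(p$id, p$sequence, p$copy_number %||% 1L))
  list(genome = genome, proteome = proteome)
}

#' Read a monomer table from TSV
#'
#' Columns: `monomer`, `class`, `molar_mass`, `model_metabolite_id`
#' (empty/`NA` id = omit that species), as in
#' [default_monomer_table()].
#'
#' @param path TSV file.
#' @return a `monomer_table` data.frame.
#' @export
read_monomer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("monomer", "class", "molar_mass", "model_metabolite_id")
  if (!all(need %in% names(tab)))
    stop("monomer table must have columns: ", paste(need, collapse = ", "))
  structure(tab[need], class = c("monomer_table", "data.frame"))
}

#' Read a media composition table
#'
#' Either a TSV with columns `metabolite_id`, `mmol`, or a YAML mapping
#' of metabolite id to mmol.
#'
#' @param path file; format chosen by extension (`.yml`/`.yaml` = YAML).
#' @return named numeric vector, metabolite id -> mmol.
#' @export
read_media <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    return(stats::setNames(vapply(doc, as.numeric, 0), names(doc)))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "mmol") %in% names(tab)))
    stop("media TSV must have columns metabolite_id, mmol")
  stats::setNames(tab$mmol, tab$metabolite_id)
}

#' Write a conflict report as TSV
#'
#' Two files: `<path>` with the per-reaction table (id, subsystem, host
#' range, MGE range, conflict flag; rows sorted by reaction id) and
#' `<path base>_subsystems.tsv` with the per-subsystem tallies.
#'
#' @param report a `conflict_report`.
#' @param fva_host,fva_mge the range sets the report was built from.
#' @param model the model (subsystem labels).
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_conflict_report <- function(report, fva_host, fva_mge, model, path) {
  ids <- sort(fva_host$reaction_id)
  tab <- data.frame(
    reaction_id = ids,
    subsystem = reaction_subsystems(model)[ids],
    host_min = fva_host[ids, "min_flux"], host_max = fva_host[ids, "max_flux"],
    mge_min = fva_mge[ids, "min_flux"], mge_max = fva_mge[ids, "max_flux"],
    conflict = ids %in% report$conflict_reactions,
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sub_path <- sub("(\\.tsv)?$", "_subsystems.tsv", path)
  utils::write.table(report$per_subsystem, sub_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pseudoreaction as a human-readable stoichiometry TSV
#'
#' @param built output of [build_pseudoreaction()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_pseudoreaction_tsv <- function(built, path) {
  st <- built$reaction$stoichiometry
  tab <- data.frame(metabolite_id = names(st),
                    coefficient_mmol_per_g = as.numeric(st),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$metabolite_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dynamic FBA trajectory as tidy TSV
#'
#' @param traj a `dfba_trajectory`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
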