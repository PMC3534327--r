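# Secretome construction and domain-architecture classification.
#
# Starting from proteins with a signal peptide and no effective TM segment
# (SP_only), proteins whose yeast/mouse orthologs place them in an
# endomembrane compartment are removed (unless whitelisted as known
# extracellular proteins that merely transit the pathway), and proteins with
# mitochondrial evidence are removed as a group. The remainder is the
# putative secretome.

ENDOMEMBRANE_DEFAULT <- c("ER", "Golgi", "endosome", "lysosome", "peroxisome",
                          "vesicle")

#' Transfer subcellular localization by orthology
#'
#' Each study-species protein inherits every compartment of every yeast or
#' mouse source protein it is orthologous to. Proteins without evidence are
#' absent from the map.
#'
#' @param evidence a localization-evidence data frame
#'   ([read_localization_evidence()]).
#' @return named list: protein id -> character vector of compartments.
#' @export
transfer_localization <- function(evidence) {
  map <- list()
  for (i in seq_len(nrow(evidence))) {
    for (id in evidence$ortholog_gene_ids[[i]]) {
      map[[id]] <- union(map[[id]], evidence$compartment[i])
    }
  }
  map
}

#' Build the putative secretome
#'
#' Partitions the SP_only set into three disjoint sets: removed
#' endomembrane-resident proteins, removed (potentially) mitochondrial
#' proteins, and the remaining putative secretome. The mitochondrial removal
#' is all-or-nothing: any protein with mitochondrial evidence is removed,
#' with no whitelist override. The extracellular whitelist only rescues
#' proteins from the endomembrane removal (known secreted proteins are only
#' transiently present in the ER/Golgi).
#'
#' @param topology a `topology_table` from [reconcile_topology()].
#' @param localization_map named list from [transfer_localization()].
#' @param extracellular_whitelist ids of known extracellular proteins.
#' @param endomembrane_compartments compartments counting as endomembrane.
#' @param mito_compartment the mitochondrial compartment label.
#' @return an object of class `secretome_result` with character-vector
#'   fields `secretome`, `removed_endomembrane`, `removed_mitochondrial`,
#'   `sp_only_input`.
#' @export
build_secretome <- function(topology, localization_map = list(),
                            extracellular_whitelist = character(0),
                            endomembrane_compartments = ENDOMEMBRANE_DEFAULT,
                            mito_compartment = "mitochondrion") {
  sp_only <- topology$protein_id[topology$topology_class == "SP_only"]
  stray <- setdiff(extracellular_whitelist, sp_only)
  if (length(stray)) {
    warning("whitelisted protein(s) not in the SP-only set: ",
            paste(stray, collapse = ", "), call. = FALSE)
  }
  comp <- localization_map[sp_only]
  names(comp) <- sp_only
  is_mito <- vapply(comp, function(x) mito_compartment %in% x, logical(1))
  is_endo <- vapply(comp, function(x) {
    length(intersect(x, endomembrane_compartments)) > 0
  }, logical(1))
  removed_mito <- sp_only[is_mito]
  removed_endo <- setdiff(sp_only[is_endo & !is_mito],
                          extracellular_whitelist)
  secretome <- setdiff(sp_only, union(removed_mito, removed_endo))
  structure(list(secretome = secretome,
                 removed_endomembrane = removed_endo,
                 removed_mitochondrial = removed_mito,
                 sp_only_input = sp_only),
            class = "secretome_result")
}

#' @export
print.secretome_result <- function(x, ...) {
  cat("secretome_result: ", length(x$sp_only_input), " SP-only proteins -> ",
      length(x$secretome), " secretome, ",
      length(x$removed_endomembrane), " endomembrane removed, ",
      length(x$removed_mitochondrial), " mitochondrial removed\n", sep = "")
  invisible(x)
}

#' Classify domain architecture of a protein
#'
#' `complex`: four or more different domain types. `repetitive`: at most two
#' different domain types with at least `repeat_min` total copies. Otherwise
#' `simple`. Distinct types are counted by accession (tandem copies of one
#' accession count once toward types, each toward total copies); no pooling
#' across Pfam-like and SMART-like dialects unless the caller maps synonyms
#' beforehand.
#'
#' @param proteins a [protein_table()] (any subset of rows).
#' @param repeat_min minimum total domain copies for the repetitive class
#'   (default 5).
#' @return data frame: `protein_id`, `architecture`, `distinct_domain_types`,
#'   `total_domain_copies`.
#' @export
classify_architecture <- function(proteins, repeat_min = 5) {
  distinct <- vapply(proteins$domain_hits,
                     function(d) length(unique(d$accession)), 0L)
  total <- vapply(proteins$domain_hits, nrow, 0L)
  arch <- ifelse(distinct >= 4L, "complex",
                 ifelse(distinct <= 2L & total >= repeat_min, "repetitive",
                        "simple"))
  data.frame(protein_id = proteins$protein_id,
             architecture = factor(arch,
                                   levels = c("complex", "repetitive", "simple")),
             distinct_domain_types = distinct,
             total_domain_copies = total,
             stringsAsFactors = FALSE)
}

#' Summary counts of domain-rich proteins
#'
#' Besides the architecture classes, reports how many proteins carry more
#' than 10 and more than 20 total domain copies.
#'
#' @inheritParams classify_architecture
#' @return named integer vector with entries `complex`, `repetitive`,
#'   `simple`, `over_10_domains`, `over_20_domains`.
#' @export
architecture_summary <- function(proteins, repeat_min = 5) {
  arch <- classify_architecture(proteins, repeat_min = repeat_min)
  c(table(arch$architecture),
    over_10_domains = sum(arch$total_domain_copies > 10L),
    over_20_domains = sum(arch$total_domain_copies > 20L))
}

#' Define a protein family
#'
#' A family rule matches on any of: domain accessions (a protein matches if
#' it carries at least one listed accession), gene-name prefixes, or an
#' explicit id list. Definitions are applied in priority order; a protein
#' joins the first matching family only.
#'
#' @param family_id family label.
#' @param accessions domain accessions whose presence places a protein in
#'   the family.
#' @param gene_prefixes gene-name prefixes (e.g. `"clec-"`, `"ins-"`).
#' @param ids explicit protein ids.
#' @param priority integer priority; lower values are tried first.
#' @param large_threshold member count at which a family counts as "large"
#'   (default 10).
#' @return an object of class `family_definition`.
#' @export
family_definition <- function(family_id, accessions = character(0),
                              gene_prefixes = character(0),
                              ids = character(0), priority = NA_integer_,
                              large_threshold = 10L) {
  structure(list(family_id = family_id, accessions = accessions,
                 gene_prefixes = gene_prefixes, ids = ids,
                 priority = as.integer(priority),
                 large_threshold = as.integer(large_threshold)),
            class = "family_definition")
}

family_matches <- function(def, proteins) {
  acc_hit <- if (length(def$accessions)) {
    vapply(proteins$domain_hits,
           function(d) any(d$accession %in% def$accessions), logical(1))
  } else rep(FALSE, nrow(proteins))
  pre_hit <- if (length(def$gene_prefixes)) {
    gn <- as.character(proteins$gene_name)
    gn[is.na(gn)] <- ""
    Reduce(`|`, lapply(def$gene_prefixes, function(p) startsWith(gn, p)))
  } else rep(FALSE, nrow(proteins))
  id_hit <- proteins$protein_id %in% def$ids
  acc_hit | pre_hit | id_hit
}

#' Group proteins into families
#'
#' Definitions are sorted by priority (ties are a configuration error) and
#' applied first-match-wins. Family rules are evaluated over all supplied
#' proteins, not only signal-peptide carriers: members of a secreted family
#' without a predicted signal peptide are deliberately included, as they are
#' potentially secreted as well.
#'
#' @param proteins a [protein_table()].
#' @param defs list of [family_definition()] objects.
#' @return list with `membership` (named list family_id -> protein ids),
#'   `assignment` (data frame `protein_id`, `family_id`, `NA` when
#'   unassigned) and `summary` (data frame `family_id`, `n`, `large`).
#' @export
group_families <- function(proteins, defs) {
  prios <- vapply(defs, function(d) d$priority, 0L)
  if (anyNA(prios)) prios[is.na(prios)] <- seq_along(defs)[is.na(prios)] + 1000L
  if (anyDuplicated(prios)) {
    stop("family definitions with equal priority", call. = FALSE)
  }
  defs <- defs[order(prios)]
  assigned <- rep(NA_character_, nrow(proteins))
  membership <- list()
  for (def in defs) {
    hit <- family_matches(def, proteins) & is.na(assigned)
    assigned[hit] <- def$family_id
    membership[[def$family_id]] <- proteins$protein_id[hit]
  }
  summary <- data.frame(
    family_id = vapply(defs, function(d) d$family_id, ""),
    n = vapply(defs, function(d) length(membership[[d$family_id]]), 0L),
    large = vapply(defs, function(d) {
      length(membership[[d$family_id]]) >= d$large_threshold
    }, logical(1)),
    stringsAsFactors = FALSE)
  list(membership = membership,
       assignment = data.frame(protein_id = proteins$protein_id,
                               family_id = assigned,
                               stringsAsFactors = FALSE),
       summary = summary)
}

#' Read family definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `family_id` and any of
#' `accessions`, `gene_prefixes`, `ids`, `priority`, `large_threshold`.
#'
#' @param path path to the JSON file.
#' @return list of [family_definition()] objects.
#' @export
read_family_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(seq_along(raw), function(i) {
    d <- raw[[i]]
    family_definition(family_id = d$family_id,
                      accessions = unlist(d$accessions) %||% character(0),
                      gene_prefixes = unlist(d$gene_prefixes) %||% character(0),
                      ids = unlist(d$ids) %||% character(0),
                      priority = d$priority %||% i,
                      large_threshold = d$large_threshold %||% 10L)
  })
}
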