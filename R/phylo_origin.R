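# Three-tier phylogenetic-origin classification.
#
# Each gene is classed nematoda (no homologs outside nematodes), metazoa
# (homologs in invertebrates and vertebrates but not plants/fungi),
# eukaryota (homologs in all of the above) or unclassified, by a cascade:
# family-tree species composition first, then ortholog-cluster classes, then
# best-BLAST-hit species. The first decisive tier wins; the BLAST tier is
# flagged as lower confidence (it tends to overestimate metazoan/eukaryotic
# calls but is conservative for nematode-specific ones).

ORIGINS <- c("nematoda", "metazoa", "eukaryota", "unclassified")
ORIGIN_TIERS <- c("treefam", "inparanoid", "blast", "none")
INPARANOID_CLASSES <- c("InP_cae", "InP_met", "InP_uni")
TAXON_GROUPS <- c("nematode", "vertebrate_or_chordate", "arthropod",
                  "plant_or_fungus", "other")

#' Species taxonomy for origin classification
#'
#' Maps species names to one of the coarse groups `nematode`,
#' `vertebrate_or_chordate`, `arthropod`, `plant_or_fungus`, `other`.
#'
#' @param mapping named character vector: species name -> group.
#' @param strict if `TRUE`, classifying a species missing from the mapping
#'   is an error; if `FALSE`, it falls back to `"other"`.
#' @return an object of class `species_taxonomy`.
#' @export
species_taxonomy <- function(mapping, strict = TRUE) {
  bad <- setdiff(unique(mapping), TAXON_GROUPS)
  if (length(bad)) {
    stop("unknown taxonomy group: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(mapping = mapping, strict = strict),
            class = "species_taxonomy")
}

#' @rdname species_taxonomy
#' @export
default_taxonomy <- function(strict = TRUE) {
  species_taxonomy(c(
    "C. elegans" = "nematode", "C. briggsae" = "nematode",
    "C. remanei" = "nematode", "C. brenneri" = "nematode",
    "P. pacificus" = "nematode", "B. malayi" = "nematode",
    "H. sapiens" = "vertebrate_or_chordate",
    "M. musculus" = "vertebrate_or_chordate",
    "D. rerio" = "vertebrate_or_chordate",
    "G. gallus" = "vertebrate_or_chordate",
    "C. intestinalis" = "vertebrate_or_chordate",
    "D. melanogaster" = "arthropod", "A. gambiae" = "arthropod",
    "A. mellifera" = "arthropod",
    "S. cerevisiae" = "plant_or_fungus", "S. pombe" = "plant_or_fungus",
    "A. thaliana" = "plant_or_fungus", "O. sativa" = "plant_or_fungus",
    "D. discoideum" = "other", "E. coli" = "other"), strict = strict)
}

taxon_groups_of <- function(species, tax) {
  g <- tax$mapping[species]
  if (anyNA(g)) {
    missing <- species[is.na(g)]
    if (tax$strict) {
      stop("species not in taxonomy: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    g[is.na(g)] <- "other"
  }
  unname(g)
}

#' Classify origin from family-tree species composition
#'
#' `nematoda` iff the tree holds at most one distinct non-nematode species
#' (allowing an outgroup); this test runs first, so a tree of many nematodes
#' plus one human outgroup is still nematode-specific. Otherwise `eukaryota`
#' iff the tree holds a vertebrate-or-chordate, an arthropod and a
#' plant-or-fungus species; `metazoa` iff it holds a vertebrate-or-chordate
#' and an arthropod but no plant-or-fungus; otherwise undecided. Species are
#' counted as distinct names, not sequence counts.
#'
#' @param species character vector of species names in the tree.
#' @param tax a [species_taxonomy()].
#' @return one of `"nematoda"`, `"metazoa"`, `"eukaryota"`, `"undecided"`.
#' @export
classify_treefam <- function(species, tax = default_taxonomy()) {
  species <- unique(species)
  if (length(species) == 0) return("undecided")
  groups <- taxon_groups_of(species, tax)
  n_non_nematode <- sum(groups != "nematode")
  if (n_non_nematode <= 1L) return("nematoda")
  has_vert <- any(groups == "vertebrate_or_chordate")
  has_arth <- any(groups == "arthropod")
  has_plant <- any(groups == "plant_or_fungus")
  if (has_vert && has_arth && has_plant) return("eukaryota")
  if (has_vert && has_arth) return("metazoa")
  "undecided"
}

#' Classify origin from ortholog-cluster classes
#'
#' Cluster classes: `InP_cae` (study species vs congeneric nematode pairs),
#' `InP_met` (metazoan pairs), `InP_uni` (non-metazoan eukaryotic pairs).
#' `eukaryota` iff `InP_uni` present; else `metazoa` iff `InP_met`; else
#' `nematoda` iff `InP_cae`; else undecided. The precedence is forced by the
#' exclusion-style definitions (nematoda = InP_cae but not InP_met/InP_uni).
#'
#' @param classes character vector, subset of
#'   `c("InP_cae", "InP_met", "InP_uni")`.
#' @return origin string or `"undecided"`.
#' @export
classify_inparanoid <- function(classes) {
  bad <- setdiff(classes, INPARANOID_CLASSES)
  if (length(bad)) stop("unknown Inparanoid class: ", bad[1], call. = FALSE)
  if ("InP_uni" %in% classes) return("eukaryota")
  if ("InP_met" %in% classes) return("metazoa")
  if ("InP_cae" %in% classes) return("nematoda")
  "undecided"
}

#' Classify origin from best-BLAST-hit species
#'
#' `eukaryota` iff the hits include a listed unicellular-eukaryote/plant
#' species; else `metazoa` iff they include a listed vertebrate; else
#' `nematoda` iff they include a listed non-study nematode; else undecided.
#'
#' @param hit_species character vector of best-hit species.
#' @param nematode_species,vertebrate_species,eukaryote_species the species
#'   lists driving each rule; defaults follow the standard WormBase-derived
#'   setup.
#' @return origin string or `"undecided"`.
#' @export
classify_blast <- function(hit_species,
                           nematode_species = c("C. remanei", "C. briggsae",
                                                "P. pacificus"),
                           vertebrate_species = c("M. musculus", "H. sapiens"),
                           eukaryote_species = c("S. cerevisiae",
                                                 "A. thaliana")) {
  if (any(hit_species %in% eukaryote_species)) return("eukaryota")
  if (any(hit_species %in% vertebrate_species)) return("metazoa")
  if (any(hit_species %in% nematode_species)) return("nematoda")
  "undecided"
}

#' Three-tier origin cascade
#'
#' Applies [classify_treefam()], [classify_inparanoid()] and
#' [classify_blast()] in that order; the first decisive tier determines the
#' origin and is recorded. A gene undecided at every tier is `unclassified`
#' with tier `none`. A tier with absent evidence is undecided by definition.
#'
#' @param evidence origin-evidence data frame ([read_origin_evidence()] or
#'   the synthetic generator); needs `gene_id` and list columns
#'   `treefam_species`, `inparanoid_classes`, `blast_species` (optional
#'   logical columns `has_treefam`/`has_blast` distinguish absent evidence).
#' @param tax a [species_taxonomy()].
#' @param blast_args optional list of species-list overrides passed to
#'   [classify_blast()].
#' @return data frame `gene_id`, `origin` (factor over nematoda, metazoa,
#'   eukaryota, unclassified), `tier` (factor over treefam, inparanoid,
#'   blast, none), `low_confidence` (`TRUE` for BLAST-tier calls).
#' @export
classify_origin <- function(evidence, tax = default_taxonomy(),
                            blast_args = list()) {
  n <- nrow(evidence)
  origin <- character(n)
  tier <- character(n)
  for (i in seq_len(n)) {
    call_i <- classify_treefam(evidence$treefam_species[[i]], tax)
    if (call_i != "undecided") {
      origin[i] <- call_i; tier[i] <- "treefam"; next
    }
    call_i <- classify_inparanoid(evidence$inparanoid_classes[[i]])
    if (call_i != "undecided") {
      origin[i] <- call_i; tier[i] <- "inparanoid"; next
    }
    call_i <- do.call(classify_blast,
                      c(list(evidence$blast_species[[i]]), blast_args))
    if (call_i != "undecided") {
      origin[i] <- call_i; tier[i] <- "blast"; next
    }
    origin[i] <- "unclassified"; tier[i] <- "none"
  }
  data.frame(gene_id = evidence$gene_id,
             origin = factor(origin, levels = ORIGINS),
             tier = factor(tier, levels = ORIGIN_TIERS),
             low_confidence = tier == "blast",
             stringsAsFactors = FALSE)
}

#' Per-origin fractions of a cohort
#'
#' @param calls output of [classify_origin()].
#' @return named numeric vector over the four origins summing to 1 (all
#'   zero for empty input).
#' @export
origin_fractions <- function(calls) {
  tab <- table(calls$origin)
  tot <- sum(tab)
  out <- as.numeric(tab) / max(tot, 1L)
  names(out) <- names(tab)
  out
}
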