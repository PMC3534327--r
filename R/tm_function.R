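# Functional grouping of transmembrane proteins.
#
# TM proteins split into three major groups: serpentine-type GPCRs (putative
# chemoreceptors, supplied as an id list and checked first), proteins with
# no usable information, and domain-classified proteins sorted into eight
# broad functional categories by an ordered rule list seeded from known
# Pfam/SMART accessions and gene-name prefixes.

TM_CATEGORIES <- c("chemoreceptor", "channels", "transporters", "enzymes",
                   "signaling", "trafficking", "adhesion", "ECM", "other",
                   "no_information")

TM_DOMAIN_CATEGORIES <- c("channels", "transporters", "enzymes", "signaling",
                          "trafficking", "adhesion", "ECM", "other")

# Bulk RNAi-screen annotations that tag many indirectly-involved genes;
# excluded from GO-based assignment by default.
GO_BLOCKLIST_DEFAULT <- c("lipid_storage", "receptor-mediated endocytosis")

#' Define a functional-category rule
#'
#' A rule matches a protein if it carries any listed domain accession, its
#' gene name starts with any listed prefix, it carries any listed GO term,
#' or its id is explicitly listed. Rules are applied in increasing priority
#' value.
#'
#' @param category one of `channels`, `transporters`, `enzymes`,
#'   `signaling`, `trafficking`, `adhesion`, `ECM`, `other`.
#' @param accessions Pfam/SMART accessions.
#' @param gene_prefixes gene-name prefixes (e.g. `"lgc-"`).
#' @param go_terms GO identifiers (fallback evidence tier).
#' @param ids explicit protein ids.
#' @param priority unique integer priority.
#' @param rule_id optional label; defaults to `category/priority`.
#' @return an object of class `category_rule`.
#' @export
category_rule <- function(category, accessions = character(0),
                          gene_prefixes = character(0),
                          go_terms = character(0), ids = character(0),
                          priority, rule_id = NULL) {
  if (!category %in% TM_DOMAIN_CATEGORIES) {
    stop("unknown category '", category, "'", call. = FALSE)
  }
  structure(list(category = category, accessions = accessions,
                 gene_prefixes = gene_prefixes, go_terms = go_terms,
                 ids = ids, priority = as.integer(priority),
                 rule_id = rule_id %||% paste0(category, "/", priority)),
            class = "category_rule")
}

#' Default functional-category rule set
#'
#' Seeded from the printed large TM families: ligand-gated ion channels
#' (PF02931/PF02932, `lgc-`), potassium (PF07885) and sodium
#' (PF00858/PF00999/PF01699) channels, innexins (PF00876); major
#' facilitators (PF07690), ABC (PF00664/PF06472), sugar (PF00083) and amino
#' acid (PF00324/PF01490) transporters; acyltransferases (PF01757/PF03062,
#' `oac-`), UDP-glucuronosyltransferases (PF00201), AAA ATPases (SM00382);
#' GPCRs (PF00002/PF00003/PF08395), kinases
#' (PF00069/PF07714/SM00219/SM00220/SM00221), ANF receptors (PF01094),
#' cyclases (PF00211/SM00044); t-SNAREs (SM00397); claudin-like (PF07062,
#' `clc-`) and cadherins (PF00028/SM00112); cuticlins (PF00100/SM00241) and
#' TM collagens (PF01391). Precedence when multiple category domains
#' co-occur: channels > transporters > signaling > enzymes > trafficking >
#' adhesion > ECM.
#'
#' @return ordered list of [category_rule()] objects.
#' @export
default_tm_rules <- function() {
  list(
    category_rule("channels", accessions = c("PF02931", "PF02932", "PF07885",
                                             "PF00858", "PF00999", "PF01699",
                                             "PF00876"),
                  gene_prefixes = c("lgc-", "twk-"), priority = 10),
    category_rule("transporters", accessions = c("PF07690", "PF00664",
                                                 "PF06472", "PF00083",
                                                 "PF00324", "PF01490"),
                  priority = 20),
    category_rule("signaling", accessions = c("PF00002", "PF00003", "PF08395",
                                              "PF00069", "PF07714", "SM00219",
                                              "SM00220", "SM00221", "PF01094",
                                              "PF00211", "SM00044"),
                  priority = 30),
    category_rule("enzymes", accessions = c("PF01757", "PF03062", "PF00201",
                                            "SM00382", "SM00235"),
                  gene_prefixes = "oac-", priority = 40),
    category_rule("trafficking", accessions = "SM00397", priority = 50),
    category_rule("adhesion", accessions = c("PF07062", "PF00028", "SM00112"),
                  gene_prefixes = "clc-", priority = 60),
    category_rule("ECM", accessions = c("PF00100", "SM00241", "PF01391"),
                  priority = 70))
}

rule_match_kind <- function(rule, proteins, go_blocklist) {
  n <- nrow(proteins)
  kind <- rep(NA_character_, n)
  if (length(rule$go_terms)) {
    go_ok <- setdiff(rule$go_terms, go_blocklist)
    hit <- vapply(proteins$go_terms, function(g) any(g %in% go_ok), logical(1))
    kind[hit] <- "go"
  }
  if (length(rule$gene_prefixes)) {
    gn <- as.character(proteins$gene_name)
    gn[is.na(gn)] <- ""
    hit <- Reduce(`|`, lapply(rule$gene_prefixes,
                              function(p) startsWith(gn, p)))
    kind[hit] <- "gene_name"
  }
  if (length(rule$accessions)) {
    hit <- vapply(proteins$domain_hits,
                  function(d) any(d$accession %in% rule$accessions),
                  logical(1))
    kind[hit] <- "domain"
  }
  kind[proteins$protein_id %in% rule$ids] <- "explicit_list"
  kind
}

#' Assign transmembrane proteins to functional categories
#'
#' Proteins in `chemoreceptor_ids` are `chemoreceptor` regardless of any
#' rule (set membership outranks rules). Otherwise the first matching rule
#' by priority assigns its category. Unmatched proteins with no domain hit,
#' no GO term and no description are `no_information`; all other unmatched
#' proteins are `other`. Proteins matched by more than one rule are logged
#' in the `multi_match` attribute.
#'
#' @param proteins a [protein_table()] restricted to (or containing) the TM
#'   proteins to assign.
#' @param topology matching `topology_table`; only proteins with
#'   `effective_tm_count >= 1` are assigned.
#' @param rules ordered list of [category_rule()] objects.
#' @param chemoreceptor_ids serpentine-type GPCR ids.
#' @param go_blocklist GO terms never used as assignment evidence.
#' @return data frame `protein_id`, `category` (factor over the ten
#'   labels), `matched_rule`, `evidence_kind`.
#' @export
assign_group <- function(proteins, topology, rules = default_tm_rules(),
                         chemoreceptor_ids = character(0),
                         go_blocklist = GO_BLOCKLIST_DEFAULT) {
  prios <- vapply(rules, function(r) r$priority, 0L)
  if (anyDuplicated(prios)) {
    stop("category rules with duplicate priority", call. = FALSE)
  }
  rules <- rules[order(prios)]
  is_tm <- topology$effective_tm_count[match(proteins$protein_id,
                                             topology$protein_id)] >= 1L
  tm <- proteins[which(is_tm), , drop = FALSE]
  n <- nrow(tm)
  category <- rep(NA_character_, n)
  matched_rule <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  n_matches <- integer(n)
  for (rule in rules) {
    k <- rule_match_kind(rule, tm, go_blocklist)
    hit <- !is.na(k)
    n_matches <- n_matches + hit
    take <- hit & is.na(category)
    category[take] <- rule$category
    matched_rule[take] <- rule$rule_id
    kind[take] <- k[take]
  }
  is_chemo <- tm$protein_id %in% chemoreceptor_ids
  category[is_chemo] <- "chemoreceptor"
  matched_rule[is_chemo] <- "chemoreceptor_set"
  kind[is_chemo] <- "explicit_list"
  no_info <- is.na(category) &
    vapply(tm$domain_hits, nrow, 0L) == 0L &
    vapply(tm$go_terms, length, 0L) == 0L &
    is.na(tm$description)
  category[no_info] <- "no_information"
  kind[no_info] <- "none"
  kind[is.na(category)] <- "none"
  category[is.na(category)] <- "other"
  out <- data.frame(protein_id = tm$protein_id,
                    category = factor(category, levels = TM_CATEGORIES),
                    matched_rule = matched_rule,
                    evidence_kind = kind,
                    stringsAsFactors = FALSE)
  attr(out, "multi_match") <- tm$protein_id[n_matches > 1L & !is_chemo]
  out
}

#' Per-category counts of TM-protein assignments
#'
#' @param assignments output of [assign_group()].
#' @return named integer vector over all ten category labels; sums to the
#'   number of assigned TM proteins.
#' @export
summarize_groups <- function(assignments) {
  tab <- table(assignments$category)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Read a functional-category rule config (JSON array)
#'
#' @param path path to the JSON file; objects carry `category`, `priority`
#'   and any of `accessions`, `gene_prefixes`, `go_terms`, `ids`, `rule_id`.
#' @return ordered list of [category_rule()] objects.
#' @export
read_tm_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(d) {
    category_rule(category = d$category,
                  accessions = unlist(d$accessions) %||% character(0),
                  gene_prefixes = unlist(d$gene_prefixes) %||% character(0),
                  go_terms = unlist(d$go_terms) %||% character(0),
                  ids = unlist(d$ids) %||% character(0),
                  priority = d$priority,
                  rule_id = d$rule_id %||% NULL)
  })
}
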