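# Survey orchestration and the count ledger.
#
# The ledger holds every headline set size the survey prints and verifies
# the arithmetic identities tying them together; identity violations
# indicate classification leaks and are fatal by default.

LEDGER_KEYS <- c("proteome", "sp_total", "tm_total", "tm_lacking_sp",
                 "sp_tm_union", "sp_only", "removed_endomembrane",
                 "removed_mitochondrial", "secretome", "tm_organelle_assigned",
                 "tm_no_localization", "chemoreceptors", "tm_no_information",
                 "tm_domain_classified")

#' Count ledger with arithmetic identity checks
#'
#' @param counts named list / vector of integers; recognized headline keys
#'   are listed in the package ledger documentation, `category_counts`
#'   (named vector over the eight domain categories) and `origin_counts`
#'   (named vector over the four origins) ride along.
#' @param category_counts named integer vector over the eight TM functional
#'   categories.
#' @param origin_counts named integer vector over the four origins.
#' @return an object of class `count_ledger`.
#' @export
count_ledger <- function(counts, category_counts = NULL,
                         origin_counts = NULL) {
  counts <- as.list(counts)
  structure(list(counts = counts, category_counts = category_counts,
                 origin_counts = origin_counts),
            class = "count_ledger")
}

#' @export
print.count_ledger <- function(x, ...) {
  cat("count_ledger\n")
  for (k in names(x$counts)) cat(sprintf("  %-24s %d\n", k, x$counts[[k]]))
  if (!is.null(x$category_counts)) {
    cat("  categories:", paste(names(x$category_counts),
                               x$category_counts, sep = "=",
                               collapse = " "), "\n")
  }
  invisible(x)
}

#' Verify the ledger identities
#'
#' Checks, where the needed counts are present: the union identity
#' `sp_tm_union = sp_total + tm_lacking_sp`; the secretome conservation
#' `secretome + removed_endomembrane + removed_mitochondrial = sp_only`;
#' the TM three-way partition `chemoreceptors + tm_no_information +
#' tm_domain_classified = tm_total`; the category sum
#' `sum(category_counts) = tm_domain_classified`; and the origin sum
#' `sum(origin_counts) = cohort size` (when `cohort` is given).
#'
#' @param ledger a [count_ledger()].
#' @param cohort cohort size for the origin identity, or `NULL`.
#' @param strict fail hard on a violation (default); otherwise return the
#'   failure messages.
#' @return invisibly, a character vector of violated identities (empty when
#'   all hold).
#' @export
check_count_ledger <- function(ledger, cohort = NULL, strict = TRUE) {
  cnt <- ledger$counts
  bad <- character(0)
  have <- function(...) all(c(...) %in% names(cnt))
  if (have("sp_tm_union", "sp_total", "tm_lacking_sp") &&
      cnt$sp_tm_union != cnt$sp_total + cnt$tm_lacking_sp) {
    bad <- c(bad, "sp_tm_union != sp_total + tm_lacking_sp")
  }
  if (have("sp_tm_union", "sp_total", "tm_total", "sp_and_tm") &&
      cnt$sp_tm_union != cnt$sp_total + cnt$tm_total - cnt$sp_and_tm) {
    bad <- c(bad, "sp_tm_union != sp_total + tm_total - sp_and_tm")
  }
  if (have("secretome", "removed_endomembrane", "removed_mitochondrial",
           "sp_only") &&
      cnt$secretome + cnt$removed_endomembrane +
        cnt$removed_mitochondrial != cnt$sp_only) {
    bad <- c(bad, "secretome partition does not sum to sp_only")
  }
  if (have("chemoreceptors", "tm_no_information", "tm_domain_classified",
           "tm_total") &&
      cnt$chemoreceptors + cnt$tm_no_information +
        cnt$tm_domain_classified != cnt$tm_total) {
    bad <- c(bad, "TM three-way partition does not sum to tm_total")
  }
  if (!is.null(ledger$category_counts) && have("tm_domain_classified") &&
      sum(ledger$category_counts) != cnt$tm_domain_classified) {
    bad <- c(bad, "category counts do not sum to tm_domain_classified")
  }
  if (!is.null(ledger$origin_counts) && !is.null(cohort) &&
      sum(ledger$origin_counts) != cohort) {
    bad <- c(bad, "origin counts do not sum to the cohort size")
  }
  if (strict && length(bad)) {
    stop("ledger identity violation: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(bad)
}

#' Whole-number percentage, half away from zero
#'
#' @param a,b counts, `b > 0`.
#' @return `round(100 * a / b)` with ties rounded away from zero (so
#'   0.5 -> 1, unlike banker's rounding).
#' @export
percent <- function(a, b) {
  if (b == 0) stop("percent undefined for b = 0", call. = FALSE)
  p <- 100 * a / b
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Ledger of published C. elegans survey marginals (WormBase release 210)
#'
#' Reads the genome-wide marginal counts shipped with the package
#' (`extdata/celegans_ws210_counts.tsv`) and derives the remaining ledger
#' entries through the identities: the SP-or-TM union from the SP total and
#' the TM-lacking-SP count; the secretome from the SP-only total minus the
#' endomembrane and mitochondrial removals; the domain-classified TM total
#' as the sum of the eight category counts; the no-information TM count as
#' the remainder of the TM three-way partition; and the
#' lacking-localization TM count from the organelle-assigned total.
#'
#' @return a [count_ledger()] that passes [check_count_ledger()].
#' @export
reference_count_ledger <- function() {
  path <- system.file("extdata", "celegans_ws210_counts.tsv",
                      package = "secretomeSurvey", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  kv <- stats::setNames(as.integer(raw$count), raw$key)
  cats <- kv[TM_DOMAIN_CATEGORIES]
  cnt <- list(
    proteome = kv[["proteome"]],
    sp_total = kv[["sp_total"]],
    tm_total = kv[["tm_total"]],
    tm_lacking_sp = kv[["tm_lacking_sp"]],
    sp_and_tm = kv[["tm_total"]] - kv[["tm_lacking_sp"]],
    sp_tm_union = kv[["sp_total"]] + kv[["tm_lacking_sp"]],
    sp_only = kv[["sp_only"]],
    removed_endomembrane = kv[["removed_endomembrane"]],
    removed_mitochondrial = kv[["removed_mitochondrial"]],
    secretome = kv[["sp_only"]] - kv[["removed_endomembrane"]] -
      kv[["removed_mitochondrial"]],
    tm_organelle_assigned = kv[["tm_organelle_assigned"]],
    tm_no_localization = kv[["tm_total"]] - kv[["tm_organelle_assigned"]],
    chemoreceptors = kv[["chemoreceptors"]],
    tm_domain_classified = sum(cats))
  cnt$tm_no_information <- cnt$tm_total - cnt$chemoreceptors -
    cnt$tm_domain_classified
  count_ledger(cnt, category_counts = cats)
}

#' Large secreted families with domains of unknown function
#'
#' Reads the shipped table of large secreted-protein families characterized
#' by a DUF or other nematode-restricted domain (family label and member
#' count), as published for WormBase release 210.
#'
#' @return data frame `family`, `n_genes`.
#' @export
duf_family_table <- function() {
  path <- system.file("extdata", "celegans_duf_families.tsv",
                      package = "secretomeSurvey", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full survey on one set of inputs
#'
#' Composes every pipeline stage: topology reconciliation, localization
#' transfer and secretome construction, architecture and family grouping,
#' origin classification, TM functional grouping, and (when an expression
#' matrix is supplied) stage/sex/infection enrichment. Builds the count
#' ledger and verifies its identities.
#'
#' @param proteins a [protein_table()].
#' @param origin_evidence origin-evidence data frame, or `NULL`.
#' @param localization localization-evidence data frame, or `NULL`.
#' @param expression an `expression_matrix`, or `NULL`.
#' @param infection_flags data frame `gene_id`, `condition`, or `NULL`.
#' @param chemoreceptor_ids serpentine-type GPCR ids.
#' @param whitelist extracellular whitelist for [build_secretome()].
#' @param family_defs list of [family_definition()]s.
#' @param rules ordered [category_rule()] list.
#' @param tax a [species_taxonomy()].
#' @param n_terminal_window window for [reconcile_topology()].
#' @param strict fail on ledger identity violations (default `TRUE`).
#' @return list with `ledger`, `classification` (per-protein table ready
#'   for [write_classification_table()]), `topology`, `secretome`,
#'   `origin`, `assignments`, `families`, `enrichment` (or `NULL`).
#' @export
run_survey <- function(proteins, origin_evidence = NULL, localization = NULL,
                       expression = NULL, infection_flags = NULL,
                       chemoreceptor_ids = character(0),
                       whitelist = character(0),
                       family_defs = default_family_defs(),
                       rules = default_tm_rules(),
                       tax = default_taxonomy(),
                       n_terminal_window = 40, strict = TRUE) {
  topo <- reconcile_topology(proteins, n_terminal_window)
  loc_map <- if (is.null(localization)) list() else
    transfer_localization(localization)
  secr <- build_secretome(topo, loc_map, extracellular_whitelist = whitelist)
  fams <- group_families(proteins, family_defs)
  arch <- classify_architecture(proteins)
  asg <- assign_group(proteins, topo, rules = rules,
                      chemoreceptor_ids = chemoreceptor_ids)
  origin <- if (!is.null(origin_evidence)) {
    classify_origin(origin_evidence, tax)
  } else NULL

  cat_counts <- summarize_groups(asg)
  tm_total <- sum(topo$effective_tm_count >= 1L)
  secr_status <- rep(NA_character_, nrow(proteins))
  secr_status[proteins$protein_id %in% secr$secretome] <- "secretome"
  secr_status[proteins$protein_id %in% secr$removed_endomembrane] <-
    "removed_endomembrane"
  secr_status[proteins$protein_id %in% secr$removed_mitochondrial] <-
    "removed_mitochondrial"
  classification <- data.frame(
    protein_id = proteins$protein_id,
    gene_name = proteins$gene_name,
    topology_class = as.character(topo$topology_class),
    effective_tm_count = topo$effective_tm_count,
    secretome_status = secr_status,
    family_id = fams$assignment$family_id,
    architecture = ifelse(proteins$protein_id %in% secr$secretome,
                          as.character(arch$architecture), NA_character_),
    stringsAsFactors = FALSE)
  classification$functional_category <-
    as.character(asg$category)[match(classification$protein_id,
                                     asg$protein_id)]
  if (!is.null(origin)) {
    key <- if (all(origin$gene_id %in% proteins$protein_id)) {
      classification$protein_id
    } else classification$gene_name
    idx <- match(key, origin$gene_id)
    classification$origin <- as.character(origin$origin)[idx]
    classification$origin_tier <- as.character(origin$tier)[idx]
  }

  counts <- list(
    proteome = nrow(proteins),
    sp_total = sum(topo$has_sp),
    tm_total = tm_total,
    tm_lacking_sp = sum(topo$topology_class == "TM_only"),
    sp_and_tm = sum(topo$topology_class == "SP_and_TM"),
    sp_tm_union = sum(topo$has_sp | topo$effective_tm_count >= 1L),
    sp_only = length(secr$sp_only_input),
    removed_endomembrane = length(secr$removed_endomembrane),
    removed_mitochondrial = length(secr$removed_mitochondrial),
    secretome = length(secr$secretome),
    chemoreceptors = unname(cat_counts["chemoreceptor"]),
    tm_no_information = unname(cat_counts["no_information"]),
    tm_domain_classified = sum(cat_counts[TM_DOMAIN_CATEGORIES]))
  origin_counts <- if (!is.null(origin)) {
    tab <- table(origin$origin)
    stats::setNames(as.integer(tab), names(tab))
  } else NULL
  ledger <- count_ledger(counts,
                         category_counts = cat_counts[TM_DOMAIN_CATEGORIES],
                         origin_counts = origin_counts)
  check_count_ledger(ledger, cohort = if (!is.null(origin)) nrow(origin),
                     strict = strict)

  enrichment <- NULL
  if (!is.null(expression)) {
    up <- upregulated_sets(expression)
    if (!is.null(infection_flags)) {
      inf <- infection_upregulated(expression, infection_flags)
      up[["infection_any"]] <- inf$union
    }
    gene_class <- ifelse(!is.na(secr_status) & secr_status == "secretome",
                         "secreted",
                         ifelse(topo$effective_tm_count >= 1L, "TM", "other"))
    cls_df <- data.frame(gene_id = proteins$gene_name, class = gene_class,
                         stringsAsFactors = FALSE)
    cls_df <- cls_df[!is.na(cls_df$gene_id), , drop = FALSE]
    enrichment <- list(upregulated = up,
                       overlap = class_overlap_summary(up, cls_df))
  }
  list(ledger = ledger, classification = classification, topology = topo,
       secretome = secr, origin = origin, assignments = asg,
       families = fams, enrichment = enrichment)
}
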