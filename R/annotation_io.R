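# Input/output for the annotation tables the survey consumes and produces.
#
# All tables are plain TSV. Residue coordinates are 1-based and inclusive at
# both ends, following the SMART/Pfam reporting convention. Optional fields
# are encoded as empty cells, never as sentinel numbers.

PROTEIN_COLUMNS <- c("protein_id", "gene_name", "length", "sp_start", "sp_end",
                     "tm_segments", "domains", "go_terms", "description")

DOMAIN_SOURCES <- c("pfam", "smart", "other")

#' Construct a validated protein annotation table
#'
#' One row per protein (isoforms must already be collapsed to a single
#' representative per gene). Interval columns use 1-based inclusive residue
#' coordinates. `tm_segments` and `domain_hits` are list columns holding,
#' respectively, a 2-column integer matrix (`start`, `end`) and a data frame
#' with columns `accession`, `source` (one of `"pfam"`, `"smart"`, `"other"`)
#' and `start`, `end`.
#'
#' @param protein_id character vector of unique protein identifiers.
#' @param length integer vector of protein lengths in amino acids.
#' @param gene_name optional character vector of gene names (`NA` allowed).
#' @param sp_start,sp_end signal-peptide interval bounds, `NA` when no signal
#'   peptide is predicted.
#' @param tm_segments list of 2-column matrices of transmembrane segments.
#' @param domain_hits list of data frames of domain hits.
#' @param go_terms list of character vectors of GO identifiers.
#' @param description optional character vector of free-text descriptions.
#' @return a `data.frame` of class `protein_table`.
#' @export
protein_table <- function(protein_id, length, gene_name = NA_character_,
                          sp_start = NA_integer_, sp_end = NA_integer_,
                          tm_segments = NULL, domain_hits = NULL,
                          go_terms = NULL, description = NA_character_) {
  n <- length(protein_id)
  empty_iv <- matrix(integer(0), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  empty_dom <- data.frame(accession = character(0), source = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
  tm_segments <- tm_segments %||% rep(list(empty_iv), n)
  domain_hits <- domain_hits %||% rep(list(empty_dom), n)
  go_terms <- go_terms %||% rep(list(character(0)), n)
  tab <- data.frame(protein_id = as.character(protein_id),
                    gene_name = rep_len(as.character(gene_name), n),
                    length = as.integer(length),
                    sp_start = rep_len(as.integer(sp_start), n),
                    sp_end = rep_len(as.integer(sp_end), n),
                    description = rep_len(as.character(description), n),
                    stringsAsFactors = FALSE)
  tab$tm_segments <- tm_segments
  tab$domain_hits <- domain_hits
  tab$go_terms <- go_terms
  class(tab) <- c("protein_table", "data.frame")
  validate_protein_table(tab)
}

#' @rdname protein_table
#' @param tab a candidate `protein_table`.
#' @export
validate_protein_table <- function(tab) {
  if (anyDuplicated(tab$protein_id)) {
    dup <- unique(tab$protein_id[duplicated(tab$protein_id)])
    stop("duplicate protein_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$length) | tab$length < 1L)) {
    stop("protein length must be a positive integer", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    id <- tab$protein_id[i]
    len <- tab$length[i]
    has_sp <- !is.na(tab$sp_start[i]) || !is.na(tab$sp_end[i])
    if (has_sp) {
      check_interval(tab$sp_start[i], tab$sp_end[i], len, "signal peptide",
                     paste0("protein ", id, ", column sp_start/sp_end"))
    }
    tm <- tab$tm_segments[[i]]
    if (nrow(tm) > 0) {
      for (j in seq_len(nrow(tm))) {
        check_interval(tm[j, "start"], tm[j, "end"], len, "TM segment",
                       paste0("protein ", id, ", column tm_segments"))
      }
      if (anyDuplicated(paste(tm[, "start"], tm[, "end"]))) {
        stop("identical TM segments repeated for protein ", id, call. = FALSE)
      }
    }
    dom <- tab$domain_hits[[i]]
    if (nrow(dom) > 0) {
      bad_src <- setdiff(unique(dom$source), DOMAIN_SOURCES)
      if (length(bad_src)) {
        stop("unknown domain source '", bad_src[1], "' for protein ", id,
             call. = FALSE)
      }
      for (j in seq_len(nrow(dom))) {
        check_interval(dom$start[j], dom$end[j], len, "domain",
                       paste0("protein ", id, ", column domains"))
      }
    }
  }
  tab
}

parse_domain_cell <- function(x, id) {
  toks <- split_cell(x)
  if (length(toks) == 0) {
    return(data.frame(accession = character(0), source = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(toks, ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 3L, logical(1))
  if (any(bad)) {
    stop("malformed domain cell for protein ", id,
         " (expected accession:source:start-end)", call. = FALSE)
  }
  iv <- t(vapply(parts, function(p) {
    b <- strsplit(p[3], "-", fixed = TRUE)[[1]]
    if (length(b) != 2L) stop("malformed domain interval for protein ", id,
                              call. = FALSE)
    as.integer(b)
  }, integer(2)))
  data.frame(accession = vapply(parts, `[`, "", 1),
             source = vapply(parts, `[`, "", 2),
             start = iv[, 1], end = iv[, 2], stringsAsFactors = FALSE)
}

format_domain_cell <- function(dom) {
  if (is.null(dom) || nrow(dom) == 0) return("")
  paste(paste0(dom$accession, ":", dom$source, ":", dom$start, "-", dom$end),
        collapse = ";")
}

#' Read a protein annotation table from TSV
#'
#' Columns: `protein_id`, `gene_name`, `length`, `sp_start`, `sp_end`,
#' `tm_segments` (semicolon-separated `start-end`), `domains`
#' (semicolon-separated `accession:source:start-end`), `go_terms`
#' (semicolon-separated), `description`. Empty cells mark absent optional
#' fields. All intervals are 1-based inclusive and validated against the
#' protein length; violations are hard errors naming the offending protein.
#'
#' @param path path to the TSV file.
#' @return a `protein_table`.
#' @export
read_protein_table <- function(path) {
  stopifnot_scalar_path(path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL)
  missing_cols <- setdiff(PROTEIN_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("protein table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0) {
    return(protein_table(character(0), integer(0)))
  }
  as_opt_int <- function(x) ifelse(nzchar(x), suppressWarnings(as.integer(x)),
                                   NA_integer_)
  tm <- lapply(seq_len(n), function(i) {
    tryCatch(parse_intervals(raw$tm_segments[i]),
             error = function(e) stop("row ", i, " (", raw$protein_id[i],
                                      "), column tm_segments: ",
                                      conditionMessage(e), call. = FALSE))
  })
  dom <- lapply(seq_len(n), function(i) parse_domain_cell(raw$domains[i],
                                                          raw$protein_id[i]))
  go <- lapply(raw$go_terms, split_cell)
  tryCatch(
    protein_table(protein_id = raw$protein_id,
                  gene_name = ifelse(nzchar(raw$gene_name), raw$gene_name,
                                     NA_character_),
                  length = as.integer(raw$length),
                  sp_start = as_opt_int(raw$sp_start),
                  sp_end = as_opt_int(raw$sp_end),
                  tm_segments = tm, domain_hits = dom, go_terms = go,
                  description = ifelse(nzchar(raw$description),
                                       raw$description, NA_character_)),
    error = function(e) stop("while reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' @rdname read_protein_table
#' @param tab a `protein_table` to serialize.
#' @export
write_protein_table <- function(tab, path) {
  stopifnot_scalar_path(path)
  out <- data.frame(
    protein_id = tab$protein_id,
    gene_name = ifelse(is.na(tab$gene_name), "", tab$gene_name),
    length = tab$length,
    sp_start = ifelse(is.na(tab$sp_start), "", tab$sp_start),
    sp_end = ifelse(is.na(tab$sp_end), "", tab$sp_end),
    tm_segments = vapply(tab$tm_segments, format_intervals, ""),
    domains = vapply(tab$domain_hits, format_domain_cell, ""),
    go_terms = vapply(tab$go_terms, join_cell, ""),
    description = ifelse(is.na(tab$description), "", tab$description),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CONDITION_TAGS <- c("stage", "male_L4", "herm_L4")

#' Construct an expression matrix of dcpm values
#'
#' Wraps a non-negative gene-by-condition matrix of dcpm (depth of coverage
#' per base per million reads) values together with a condition tag per
#' column (`"stage"`, `"male_L4"`, `"herm_L4"` or `"infection:<name>"`), the
#' expression threshold `tau` and the fold-change cutoff used for
#' upregulation calls.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   conditions in columns (colnames = condition labels).
#' @param tags named character vector mapping every condition label to its
#'   tag.
#' @param tau expression threshold in dcpm; a gene counts as expressed in a
#'   condition when its value is strictly greater than `tau`. Default 0.04.
#' @param fold_cutoff dimensionless fold-change cutoff; upregulation requires
#'   a fold strictly greater than this. Default 5.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, tags, tau = 0.04, fold_cutoff = 5) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs gene rownames and condition colnames", call. = FALSE)
  }
  if (any(is.na(values)) || any(values < 0)) {
    stop("dcpm values must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!is.numeric(fold_cutoff) || fold_cutoff <= 1) {
    stop("fold_cutoff must be > 1", call. = FALSE)
  }
  tags <- tags[colnames(values)]
  if (anyNA(names(tags)) || anyNA(tags)) {
    stop("every condition column needs a tag", call. = FALSE)
  }
  known <- tags %in% CONDITION_TAGS | startsWith(tags, "infection:")
  if (any(!known)) {
    stop("unknown condition tag: ", paste(unique(tags[!known]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(tags == "male_L4") > 0 && sum(tags == "herm_L4") != 1L) {
    stop("a male_L4 condition requires exactly one herm_L4 condition",
         call. = FALSE)
  }
  structure(list(values = values, tags = tags, tau = tau,
                 fold_cutoff = fold_cutoff),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "conditions (tau =", x$tau, "dcpm, fold cutoff =", x$fold_cutoff, ")\n")
  invisible(x)
}

#' Read an expression matrix and its condition-tag sidecar
#'
#' The matrix is TSV with the gene identifier in the first column (`gene_id`)
#' and one column per condition. The sidecar is a two-column TSV
#' (`condition`, `tag`) mapping each condition label to one of `stage`,
#' `male_L4`, `herm_L4` or `infection:<name>`.
#'
#' @inheritParams expression_matrix
#' @param path path to the matrix TSV.
#' @param conditions_path path to the sidecar tag file.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, conditions_path, tau = 0.04,
                                   fold_cutoff = 5) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (names(raw)[1] != "gene_id") {
    stop("first column of the expression matrix must be 'gene_id'",
         call. = FALSE)
  }
  blank <- !nzchar(raw$gene_id)
  if (any(blank)) {
    stop("empty gene_id in row ", which(blank)[1], call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  if (any(is.na(vals))) stop("non-numeric dcpm value in ", path, call. = FALSE)
  if (any(vals < 0)) {
    stop("negative dcpm value for gene ",
         raw$gene_id[which(rowSums(vals < 0) > 0)[1]], call. = FALSE)
  }
  rownames(vals) <- raw$gene_id
  side <- utils::read.delim(conditions_path, colClasses = "character",
                            check.names = FALSE)
  if (!all(c("condition", "tag") %in% names(side))) {
    stop("condition sidecar needs columns 'condition' and 'tag'",
         call. = FALSE)
  }
  tags <- stats::setNames(side$tag, side$condition)
  missing_tag <- setdiff(colnames(vals), names(tags))
  if (length(missing_tag)) {
    stop("no tag for condition(s): ", paste(missing_tag, collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(vals, tags, tau = tau, fold_cutoff = fold_cutoff)
}

#' @rdname read_expression_matrix
#' @param em an `expression_matrix` to serialize.
#' @export
write_expression_matrix <- function(em, path, conditions_path) {
  out <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(condition = names(em$tags), tag = unname(em$tags),
                     stringsAsFactors = FALSE)
  utils::write.table(side, conditions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read orthology evidence for phylogenetic-origin classification
#'
#' TSV columns: `gene_id`, `treefam_species` (semicolon-separated species
#' names, empty when the gene is in no family tree), `inparanoid_classes`
#' (semicolon-separated subset of `InP_cae`, `InP_met`, `InP_uni`),
#' `blast_species` (semicolon-separated best-hit species, empty when absent).
#'
#' @param path path to the TSV file.
#' @return a data frame with list columns `treefam_species`,
#'   `inparanoid_classes`, `blast_species` and logical columns
#'   `has_treefam` / `has_blast` distinguishing absent evidence from an
#'   empty set.
#' @export
read_origin_evidence <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  need <- c("gene_id", "treefam_species", "inparanoid_classes", "blast_species")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("origin evidence is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$gene_id)) {
    stop("duplicate gene_id in origin evidence", call. = FALSE)
  }
  cls <- lapply(raw$inparanoid_classes, split_cell)
  bad <- vapply(cls, function(x) length(setdiff(x, INPARANOID_CLASSES)) > 0,
                logical(1))
  if (any(bad)) {
    stop("unknown Inparanoid class for gene ", raw$gene_id[which(bad)[1]],
         call. = FALSE)
  }
  out <- data.frame(gene_id = raw$gene_id, stringsAsFactors = FALSE)
  out$treefam_species <- lapply(raw$treefam_species, split_cell)
  out$inparanoid_classes <- cls
  out$blast_species <- lapply(raw$blast_species, split_cell)
  out$has_treefam <- nzchar(raw$treefam_species)
  out$has_blast <- nzchar(raw$blast_species)
  out
}

#' @rdname read_origin_evidence
#' @param evidence an origin-evidence data frame to serialize.
#' @export
write_origin_evidence <- function(evidence, path) {
  out <- data.frame(
    gene_id = evidence$gene_id,
    treefam_species = vapply(evidence$treefam_species, join_cell, ""),
    inparanoid_classes = vapply(evidence$inparanoid_classes, join_cell, ""),
    blast_species = vapply(evidence$blast_species, join_cell, ""),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPARTMENTS <- c("ER", "Golgi", "endosome", "lysosome", "peroxisome",
                  "mitochondrion", "vesicle", "extracellular", "other")

#' Read organelle-localization evidence transferred from yeast/mouse
#'
#' TSV columns: `source_protein`, `source_organism` (`yeast` or `mouse`),
#' `compartment` (closed vocabulary: ER, Golgi, endosome, lysosome,
#' peroxisome, mitochondrion, vesicle, extracellular, other), and
#' `ortholog_gene_ids` (semicolon-separated study-species identifiers).
#'
#' @param path path to the TSV file.
#' @return a data frame with one evidence relation per row and a list column
#'   `ortholog_gene_ids`.
#' @export
read_localization_evidence <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  need <- c("source_protein", "source_organism", "compartment",
            "ortholog_gene_ids")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("localization evidence is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_org <- setdiff(unique(raw$source_organism), c("yeast", "mouse"))
  if (length(bad_org)) {
    stop("unknown source organism: ", bad_org[1], call. = FALSE)
  }
  bad_cmp <- setdiff(unique(raw$compartment), COMPARTMENTS)
  if (length(bad_cmp)) {
    stop("unknown compartment: ", bad_cmp[1], call. = FALSE)
  }
  out <- raw[, c("source_protein", "source_organism", "compartment")]
  out$ortholog_gene_ids <- lapply(raw$ortholog_gene_ids, split_cell)
  out
}

#' @rdname read_localization_evidence
#' @param evidence a localization-evidence data frame to serialize.
#' @export
write_localization_evidence <- function(evidence, path) {
  out <- data.frame(
    source_protein = evidence$source_protein,
    source_organism = evidence$source_organism,
    compartment = evidence$compartment,
    ortholog_gene_ids = vapply(evidence$ortholog_gene_ids, join_cell, ""),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLASSIFICATION_COLUMNS <- c("protein_id", "gene_name", "topology_class",
                            "effective_tm_count", "secretome_status", "origin",
                            "origin_tier", "functional_category", "family_id",
                            "architecture")

#' Write / read the per-protein classification table
#'
#' Deterministic column order, one row per protein, tab-separated; re-reading
#' reproduces the input. Missing assignments are empty cells.
#'
#' @param results a data frame carrying any subset of the classification
#'   columns plus `protein_id`.
#' @param path output path.
#' @export
write_classification_table <- function(results, path) {
  stopifnot_scalar_path(path)
  out <- data.frame(protein_id = as.character(results$protein_id),
                    stringsAsFactors = FALSE)
  for (col in setdiff(CLASSIFICATION_COLUMNS, "protein_id")) {
    v <- if (col %in% names(results)) as.character(results[[col]]) else
      rep(NA_character_, nrow(out))
    out[[col]] <- ifelse(is.na(v), "", v)
  }
  out <- out[order(out$protein_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification_table
#' @export
read_classification_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  missing_cols <- setdiff(CLASSIFICATION_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("classification table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(raw)) raw[[col]][!nzchar(raw[[col]])] <- NA_character_
  raw$effective_tm_count <- as.integer(raw$effective_tm_count)
  raw
}
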