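# Stage-, sex- and infection-associated expression enrichment.
#
# All thresholds are strict: a gene is expressed in a condition when its
# dcpm is strictly greater than tau, and upregulated when additionally its
# fold enrichment is strictly greater than the fold cutoff. Values below
# tau enter reference means as-is (tau is an expression filter only, not a
# floor). A zero reference mean with expression above tau yields fold
# +Inf: a gene expressed in exactly one stage is maximally stage-enriched.

# fold = x_s / mean(reference values), computed with a single division
# (numerator and denominator scale together, keeping fold(c*x) == fold(x)
# bit-exact whenever c*x itself is exactly representable)
enrichment_fold <- function(x_s, ref_sum, ref_n) {
  num <- x_s * ref_n
  if (ref_sum > 0) return(num / ref_sum)
  if (x_s > 0) Inf else NaN
}

stage_condition_names <- function(em) {
  names(em$tags)[em$tags %in% c("stage", "herm_L4")]
}

#' Stage-specific fold enrichment
#'
#' Fold enrichment of a gene in one stage is its dcpm divided by the mean
#' dcpm over all other stages. Stage conditions are those tagged `stage`
#' plus the `herm_L4` condition; `male_L4` and infection conditions never
#' enter stage means. With an `expression_matrix` the call is evaluated for
#' every gene and every stage; with a bare numeric vector of per-stage
#' values for one gene, `stage_index` selects the stage of interest.
#'
#' @param x an `expression_matrix`, or a numeric vector of per-stage dcpm
#'   values for a single gene.
#' @param stage_index stage position in `x` (vector form only).
#' @param tau,fold_cutoff thresholds; default from the matrix, or 0.04 / 5
#'   for the vector form.
#' @return data frame `gene_id`, `condition`, `fold`, `expressed`,
#'   `upregulated` (one row for the vector form).
#' @export
stage_enrichment <- function(x, stage_index = NULL, tau = 0.04,
                             fold_cutoff = 5) {
  if (is.numeric(x)) {
    if (length(x) < 2) stop("at least two stage conditions required",
                            call. = FALSE)
    if (is.null(stage_index)) stop("'stage_index' required for vector input",
                                   call. = FALSE)
    fold <- enrichment_fold(x[stage_index], sum(x[-stage_index]),
                            length(x) - 1L)
    expressed <- x[stage_index] > tau
    return(data.frame(gene_id = NA_character_,
                      condition = as.character(stage_index),
                      fold = fold, expressed = expressed,
                      upregulated = isTRUE(expressed && fold > fold_cutoff),
                      stringsAsFactors = FALSE))
  }
  em <- x
  stages <- stage_condition_names(em)
  if (length(stages) < 2) stop("at least two stage conditions required",
                               call. = FALSE)
  vals <- em$values[, stages, drop = FALSE]
  n_g <- nrow(vals)
  out <- vector("list", length(stages))
  row_sums <- rowSums(vals)
  for (s in seq_along(stages)) {
    ref_sum <- row_sums - vals[, s]
    fold <- ifelse(ref_sum > 0,
                   (vals[, s] * (length(stages) - 1L)) / ref_sum,
                   ifelse(vals[, s] > 0, Inf, NaN))
    expressed <- vals[, s] > em$tau
    out[[s]] <- data.frame(gene_id = rownames(vals),
                           condition = stages[s],
                           fold = fold,
                           expressed = expressed,
                           upregulated = expressed & !is.nan(fold) &
                             fold > em$fold_cutoff,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Male-specific fold enrichment
#'
#' Fold enrichment of male L4 expression over the L4 hermaphrodite
#' reference, with the same strict thresholds and zero-denominator rule as
#' [stage_enrichment()].
#'
#' @param x an `expression_matrix` with `male_L4` and `herm_L4` conditions,
#'   or a numeric vector of male-L4 dcpm values.
#' @param herm_L4 numeric vector of hermaphrodite-L4 dcpm values (vector
#'   form only).
#' @param tau,fold_cutoff thresholds (vector form only).
#' @return data frame `gene_id`, `condition` (`"male_L4"`), `fold`,
#'   `expressed`, `upregulated`.
#' @export
male_enrichment <- function(x, herm_L4 = NULL, tau = 0.04, fold_cutoff = 5) {
  if (is.numeric(x)) {
    male <- x
    herm <- herm_L4
    gene_id <- names(x) %||% rep(NA_character_, length(x))
  } else {
    em <- x
    male_col <- names(em$tags)[em$tags == "male_L4"]
    herm_col <- names(em$tags)[em$tags == "herm_L4"]
    if (length(male_col) != 1 || length(herm_col) != 1) {
      stop("matrix needs exactly one male_L4 and one herm_L4 condition",
           call. = FALSE)
    }
    male <- em$values[, male_col]
    herm <- em$values[, herm_col]
    gene_id <- rownames(em$values)
    tau <- em$tau
    fold_cutoff <- em$fold_cutoff
  }
  fold <- ifelse(herm > 0, male / herm, ifelse(male > 0, Inf, NaN))
  expressed <- male > tau
  data.frame(gene_id = gene_id, condition = "male_L4", fold = fold,
             expressed = expressed,
             upregulated = expressed & !is.nan(fold) & fold > fold_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Infection-upregulated genes
#'
#' Upregulation flags per infection condition are consumed as input (gene
#' lists from published infection profiles); a gene counts as
#' infection-upregulated in a condition iff it is flagged there AND its
#' post-infection dcpm is strictly above `tau` in that condition. The union
#' over conditions gives the "upregulated in at least one scenario" set.
#'
#' @param em an `expression_matrix` whose `infection:<name>` conditions hold
#'   post-infection dcpm values.
#' @param flags data frame `gene_id`, `condition` listing the flagged
#'   (gene, infection condition) pairs.
#' @return list with `per_gene` (named list gene -> character vector of
#'   conditions passing the threshold) and `union` (genes upregulated in at
#'   least one condition).
#' @export
infection_upregulated <- function(em, flags) {
  inf_conds <- names(em$tags)[startsWith(em$tags, "infection:")]
  bad <- setdiff(unique(flags$condition), inf_conds)
  if (length(bad)) {
    stop("flagged condition(s) not in matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  per_gene <- list()
  for (i in seq_len(nrow(flags))) {
    g <- flags$gene_id[i]
    cond <- flags$condition[i]
    if (!g %in% rownames(em$values)) next
    if (em$values[g, cond] > em$tau) {
      per_gene[[g]] <- union(per_gene[[g]], cond)
    }
  }
  list(per_gene = per_gene, union = names(per_gene))
}

#' Overlap of upregulated gene sets with protein classes
#'
#' For each upregulated set (one per condition) and each protein class
#' (`secreted`, `TM`, `other`), reports the share of the upregulated set in
#' the class (`frac_of_upregulated`, summing to 1 over the exhaustive
#' class partition) and the share of the class that is upregulated
#' (`frac_of_class`). Genes missing from the classification are counted as
#' `other` with a warning. Empty upregulated sets yield `NA` fractions.
#'
#' @param upregulated_sets named list: condition -> character vector of
#'   upregulated gene ids.
#' @param classification data frame `gene_id`, `class` with class in
#'   `c("secreted", "TM", "other")` covering the gene universe.
#' @return data frame `condition`, `class`, `n`, `frac_of_upregulated`,
#'   `frac_of_class`.
#' @export
class_overlap_summary <- function(upregulated_sets, classification) {
  classes <- c("secreted", "TM", "other")
  cls <- stats::setNames(as.character(classification$class),
                         classification$gene_id)
  class_sizes <- table(factor(cls, levels = classes))
  rows <- list()
  for (cond in names(upregulated_sets)) {
    genes <- upregulated_sets[[cond]]
    g_cls <- cls[genes]
    if (anyNA(g_cls)) {
      warning(sum(is.na(g_cls)), " upregulated gene(s) absent from the ",
              "classification; counted as 'other'", call. = FALSE)
      g_cls[is.na(g_cls)] <- "other"
    }
    tab <- table(factor(g_cls, levels = classes))
    n_up <- length(genes)
    rows[[cond]] <- data.frame(
      condition = cond, class = classes, n = as.integer(tab),
      frac_of_upregulated = if (n_up > 0) as.numeric(tab) / n_up else
        rep(NA_real_, 3),
      frac_of_class = ifelse(class_sizes > 0,
                             as.numeric(tab) / as.numeric(class_sizes),
                             NA_real_),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Genes upregulated per stage / in males
#'
#' Convenience wrapper turning [stage_enrichment()] and [male_enrichment()]
#' output into named gene sets per condition.
#'
#' @param em an `expression_matrix`.
#' @param include_male include the male-vs-hermaphrodite comparison when
#'   the matrix has a `male_L4` condition.
#' @return named list condition -> character vector of upregulated genes.
#' @export
upregulated_sets <- function(em, include_male = TRUE) {
  st <- stage_enrichment(em)
  stages <- stage_condition_names(em)
  sets <- stats::setNames(lapply(stages, function(s) {
    st$gene_id[st$condition == s & st$upregulated]
  }), stages)
  if (include_male && any(em$tags == "male_L4")) {
    me <- male_enrichment(em)
    sets[["male_L4"]] <- me$gene_id[me$upregulated]
  }
  sets
}
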