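# Topology reconciliation: combine signal-peptide and transmembrane-segment
# predictions into one of four topology classes per protein.
#
# When a signal peptide and a TM segment are predicted at the N-terminus in
# an overlapping fashion, the segment is treated as a misread of the signal
# peptide's hydrophobic core and dropped; a protein whose every TM segment is
# dropped this way is classed SP_only.

TOPOLOGY_CLASSES <- c("SP_only", "TM_only", "SP_and_TM", "neither")

#' Reconcile signal-peptide and transmembrane predictions
#'
#' A TM segment is dropped iff the protein has a signal peptide, the segment
#' shares at least one residue with the signal-peptide interval, and the
#' segment starts within the first `n_terminal_window` residues. The class is
#' then computed from signal-peptide presence and the effective (surviving)
#' TM-segment count. The rule is applied per segment: a protein keeping a
#' non-overlapping segment stays `SP_and_TM`.
#'
#' @param proteins a [protein_table()].
#' @param n_terminal_window N-terminal window in amino acids within which an
#'   overlapping segment may be dropped (default 40, generously covering
#'   signal-peptide lengths).
#' @return a data frame of class `topology_table`: `protein_id`,
#'   `topology_class`, `effective_tm_count`, list column
#'   `dropped_tm_segments`, plus `has_sp` and `length` carried through for
#'   downstream summaries.
#' @export
reconcile_topology <- function(proteins, n_terminal_window = 40) {
  n <- nrow(proteins)
  has_sp <- !is.na(proteins$sp_start)
  cls <- character(n)
  eff <- integer(n)
  dropped <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- proteins$tm_segments[[i]]
    if (has_sp[i] && nrow(tm) > 0) {
      ov <- vapply(seq_len(nrow(tm)), function(j) {
        interval_overlap(proteins$sp_start[i], proteins$sp_end[i],
                         tm[j, "start"], tm[j, "end"]) >= 1L &&
          tm[j, "start"] <= n_terminal_window
      }, logical(1))
      dropped[[i]] <- tm[ov, , drop = FALSE]
      eff[i] <- sum(!ov)
    } else {
      dropped[[i]] <- tm[0, , drop = FALSE]
      eff[i] <- nrow(tm)
    }
    cls[i] <- if (has_sp[i] && eff[i] == 0L) "SP_only"
      else if (has_sp[i]) "SP_and_TM"
      else if (eff[i] >= 1L) "TM_only"
      else "neither"
  }
  out <- data.frame(protein_id = proteins$protein_id,
                    topology_class = factor(cls, levels = TOPOLOGY_CLASSES),
                    effective_tm_count = eff,
                    has_sp = has_sp,
                    length = proteins$length,
                    stringsAsFactors = FALSE)
  out$dropped_tm_segments <- dropped
  class(out) <- c("topology_table", "data.frame")
  out
}

#' Histogram specification
#'
#' @param bin_edges strictly increasing positive integers; values fall into
#'   `[edge_i, edge_{i+1})` with a final open-ended `>= last_edge` bin.
#' @param normalized report fractions instead of counts.
#' @return an object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_edges, normalized = FALSE) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 1 || any(diff(bin_edges) <= 0) || any(bin_edges <= 0)) {
    stop("bin_edges must be strictly increasing and positive", call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, normalized = normalized),
            class = "histogram_spec")
}

bin_labels <- function(edges) {
  n <- length(edges)
  c(paste0("[", edges[-n], ",", edges[-1], ")"), paste0(">=", edges[n]))
}

bin_values <- function(x, spec) {
  edges <- spec$bin_edges
  labs <- bin_labels(edges)
  idx <- findInterval(x, edges)
  idx[x < edges[1]] <- NA_integer_  # below first edge: outside histogram
  tab <- tabulate(idx, nbins = length(labs))
  names(tab) <- labs
  if (spec$normalized) {
    tot <- sum(tab)
    if (tot > 0) tab <- tab / tot
  }
  tab
}

#' Distribution of transmembrane proteins by TM-segment count
#'
#' Only proteins with `effective_tm_count >= 1` contribute; counts sum to the
#' number of such proteins.
#'
#' @param topology a `topology_table` from [reconcile_topology()].
#' @param spec a [histogram_spec()]; default: one bin per count 1..14 plus a
#'   `>=15` bin.
#' @return named numeric vector of per-bin counts (or fractions).
#' @export
tm_count_histogram <- function(topology, spec = histogram_spec(1:15)) {
  counts <- topology$effective_tm_count[topology$effective_tm_count >= 1L]
  bin_values(counts, spec)
}

SIZE_SUBSETS <- c("all", "secreted", "secreted_no_domain", "TM", "TM_non_sr")

#' Size distribution of secreted and transmembrane proteins
#'
#' Supported subsets: `"all"` (every protein with a signal peptide or an
#' effective TM segment), `"secreted"` (the putative secretome),
#' `"secreted_no_domain"` (secretome members without any domain hit),
#' `"TM"` (effective TM count >= 1), and `"TM_non_sr"` (TM minus
#' serpentine-type GPCRs, i.e. putative chemoreceptors).
#'
#' @param proteins a [protein_table()].
#' @param topology matching `topology_table`.
#' @param subset one of the labels above.
#' @param spec a [histogram_spec()]; default 100-aa bins up to 1,000 aa plus
#'   a `>=1000` bin, normalized.
#' @param secretome character vector of secretome protein ids (required for
#'   the secreted subsets).
#' @param chemoreceptor_ids ids of serpentine-type GPCRs (for `TM_non_sr`).
#' @return named numeric vector; fractions sum to 1 over non-empty input
#'   when `spec$normalized`.
#' @export
size_distribution <- function(proteins, topology, subset = "all",
                              spec = histogram_spec(seq(1, 1001, by = 100),
                                                    normalized = TRUE),
                              secretome = NULL,
                              chemoreceptor_ids = character(0)) {
  if (!subset %in% SIZE_SUBSETS) {
    stop("unknown subset label '", subset, "'; expected one of: ",
         paste(SIZE_SUBSETS, collapse = ", "), call. = FALSE)
  }
  is_tm <- topology$effective_tm_count >= 1L
  keep <- switch(subset,
    all = topology$has_sp | is_tm,
    secreted = {
      if (is.null(secretome)) stop("subset 'secreted' needs 'secretome'",
                                   call. = FALSE)
      topology$protein_id %in% secretome
    },
    secreted_no_domain = {
      if (is.null(secretome)) stop("subset 'secreted_no_domain' needs 'secretome'",
                                   call. = FALSE)
      no_dom <- vapply(proteins$domain_hits, nrow, 0L) == 0L
      topology$protein_id %in% secretome &
        topology$protein_id %in% proteins$protein_id[no_dom]
    },
    TM = is_tm,
    TM_non_sr = is_tm & !(topology$protein_id %in% chemoreceptor_ids))
  bin_values(topology$length[keep], spec)
}

#' Candidate single-pass cell-surface receptors
#'
#' Single-pass TM proteins after removing proteins with known non-receptor
#' functions (enzymes such as proteases or glucosyltransferases, supplied as
#' an id list) and proteins assigned to organelles by localization transfer.
#'
#' @param topology a `topology_table`.
#' @param excluded_function_ids ids with known non-receptor functions.
#' @param organelle_assigned ids assigned to an organelle.
#' @return character vector of candidate protein ids.
#' @export
single_pass_candidates <- function(topology,
                                   excluded_function_ids = character(0),
                                   organelle_assigned = character(0)) {
  ids <- topology$protein_id[topology$effective_tm_count == 1L]
  setdiff(ids, union(excluded_function_ids, organelle_assigned))
}
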