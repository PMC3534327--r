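# Small builders used across test files.

make_protein <- function(id = "P1", len = 300L, sp = NULL, tm = NULL,
                         domains = NULL, gene = NA_character_,
                         go = character(0), desc = NA_character_) {
  tm_m <- if (is.null(tm)) NULL else
    list(matrix(as.integer(unlist(tm)), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("start", "end"))))
  dom_df <- if (is.null(domains)) NULL else {
    list(data.frame(accession = domains,
                    source = ifelse(startsWith(domains, "SM"), "smart",
                                    "pfam"),
                    start = 25L + (seq_along(domains) - 1L) * 10L,
                    end = 33L + (seq_along(domains) - 1L) * 10L,
                    stringsAsFactors = FALSE))
  }
  protein_table(protein_id = id, length = len, gene_name = gene,
                sp_start = if (is.null(sp)) NA_integer_ else sp[1],
                sp_end = if (is.null(sp)) NA_integer_ else sp[2],
                tm_segments = tm_m, domain_hits = dom_df,
                go_terms = list(go), description = desc)
}

bind_proteins <- function(...) {
  tabs <- list(...)
  out <- do.call(rbind, lapply(tabs, function(t) {
    class(t) <- "data.frame"
    t
  }))
  class(out) <- c("protein_table", "data.frame")
  out
}

tiny_expression <- function(values, conds, tags, tau = 0.04,
                            fold_cutoff = 5, genes = NULL) {
  m <- matrix(values, ncol = length(conds), byrow = TRUE)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- conds
  expression_matrix(m, stats::setNames(tags, conds), tau = tau,
                    fold_cutoff = fold_cutoff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
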