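# Synthetic proteome generator with planted ground truth.
#
# Emulates, at the annotation level, the four input classes the survey
# consumes: a protein annotation table, orthology evidence, transferred
# organelle localization, and a dcpm expression matrix. Every planted label
# is constructed so the pipeline's own rules decode it with zero error in
# the noise-free regime (e.g. a planted nematode-specific gene receives a
# family-tree species set satisfying the nematode rule). One global seed
# feeds named random streams, so adding a generated field never perturbs
# existing streams.

#' Simulation configuration
#'
#' Defaults state a world patterned on the C. elegans WormBase-210
#' annotation marginals: topology-class proportions from the printed
#' SP/TM counts over 20,242 genes, an organelle fraction matching the
#' 273/3,757 removal rate, a chemoreceptor share of 1,469/5,458 TM
#' proteins, functional-category proportions from the printed category
#' counts, and log-normal multiplicative dcpm noise.
#'
#' @param n_proteins number of proteins (= genes; one isoform per gene).
#' @param class_proportions probabilities over
#'   `c(SP_only, TM_only, SP_and_TM, neither)`.
#' @param organelle_fraction probability that an SP-only protein carries
#'   organelle evidence; `mito_share` of those are mitochondrial.
#' @param mito_share see above.
#' @param whitelist_fraction probability that an endomembrane-evidence
#'   protein is a known extracellular protein (whitelisted).
#' @param origin_proportions probabilities over
#'   `c(nematoda, metazoa, eukaryota, unclassified)`.
#' @param tier_mix probabilities over decisive tiers
#'   `c(treefam, inparanoid, blast)` for classified genes.
#' @param chemo_fraction share of TM proteins that are serpentine-type
#'   GPCRs (putative chemoreceptors).
#' @param tm_category_proportions probabilities over the eight domain
#'   categories plus `no_information`, for non-chemoreceptor TM proteins.
#' @param tm_count_distribution probability vector over TM-segment counts
#'   1, 2, ... for non-chemoreceptor TM proteins.
#' @param size_distribution list: `meanlog_small`, `sdlog_small`,
#'   `meanlog_large`, `sdlog_large`, `w_small_secreted`, `w_small_other` —
#'   a two-component log-normal length mixture letting the
#'   small-secreted-proteins-overrepresented pattern be planted.
#' @param family_fraction share of secretome proteins planted into a
#'   family; `family_weights` sets the relative family sizes.
#' @param family_weights named numeric vector over the default families.
#' @param sp_overlap_fraction share of SP-only proteins additionally given
#'   an N-terminal TM segment overlapping the signal peptide (to be
#'   dropped by reconciliation).
#' @param excluded_fraction share of single-pass TM proteins flagged with
#'   known non-receptor functions.
#' @param tm_organelle_fraction share of TM proteins with organelle
#'   evidence.
#' @param expression list: `n_stages`, `planted_fraction`, `planted_fold`,
#'   `male_planted_fraction`, `noise_sigma` (log-normal sigma),
#'   `baseline_meanlog`, `baseline_sdlog`, `infection_flag_fraction`,
#'   `infection_fold`, `tau`, `fold_cutoff`; or `NULL` to skip expression.
#' @param max_length capacity cap in amino acids; a TM-count distribution
#'   needing more is an error.
#' @param seed integer seed for all random streams.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_proteins = 2000,
    class_proportions = c(SP_only = 0.186, TM_only = 0.175,
                          SP_and_TM = 0.095, neither = 0.544),
    organelle_fraction = 0.0727, mito_share = 0.242,
    whitelist_fraction = 0.02,
    origin_proportions = c(nematoda = 0.45, metazoa = 0.25,
                           eukaryota = 0.26, unclassified = 0.04),
    tier_mix = c(treefam = 0.60, inparanoid = 0.25, blast = 0.15),
    chemo_fraction = 0.269,
    tm_category_proportions = c(channels = 0.086, transporters = 0.121,
                                enzymes = 0.130, signaling = 0.089,
                                trafficking = 0.016, adhesion = 0.015,
                                ECM = 0.014, other = 0.202,
                                no_information = 0.327),
    tm_count_distribution = c(0.30, 0.09, 0.06, 0.07, 0.05, 0.14, 0.17,
                              0.05, 0.03, 0.02, 0.01, 0.01),
    size_distribution = list(meanlog_small = log(140), sdlog_small = 0.4,
                             meanlog_large = log(450), sdlog_large = 0.5,
                             w_small_secreted = 0.6, w_small_other = 0.35),
    family_fraction = 0.35,
    family_weights = c(small_c_lectins = 0.28, collagens = 0.20,
                       shk_proteins = 0.08, transthyretin_like = 0.07,
                       insulins = 0.05, flp_genes = 0.04, nlp_genes = 0.05,
                       nsp_genes = 0.07, unnamed = 0.16),
    sp_overlap_fraction = 0.25,
    excluded_fraction = 0.2, tm_organelle_fraction = 0.088,
    expression = list(n_stages = 4, planted_fraction = 0.05,
                      planted_fold = 8, male_planted_fraction = 0.05,
                      noise_sigma = 0.2, baseline_meanlog = 0,
                      baseline_sdlog = 1, infection_flag_fraction = 0.08,
                      infection_fold = 4, tau = 0.04, fold_cutoff = 5),
    max_length = 5000, seed = 42) {
  cfg <- as.list(environment())
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  tm_count_distribution <- tm_count_distribution / 1  # keep names out
  check_probs(class_proportions, "class_proportions")
  check_probs(origin_proportions, "origin_proportions")
  check_probs(tier_mix, "tier_mix")
  check_probs(tm_category_proportions, "tm_category_proportions")
  check_probs(cfg$tm_count_distribution, "tm_count_distribution")
  check_probs(family_weights, "family_weights")
  k_max <- max(which(cfg$tm_count_distribution > 0), 7L)
  if (56L + 30L * k_max > max_length) {
    stop("tm_count_distribution puts mass on counts exceeding the length ",
         "capacity max_length = ", max_length, call. = FALSE)
  }
  if (!is.null(expression)) {
    if (expression$planted_fold <= 1) stop("planted_fold must be > 1",
                                           call. = FALSE)
    if (expression$noise_sigma < 0) stop("noise_sigma must be >= 0",
                                         call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Default synthetic family definitions
#'
#' The family rules the generator plants against: gene-name-prefix families
#' (clec-, col-, ins-, flp-, nlp-, nsp-) and accession families (ShK toxin
#' domain PF01549; transthyretin-like PF00576).
#'
#' @return list of [family_definition()] objects.
#' @export
default_family_defs <- function() {
  list(family_definition("small_c_lectins", gene_prefixes = "clec-",
                         priority = 10),
       family_definition("collagens", gene_prefixes = "col-", priority = 20),
       family_definition("insulins", gene_prefixes = "ins-", priority = 30),
       family_definition("flp_genes", gene_prefixes = "flp-", priority = 40),
       family_definition("nlp_genes", gene_prefixes = "nlp-", priority = 50),
       family_definition("nsp_genes", gene_prefixes = "nsp-", priority = 60),
       family_definition("shk_proteins", accessions = "PF01549",
                         priority = 70),
       family_definition("transthyretin_like", accessions = "PF00576",
                         priority = 80))
}

FAMILY_PREFIXES <- c(small_c_lectins = "clec-", collagens = "col-",
                     insulins = "ins-", flp_genes = "flp-",
                     nlp_genes = "nlp-", nsp_genes = "nsp-")
FAMILY_ACCESSIONS <- c(shk_proteins = "PF01549",
                       transthyretin_like = "PF00576")

# Category -> accessions the default rule set recognizes; "other" uses
# accessions deliberately outside every rule.
CATEGORY_ACCESSIONS <- list(
  channels = c("PF00876", "PF02931", "PF07885", "PF00858"),
  transporters = c("PF07690", "PF00664", "PF00083", "PF00324"),
  enzymes = c("PF01757", "PF00201", "SM00382"),
  signaling = c("PF00002", "PF00069", "PF01094", "SM00044"),
  trafficking = "SM00397",
  adhesion = c("PF07062", "PF00028", "SM00112"),
  ECM = c("PF00100", "SM00241", "PF01391"),
  other = c("PF00335", "PF00646", "PF00096"))

NEUTRAL_SECRETED_ACCESSIONS <- c("PF00008", "PF00431", "PF00090", "PF00094",
                                 "PF07679", "PF00057")

make_domains <- function(accessions, len) {
  m <- length(accessions)
  if (m == 0) {
    return(data.frame(accession = character(0), source = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  start <- 25L + (seq_len(m) - 1L) * 10L
  data.frame(accession = accessions,
             source = ifelse(startsWith(accessions, "SM"), "smart", "pfam"),
             start = start, end = start + 8L, stringsAsFactors = FALSE)
}

place_tm_segments <- function(k, first_start) {
  if (k == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  start <- as.integer(first_start) + (seq_len(k) - 1L) * 30L
  cbind(start = start, end = start + 20L)
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Produces a [protein_table()], origin-evidence and localization-evidence
#' tables, an expression matrix with planted stage/sex/infection
#' upregulation, and a `truth` object recording every planted label.
#' Deterministic given `config$seed`. Signal peptides start at residue 1;
#' TM segments within a protein never overlap.
#'
#' @param config a [simulation_config()].
#' @return a list of class `synthetic_survey` with elements `proteins`,
#'   `origin`, `localization`, `expression` (or `NULL`),
#'   `infection_flags`, `truth`, `config`. `truth` holds a per-protein
#'   data frame plus the planted id sets (`chemoreceptor_ids`,
#'   `excluded_function_ids`, `organelle_assigned`, `whitelist`) and
#'   per-gene expression truth.
#' @export
generate_proteome <- function(config = simulation_config()) {
  n <- config$n_proteins
  seed <- config$seed
  empty_truth <- data.frame(
    protein_id = character(0), gene_id = character(0),
    topology_class = character(0), effective_tm_count = integer(0),
    organelle = character(0), origin = character(0), tier = character(0),
    category = character(0), family_id = character(0),
    architecture = character(0), receptor_candidate = logical(0),
    stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(
      proteins = protein_table(character(0), integer(0)),
      origin = data.frame(gene_id = character(0)),
      localization = data.frame(source_protein = character(0),
                                source_organism = character(0),
                                compartment = character(0)),
      expression = NULL,
      infection_flags = data.frame(gene_id = character(0),
                                   condition = character(0)),
      truth = list(per_protein = empty_truth,
                   chemoreceptor_ids = character(0),
                   excluded_function_ids = character(0),
                   organelle_assigned = character(0),
                   whitelist = character(0)),
      config = config), class = "synthetic_survey"))
  }
  protein_id <- sprintf("SYN%05d.1", seq_len(n))
  gene_id <- sprintf("gene-%05d", seq_len(n))

  ## topology -----------------------------------------------------------
  cls <- with_stream(seed, "topology", {
    sample(names(config$class_proportions), n, replace = TRUE,
           prob = config$class_proportions)
  })
  is_tm_class <- cls %in% c("TM_only", "SP_and_TM")
  chemo <- logical(n)
  chemo[is_tm_class] <- with_stream(seed, "chemoreceptor", {
    stats::runif(sum(is_tm_class)) < config$chemo_fraction
  })
  tm_count <- integer(n)
  k_probs <- config$tm_count_distribution
  tm_count[is_tm_class] <- with_stream(seed, "tm_count", {
    sample(seq_along(k_probs), sum(is_tm_class), replace = TRUE,
           prob = k_probs)
  })
  tm_count[chemo] <- with_stream(seed, "chemo_tm_count", {
    sample(6:7, sum(chemo), replace = TRUE, prob = c(0.35, 0.65))
  })
  sp_len <- with_stream(seed, "sp_length", sample(16:28, n, replace = TRUE))
  sp_overlap <- logical(n)
  sp_overlap[cls == "SP_only"] <- with_stream(seed, "sp_overlap", {
    stats::runif(sum(cls == "SP_only")) < config$sp_overlap_fraction
  })

  ## lengths ------------------------------------------------------------
  sz <- config$size_distribution
  w_small <- ifelse(cls == "SP_only", sz$w_small_secreted, sz$w_small_other)
  len <- with_stream(seed, "length", {
    comp_small <- stats::runif(n) < w_small
    round(ifelse(comp_small,
                 stats::rlnorm(n, sz$meanlog_small, sz$sdlog_small),
                 stats::rlnorm(n, sz$meanlog_large, sz$sdlog_large)))
  })
  len <- pmax(len, 60L)
  first_start <- ifelse(cls == "SP_and_TM", 51L, 10L)
  need <- ifelse(tm_count > 0, first_start + 30L * tm_count + 5L, 0L)
  len <- as.integer(pmax(len, need))

  ## assemble intervals -------------------------------------------------
  sp_start <- ifelse(cls %in% c("SP_only", "SP_and_TM"), 1L, NA_integer_)
  sp_end <- ifelse(is.na(sp_start), NA_integer_, pmin(sp_len, len - 30L))
  tm_segments <- vector("list", n)
  eff_count <- integer(n)
  for (i in seq_len(n)) {
    if (cls[i] == "SP_only" && sp_overlap[i]) {
      # one N-terminal segment overlapping the SP: dropped on reconciliation
      tm_segments[[i]] <- cbind(start = 5L, end = 25L)
      eff_count[i] <- 0L
    } else if (tm_count[i] > 0) {
      tm_segments[[i]] <- place_tm_segments(tm_count[i], first_start[i])
      eff_count[i] <- tm_count[i]
    } else {
      tm_segments[[i]] <- place_tm_segments(0L, 0L)
      eff_count[i] <- 0L
    }
  }

  ## organelle evidence (SP-only and TM proteins) -----------------------
  organelle <- rep("none", n)
  idx_sp <- which(cls == "SP_only")
  org_draw <- with_stream(seed, "organelle", {
    list(hit = stats::runif(length(idx_sp)) < config$organelle_fraction,
         mito = stats::runif(length(idx_sp)) < config$mito_share,
         comp = sample(setdiff(ENDOMEMBRANE_DEFAULT, "peroxisome"),
                       length(idx_sp), replace = TRUE))
  })
  organelle[idx_sp[org_draw$hit & org_draw$mito]] <- "mitochondrial"
  organelle[idx_sp[org_draw$hit & !org_draw$mito]] <- "endomembrane"
  endo_idx <- idx_sp[org_draw$hit & !org_draw$mito]
  whitelist <- with_stream(seed, "whitelist", {
    protein_id[endo_idx[stats::runif(length(endo_idx)) <
                          config$whitelist_fraction]]
  })
  tm_idx <- which(eff_count >= 1L)
  tm_org <- with_stream(seed, "tm_organelle", {
    list(hit = stats::runif(length(tm_idx)) < config$tm_organelle_fraction,
         comp = sample(c(ENDOMEMBRANE_DEFAULT, "mitochondrion"),
                       length(tm_idx), replace = TRUE))
  })
  loc_rows <- list()
  add_loc <- function(ids, comps) {
    if (length(ids) == 0) return(NULL)
    data.frame(source_protein = sprintf("SRC%05d", seq_along(ids)),
               source_organism = rep(c("yeast", "mouse"),
                                     length.out = length(ids)),
               compartment = comps, stringsAsFactors = FALSE,
               ortholog = ids)
  }
  loc1 <- add_loc(protein_id[idx_sp[org_draw$hit]],
                  ifelse(org_draw$mito[org_draw$hit], "mitochondrion",
                         org_draw$comp[org_draw$hit]))
  loc2 <- add_loc(protein_id[tm_idx[tm_org$hit]], tm_org$comp[tm_org$hit])
  localization <- do.call(rbind, Filter(Negate(is.null), list(loc1, loc2)))
  if (is.null(localization)) {
    localization <- data.frame(source_protein = character(0),
                               source_organism = character(0),
                               compartment = character(0),
                               ortholog = character(0),
                               stringsAsFactors = FALSE)
  }
  localization$source_protein <- sprintf("SRC%05d",
                                         seq_len(nrow(localization)))
  localization$ortholog_gene_ids <- as.list(localization$ortholog)
  localization$ortholog <- NULL
  organelle_assigned <- unique(unlist(localization$ortholog_gene_ids))

  ## secretome truth ----------------------------------------------------
  secretome_truth <- protein_id[cls == "SP_only" &
                                  (organelle == "none" |
                                     protein_id %in% whitelist)]
  # mitochondrial removal admits no whitelist override
  secretome_truth <- setdiff(secretome_truth,
                             protein_id[organelle == "mitochondrial"])

  ## families (secretome + a few members without SP) --------------------
  gene_name <- gene_id
  family <- rep(NA_character_, n)
  fam_domains <- vector("list", n)  # accession vectors added per protein
  sec_idx <- which(protein_id %in% secretome_truth)
  fam_draw <- with_stream(seed, "family", {
    hit <- stats::runif(length(sec_idx)) < config$family_fraction
    fam <- sample(names(config$family_weights), length(sec_idx),
                  replace = TRUE, prob = config$family_weights)
    neither_idx <- which(cls == "neither")
    extra <- neither_idx[stats::runif(length(neither_idx)) < 0.01]
    extra_fam <- sample(names(FAMILY_PREFIXES), length(extra),
                        replace = TRUE)
    list(hit = hit, fam = fam, extra = extra, extra_fam = extra_fam,
         n_copies = sample(1:2, length(sec_idx), replace = TRUE))
  })
  assign_family <- function(i, fam_id, copies = 1L) {
    if (fam_id == "unnamed") return(invisible(NULL))
    family[i] <<- fam_id
    if (fam_id %in% names(FAMILY_PREFIXES)) {
      gene_name[i] <<- paste0(FAMILY_PREFIXES[[fam_id]],
                              sum(family == fam_id, na.rm = TRUE))
      if (fam_id == "small_c_lectins") {
        fam_domains[[i]] <<- rep("PF00059", copies)
      }
    } else {
      fam_domains[[i]] <<- rep(FAMILY_ACCESSIONS[[fam_id]], copies)
    }
  }
  for (j in seq_along(sec_idx)) {
    if (fam_draw$hit[j]) {
      assign_family(sec_idx[j], fam_draw$fam[j], fam_draw$n_copies[j])
    }
  }
  for (j in seq_along(fam_draw$extra)) {
    assign_family(fam_draw$extra[j], fam_draw$extra_fam[j])
  }

  ## architecture (secreted proteins) -----------------------------------
  repeat_min <- 5L
  arch_domains <- vector("list", n)
  arch_draw <- with_stream(seed, "architecture", {
    r <- stats::runif(length(sec_idx))
    kind <- ifelse(r < 0.012, "complex", ifelse(r < 0.03, "repetitive",
                                                "simple"))
    list(kind = kind,
         rep_copies = sample(repeat_min:(repeat_min + 7L), length(sec_idx),
                             replace = TRUE),
         simple_n = sample(0:2, length(sec_idx), replace = TRUE,
                           prob = c(0.6, 0.3, 0.1)),
         acc = matrix(sample(NEUTRAL_SECRETED_ACCESSIONS,
                             4L * length(sec_idx), replace = TRUE),
                      ncol = 4L))
  })
  for (j in seq_along(sec_idx)) {
    i <- sec_idx[j]
    arch_domains[[i]] <- switch(arch_draw$kind[j],
      complex = NEUTRAL_SECRETED_ACCESSIONS[1:4],
      repetitive = rep(arch_draw$acc[j, 1L], arch_draw$rep_copies[j]),
      simple = if (arch_draw$simple_n[j] > 0)
        unique(arch_draw$acc[j, seq_len(arch_draw$simple_n[j])]) else
          character(0))
  }

  ## TM functional categories -------------------------------------------
  category <- rep(NA_character_, n)
  cat_domains <- vector("list", n)
  description <- rep(NA_character_, n)
  go_terms <- rep(list(character(0)), n)
  non_chemo_tm <- setdiff(which(eff_count >= 1L), which(chemo))
  cat_draw <- with_stream(seed, "tm_category", {
    cat <- sample(names(config$tm_category_proportions),
                  length(non_chemo_tm), replace = TRUE,
                  prob = config$tm_category_proportions)
    list(cat = cat,
         acc_pick = stats::runif(length(non_chemo_tm)),
         lgc = stats::runif(length(non_chemo_tm)) < 0.15,
         other_desc = stats::runif(length(non_chemo_tm)) < 0.3)
  })
  lgc_counter <- 0L
  for (j in seq_along(non_chemo_tm)) {
    i <- non_chemo_tm[j]
    cat_j <- cat_draw$cat[j]
    category[i] <- cat_j
    if (cat_j == "no_information") next
    accs <- CATEGORY_ACCESSIONS[[cat_j]]
    if (cat_j == "channels" && cat_draw$lgc[j]) {
      lgc_counter <- lgc_counter + 1L
      gene_name[i] <- paste0("lgc-", lgc_counter)   # gene-name evidence
    } else if (cat_j == "other" && cat_draw$other_desc[j]) {
      description[i] <- "uncharacterized membrane protein"
    } else {
      pick <- 1L + floor(cat_draw$acc_pick[j] * length(accs))
      cat_domains[[i]] <- accs[min(pick, length(accs))]
    }
  }
  category[chemo] <- "chemoreceptor"

  ## receptor candidates -------------------------------------------------
  single_pass <- which(eff_count == 1L)
  excl_hit <- with_stream(seed, "excluded", {
    stats::runif(length(single_pass)) < config$excluded_fraction
  })
  excluded_function_ids <- protein_id[single_pass[excl_hit]]
  receptor_candidate <- rep(FALSE, n)
  receptor_candidate[single_pass] <- !excl_hit &
    !(protein_id[single_pass] %in% organelle_assigned)

  ## assemble protein table ----------------------------------------------
  domain_hits <- vector("list", n)
  for (i in seq_len(n)) {
    accs <- c(fam_domains[[i]], arch_domains[[i]], cat_domains[[i]])
    domain_hits[[i]] <- make_domains(accs, len[i])
    need_dom <- if (length(accs)) 25L + length(accs) * 10L + 5L else 0L
    if (need_dom > len[i]) len[i] <- need_dom
  }
  go_decorate <- with_stream(seed, "go_terms", {
    stats::runif(n) < 0.1
  })
  for (i in which(go_decorate)) {
    if (!is.na(category[i]) && category[i] %in% c("no_information")) next
    if (is.na(category[i]) || category[i] == "chemoreceptor") next
    go_terms[[i]] <- "GO:0016020"
  }
  proteins <- protein_table(protein_id = protein_id, length = len,
                            gene_name = gene_name, sp_start = sp_start,
                            sp_end = sp_end, tm_segments = tm_segments,
                            domain_hits = domain_hits, go_terms = go_terms,
                            description = description)

  ## gene identifiers: the post-rename gene names key all per-gene tables
  gene_id <- gene_name

  ## origin evidence ------------------------------------------------------
  origin_lab <- with_stream(seed, "origin", {
    sample(names(config$origin_proportions), n, replace = TRUE,
           prob = config$origin_proportions)
  })
  tier_lab <- rep("none", n)
  classified <- origin_lab != "unclassified"
  tier_lab[classified] <- with_stream(seed, "tier", {
    sample(names(config$tier_mix), sum(classified), replace = TRUE,
           prob = config$tier_mix)
  })
  ev_draw <- with_stream(seed, "origin_evidence", {
    list(outgroup = stats::runif(n) < 0.5,
         tf_present_undecided = stats::runif(n) < 0.3,
         extra_lower = stats::runif(n) < 0.5,
         pick = stats::runif(n))
  })
  undecided_tf <- c("C. elegans", "H. sapiens", "S. cerevisiae")
  treefam_species <- vector("list", n)
  inparanoid_classes <- vector("list", n)
  blast_species <- vector("list", n)
  has_treefam <- logical(n)
  has_blast <- logical(n)
  for (i in seq_len(n)) {
    org <- origin_lab[i]
    tier <- tier_lab[i]
    if (tier == "treefam") {
      has_treefam[i] <- TRUE
      treefam_species[[i]] <- switch(org,
        nematoda = c("C. elegans", "C. briggsae",
                     if (ev_draw$outgroup[i]) "H. sapiens"),
        metazoa = c("C. elegans", "H. sapiens", "D. melanogaster",
                    if (ev_draw$outgroup[i]) "D. rerio"),
        eukaryota = c("C. elegans", "H. sapiens", "D. melanogaster",
                      if (ev_draw$pick[i] < 0.5) "S. cerevisiae" else
                        "A. thaliana"))
      if (ev_draw$extra_lower[i]) {        # decided higher: lower tiers noise
        inparanoid_classes[[i]] <-
          INPARANOID_CLASSES[[1L + (ev_draw$pick[i] %/% (1 / 3))]]
      }
    } else if (tier == "inparanoid") {
      if (ev_draw$tf_present_undecided[i]) {
        has_treefam[i] <- TRUE
        treefam_species[[i]] <- undecided_tf
      }
      inparanoid_classes[[i]] <- switch(org,
        nematoda = "InP_cae",
        metazoa = if (ev_draw$pick[i] < 0.5) "InP_met" else
          c("InP_cae", "InP_met"),
        eukaryota = if (ev_draw$pick[i] < 0.5) "InP_uni" else
          c("InP_cae", "InP_met", "InP_uni"))
      if (ev_draw$extra_lower[i]) {
        has_blast[i] <- TRUE
        blast_species[[i]] <- "C. remanei"
      }
    } else if (tier == "blast") {
      if (ev_draw$tf_present_undecided[i]) {
        has_treefam[i] <- TRUE
        treefam_species[[i]] <- undecided_tf
      }
      has_blast[i] <- TRUE
      blast_species[[i]] <- switch(org,
        nematoda = c("C. remanei",
                     if (ev_draw$outgroup[i]) "C. briggsae"),
        metazoa = c(if (ev_draw$outgroup[i]) "C. briggsae",
                    if (ev_draw$pick[i] < 0.5) "H. sapiens" else
                      "M. musculus"),
        eukaryota = c(if (ev_draw$pick[i] < 0.5) "S. cerevisiae" else
                        "A. thaliana", "H. sapiens"))
    } else {                               # unclassified
      if (ev_draw$tf_present_undecided[i]) {
        has_treefam[i] <- TRUE
        treefam_species[[i]] <- undecided_tf
      }
      if (ev_draw$extra_lower[i]) {
        has_blast[i] <- TRUE
        blast_species[[i]] <- "D. melanogaster"  # in no BLAST rule list
      }
    }
    treefam_species[[i]] <- treefam_species[[i]] %||% character(0)
    inparanoid_classes[[i]] <- inparanoid_classes[[i]] %||% character(0)
    blast_species[[i]] <- blast_species[[i]] %||% character(0)
  }
  origin_ev <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  origin_ev$treefam_species <- treefam_species
  origin_ev$inparanoid_classes <- inparanoid_classes
  origin_ev$blast_species <- blast_species
  origin_ev$has_treefam <- has_treefam
  origin_ev$has_blast <- has_blast

  ## expression -----------------------------------------------------------
  expr <- NULL
  infection_flags <- data.frame(gene_id = character(0),
                                condition = character(0),
                                stringsAsFactors = FALSE)
  expr_truth <- NULL
  if (!is.null(config$expression)) {
    ex <- config$expression
    stage_names <- c("embryo", "L1", "L2", "L3", "adult",
                     "dauer")[seq_len(ex$n_stages)]
    inf_names <- c("bact1", "bact2", "bact3", "fung1", "fung2")
    conds <- c(stage_names, "herm_L4", "male_L4", inf_names)
    tags <- stats::setNames(c(rep("stage", length(stage_names)), "herm_L4",
                              "male_L4", paste0("infection:", inf_names)),
                            conds)
    draws <- with_stream(seed, "expression", {
      baseline <- stats::rlnorm(n, ex$baseline_meanlog, ex$baseline_sdlog)
      planted <- stats::runif(n) < ex$planted_fraction
      planted_cond <- sample(c(stage_names, "herm_L4"), n, replace = TRUE)
      male_planted <- !planted & stats::runif(n) < ex$male_planted_fraction
      flags <- matrix(stats::runif(n * length(inf_names)) <
                        ex$infection_flag_fraction, nrow = n)
      noise <- matrix(stats::rlnorm(n * length(conds), 0, ex$noise_sigma),
                      nrow = n)
      list(baseline = baseline, planted = planted,
           planted_cond = planted_cond, male_planted = male_planted,
           flags = flags, noise = noise)
    })
    baseline <- draws$baseline
    # plant enrichment only in robustly expressed genes, so planted truth
    # is decodable: the expression filter tau never masks a planted gene
    baseline[draws$planted | draws$male_planted] <-
      pmax(baseline[draws$planted | draws$male_planted], 0.5)
    vals <- matrix(rep(baseline, length(conds)), nrow = n,
                   dimnames = list(gene_id, conds))
    for (g in which(draws$planted)) {
      vals[g, draws$planted_cond[g]] <- baseline[g] * ex$planted_fold
    }
    vals[draws$male_planted, "male_L4"] <-
      baseline[draws$male_planted] * ex$planted_fold
    flagged <- draws$flags
    for (k in seq_along(inf_names)) {
      vals[flagged[, k], inf_names[k]] <-
        vals[flagged[, k], inf_names[k]] * ex$infection_fold
    }
    vals <- vals * draws$noise
    expr <- expression_matrix(vals, tags, tau = ex$tau,
                              fold_cutoff = ex$fold_cutoff)
    flag_idx <- which(flagged, arr.ind = TRUE)
    infection_flags <- data.frame(gene_id = gene_id[flag_idx[, 1]],
                                  condition = inf_names[flag_idx[, 2]],
                                  stringsAsFactors = FALSE)
    infection_flags <-
      infection_flags[order(infection_flags$gene_id,
                            infection_flags$condition), , drop = FALSE]
    rownames(infection_flags) <- NULL
    # planted infection truth: flagged AND above tau after noise
    inf_truth <- lapply(seq_len(n), function(g) {
      ks <- which(flagged[g, ] & vals[g, inf_names] > ex$tau)
      inf_names[ks]
    })
    expr_truth <- list(
      planted_stage = ifelse(draws$planted, draws$planted_cond,
                             NA_character_),
      planted_male = draws$male_planted,
      infection_conditions = stats::setNames(inf_truth, gene_id))
  }

  ## truth ----------------------------------------------------------------
  arch_truth <- rep(NA_character_, n)
  for (i in sec_idx) {
    accs <- c(fam_domains[[i]], arch_domains[[i]])
    distinct <- length(unique(accs))
    total <- length(accs)
    arch_truth[i] <- if (distinct >= 4L) "complex" else
      if (distinct <= 2L && total >= repeat_min) "repetitive" else "simple"
  }
  per_protein <- data.frame(
    protein_id = protein_id, gene_id = gene_id,
    topology_class = cls, effective_tm_count = eff_count,
    organelle = organelle, origin = origin_lab, tier = tier_lab,
    category = category, family_id = family, architecture = arch_truth,
    receptor_candidate = receptor_candidate,
    stringsAsFactors = FALSE)
  structure(list(proteins = proteins, origin = origin_ev,
                 localization = localization, expression = expr,
                 infection_flags = infection_flags,
                 truth = list(per_protein = per_protein,
                              secretome = secretome_truth,
                              chemoreceptor_ids = protein_id[chemo],
                              excluded_function_ids = excluded_function_ids,
                              organelle_assigned = organelle_assigned,
                              whitelist = whitelist,
                              expression = expr_truth),
                 config = config),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("synthetic_survey:", nrow(x$proteins), "proteins, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Run the full pipeline on generated data and score label recovery
#'
#' Generates a proteome from `config`, runs every pipeline stage, and
#' reports exact-match agreement with the planted truth per module, plus
#' sensitivity and false-positive rate for expression upregulation calls.
#'
#' @param config a [simulation_config()].
#' @param n_terminal_window window passed to [reconcile_topology()].
#' @return list with `agreement` (named fractions: topology, secretome,
#'   origin, tier, category, family, architecture, receptor_candidates),
#'   `expression` (sensitivity, false_positive_rate, infection_exact),
#'   and the generated `data`.
#' @export
run_end_to_end_recovery <- function(config = simulation_config(),
                                    n_terminal_window = 40) {
  sim <- generate_proteome(config)
  truth <- sim$truth$per_protein
  topo <- reconcile_topology(sim$proteins, n_terminal_window)
  agree <- c(topology = mean(as.character(topo$topology_class) ==
                               truth$topology_class &
                               topo$effective_tm_count ==
                               truth$effective_tm_count))
  loc_map <- transfer_localization(sim$localization)
  secr <- build_secretome(topo, loc_map,
                          extracellular_whitelist = sim$truth$whitelist)
  agree["secretome"] <- as.numeric(
    setequal(secr$secretome, sim$truth$secretome) &&
      setequal(secr$removed_mitochondrial,
               truth$protein_id[truth$organelle == "mitochondrial"]) &&
      setequal(secr$removed_endomembrane,
               setdiff(truth$protein_id[truth$organelle == "endomembrane"],
                       sim$truth$whitelist)))
  oc <- classify_origin(sim$origin)
  stopifnot(identical(oc$gene_id, truth$gene_id))
  agree["origin"] <- mean(as.character(oc$origin) == truth$origin)
  agree["tier"] <- mean(as.character(oc$tier) == truth$tier)
  asg <- assign_group(sim$proteins, topo,
                      chemoreceptor_ids = sim$truth$chemoreceptor_ids)
  truth_cat <- truth$category[match(asg$protein_id, truth$protein_id)]
  agree["category"] <- mean(as.character(asg$category) == truth_cat)
  fams <- group_families(sim$proteins, default_family_defs())
  same_fam <- mapply(function(a, b) identical(a, b) || (is.na(a) && is.na(b)),
                     fams$assignment$family_id,
                     truth$family_id[match(fams$assignment$protein_id,
                                           truth$protein_id)])
  agree["family"] <- mean(same_fam)
  sec_ids <- sim$truth$secretome
  arch <- classify_architecture(
    sim$proteins[sim$proteins$protein_id %in% sec_ids, , drop = FALSE])
  truth_arch <- truth$architecture[match(arch$protein_id, truth$protein_id)]
  agree["architecture"] <- if (nrow(arch)) {
    mean(as.character(arch$architecture) == truth_arch)
  } else 1
  cand <- single_pass_candidates(topo, sim$truth$excluded_function_ids,
                                 sim$truth$organelle_assigned)
  agree["receptor_candidates"] <- as.numeric(
    setequal(cand, truth$protein_id[truth$receptor_candidate]))

  expression <- NULL
  if (!is.null(sim$expression)) {
    tr <- sim$truth$expression
    st <- stage_enrichment(sim$expression)
    me <- male_enrichment(sim$expression)
    stage_hit <- st$gene_id[st$upregulated]
    stage_cond <- st$condition[st$upregulated]
    planted_idx <- which(!is.na(tr$planted_stage))
    sens_stage <- if (length(planted_idx)) {
      mean(vapply(planted_idx, function(g) {
        any(stage_hit == truth$gene_id[g] &
              stage_cond == tr$planted_stage[g])
      }, logical(1)))
    } else NA_real_
    male_hit <- me$gene_id[me$upregulated]
    sens_male <- if (any(tr$planted_male)) {
      mean(truth$gene_id[tr$planted_male] %in% male_hit)
    } else NA_real_
    null_genes <- truth$gene_id[is.na(tr$planted_stage) & !tr$planted_male]
    fp <- mean(null_genes %in% c(stage_hit, male_hit))
    planted_n <- length(planted_idx) + sum(tr$planted_male)
    sens <- (sum(vapply(planted_idx, function(g) {
      any(stage_hit == truth$gene_id[g] & stage_cond == tr$planted_stage[g])
    }, logical(1))) + sum(truth$gene_id[tr$planted_male] %in% male_hit)) /
      max(planted_n, 1L)
    inf <- infection_upregulated(sim$expression, sim$infection_flags)
    truth_union <- names(tr$infection_conditions)[
      vapply(tr$infection_conditions, length, 0L) > 0]
    expression <- list(sensitivity = sens, sensitivity_stage = sens_stage,
                       sensitivity_male = sens_male,
                       false_positive_rate = fp,
                       infection_exact = setequal(inf$union, truth_union))
  }
  list(agreement = agree, expression = expression, data = sim)
}
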