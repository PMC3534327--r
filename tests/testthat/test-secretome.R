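# Localization transfer, secretome construction, architecture, families.

test_that("localization transfer unions compartments across sources", {
  empty <- data.frame(source_protein = character(0),
                      source_organism = character(0),
                      compartment = character(0))
  empty$ortholog_gene_ids <- list()
  expect_identical(transfer_localization(empty), list())

  ev <- data.frame(source_protein = c("Y1", "M1"),
                   source_organism = c("yeast", "mouse"),
                   compartment = c("ER", "mitochondrion"),
                   stringsAsFactors = FALSE)
  ev$ortholog_gene_ids <- list(c("w1", "w2"), "w1")
  map <- transfer_localization(ev)
  expect_setequal(map[["w1"]], c("ER", "mitochondrion"))
  expect_identical(map[["w2"]], "ER")
  expect_null(map[["w3"]])

  ev2 <- ev
  ev2$compartment <- c("Golgi", "mitochondrion")
  ev2$ortholog_gene_ids <- list("w1", "w1")
  expect_setequal(transfer_localization(ev2)[["w1"]],
                  c("Golgi", "mitochondrion"))
})

test_that("secretome arithmetic matches the published marginals", {
  # count-level fixture: 3,757 SP-only, 207 endomembrane, 66 mitochondrial
  ids <- sprintf("sp%04d", 1:3757)
  p <- protein_table(ids, length = rep(200L, 3757),
                     sp_start = rep(1L, 3757), sp_end = rep(20L, 3757))
  topo <- reconcile_topology(p)
  map <- c(stats::setNames(rep(list("Golgi"), 207), ids[1:207]),
           stats::setNames(rep(list("mitochondrion"), 66), ids[208:273]))
  secr <- build_secretome(topo, map)
  expect_identical(length(secr$secretome), 3484L)
  expect_identical(length(secr$removed_endomembrane), 207L)
  expect_identical(length(secr$removed_mitochondrial), 66L)
})

test_that("secretome partition is conserved and disjoint on random inputs", {
  for (s in c(1, 2, 3)) {
    sim <- generate_proteome(simulation_config(n_proteins = 300, seed = s))
    topo <- reconcile_topology(sim$proteins)
    secr <- build_secretome(topo, transfer_localization(sim$localization),
                            extracellular_whitelist = sim$truth$whitelist)
    expect_identical(length(secr$secretome) +
                       length(secr$removed_endomembrane) +
                       length(secr$removed_mitochondrial),
                     length(secr$sp_only_input))
    expect_length(intersect(secr$secretome, secr$removed_endomembrane), 0)
    expect_length(intersect(secr$secretome, secr$removed_mitochondrial), 0)
    expect_length(intersect(secr$removed_endomembrane,
                            secr$removed_mitochondrial), 0)
  }
})

test_that("empty localization map keeps the whole SP-only set", {
  sim <- generate_proteome(simulation_config(n_proteins = 200, seed = 9))
  topo <- reconcile_topology(sim$proteins)
  secr <- build_secretome(topo, list())
  expect_setequal(secr$secretome, secr$sp_only_input)
})

test_that("whitelisting only ever moves proteins into the secretome", {
  sim <- generate_proteome(simulation_config(n_proteins = 400, seed = 13))
  topo <- reconcile_topology(sim$proteins)
  map <- transfer_localization(sim$localization)
  base <- build_secretome(topo, map)
  endo <- base$removed_endomembrane
  if (length(endo)) {
    wl <- build_secretome(topo, map, extracellular_whitelist = endo[1])
    expect_true(endo[1] %in% wl$secretome)
    expect_true(all(base$secretome %in% wl$secretome))
    # mitochondrial removal admits no override
    mito <- base$removed_mitochondrial
    if (length(mito)) {
      wl2 <- suppressWarnings(
        build_secretome(topo, map, extracellular_whitelist = mito[1]))
      expect_true(mito[1] %in% wl2$removed_mitochondrial)
    }
  }
  expect_warning(build_secretome(topo, map,
                                 extracellular_whitelist = "not-a-protein"),
                 "not in the SP-only set")
})

test_that("architecture classes follow the distinct/copies rules", {
  cases <- list(
    list(dom = c("EGF", "MD", "VA", "CL"), cls = "complex"),
    list(dom = rep("SHK", 12), cls = "repetitive"),
    list(dom = "CL", cls = "simple"),
    list(dom = c(rep("KU", 3), rep("DC", 2)), cls = "repetitive"),  # boundary
    list(dom = c("A", "B", "C", "A", "B", "C"), cls = "simple"),
    list(dom = NULL, cls = "simple"))
  for (cs in cases) {
    p <- make_protein(domains = cs$dom)
    arch <- classify_architecture(p, repeat_min = 5)
    expect_identical(as.character(arch$architecture), cs$cls)
  }
  s <- architecture_summary(
    bind_proteins(make_protein("a", domains = rep("KU", 11)),
                  make_protein("b", domains = rep("KU", 21)),
                  make_protein("c", domains = "KU")))
  expect_identical(unname(s["over_10_domains"]), 2L)
  expect_identical(unname(s["over_20_domains"]), 1L)
})

test_that("family grouping: threshold, priority, order invariance", {
  mk <- function(n, prefix) {
    do.call(bind_proteins, lapply(seq_len(n), function(i) {
      make_protein(paste0(prefix, "p", i), gene = paste0(prefix, i))
    }))
  }
  defs <- list(family_definition("fam10", gene_prefixes = "clec-",
                                 priority = 1),
               family_definition("fam9", gene_prefixes = "ins-",
                                 priority = 2))
  p <- bind_proteins(mk(10, "clec-"), mk(9, "ins-"),
                     make_protein("lonely", gene = "xyz-1"))
  g <- group_families(p, defs)
  expect_identical(g$summary$large, c(TRUE, FALSE))
  expect_identical(g$summary$n, c(10L, 9L))
  expect_true(is.na(g$assignment$family_id[g$assignment$protein_id ==
                                             "lonely"]))

  # first matching definition in priority order wins
  both <- list(family_definition("first", gene_prefixes = "clec-",
                                 priority = 1),
               family_definition("second", gene_prefixes = "clec-",
                                 priority = 2))
  g2 <- group_families(mk(3, "clec-"), both)
  expect_identical(g2$summary$n, c(3L, 0L))

  expect_error(group_families(p, list(
    family_definition("a", gene_prefixes = "clec-", priority = 1),
    family_definition("b", gene_prefixes = "ins-", priority = 1))),
    "equal priority")

  # invariance under input row order
  perm <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  class(perm) <- c("protein_table", "data.frame")
  g3 <- group_families(perm, defs)
  expect_setequal(g3$membership$fam10, g$membership$fam10)
  expect_setequal(g3$membership$fam9, g$membership$fam9)
})

test_that("members without a signal peptide join a matching family", {
  p <- bind_proteins(make_protein("a", sp = c(1, 18), gene = "ins-1"),
                     make_protein("b", gene = "ins-2"))  # no SP
  g <- group_families(p, list(family_definition("insulins",
                                                gene_prefixes = "ins-",
                                                priority = 1)))
  expect_setequal(g$membership$insulins, c("a", "b"))
})
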