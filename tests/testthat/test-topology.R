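# Topology reconciliation and the Fig-1-style distributions.

test_that("SP/TM reconciliation follows the N-terminal overlap rule", {
  cases <- list(
    # SP and overlapping N-terminal TM: signal peptide wins, segment dropped
    list(p = make_protein(sp = c(1, 20), tm = list(c(5, 25))),
         class = "SP_only", eff = 0L, dropped = 1L),
    list(p = make_protein(tm = list(c(30, 52), c(70, 92))),
         class = "TM_only", eff = 2L, dropped = 0L),
    # non-overlapping TM survives alongside the SP
    list(p = make_protein(sp = c(1, 18), tm = list(c(120, 140))),
         class = "SP_and_TM", eff = 1L, dropped = 0L),
    # overlap but start beyond the window: not dropped
    list(p = make_protein(len = 400, sp = c(1, 60), tm = list(c(45, 65))),
         class = "SP_and_TM", eff = 1L, dropped = 0L),
    # one overlapping + one distal segment: only the overlapping one drops
    list(p = make_protein(sp = c(1, 20), tm = list(c(5, 25), c(200, 220))),
         class = "SP_and_TM", eff = 1L, dropped = 1L),
    list(p = make_protein(), class = "neither", eff = 0L, dropped = 0L))
  for (cs in cases) {
    topo <- reconcile_topology(cs$p, n_terminal_window = 40)
    expect_identical(as.character(topo$topology_class), cs$class)
    expect_identical(topo$effective_tm_count, cs$eff)
    expect_identical(nrow(topo$dropped_tm_segments[[1]]), cs$dropped)
  }
})

test_that("topology classes partition any cohort and the rule is idempotent", {
  sim <- generate_proteome(simulation_config(n_proteins = 400, seed = 11))
  topo <- reconcile_topology(sim$proteins)
  expect_identical(sum(table(topo$topology_class)), nrow(sim$proteins))

  # idempotence: strip the dropped segments and re-reconcile
  pruned <- sim$proteins
  for (i in seq_len(nrow(pruned))) {
    d <- topo$dropped_tm_segments[[i]]
    if (nrow(d) > 0) {
      tm <- pruned$tm_segments[[i]]
      keep <- !(paste(tm[, 1], tm[, 2]) %in% paste(d[, 1], d[, 2]))
      pruned$tm_segments[[i]] <- tm[keep, , drop = FALSE]
    }
  }
  topo2 <- reconcile_topology(pruned)
  expect_identical(as.character(topo2$topology_class),
                   as.character(topo$topology_class))
  expect_identical(topo2$effective_tm_count, topo$effective_tm_count)
  expect_true(all(vapply(topo2$dropped_tm_segments, nrow, 0L) == 0L))

  # removing the SP can never increase the number of dropped segments
  no_sp <- sim$proteins
  no_sp$sp_start <- NA_integer_
  no_sp$sp_end <- NA_integer_
  topo3 <- reconcile_topology(no_sp)
  expect_true(all(vapply(topo3$dropped_tm_segments, nrow, 0L) <=
                    vapply(topo$dropped_tm_segments, nrow, 0L)))
})

test_that("TM-count histogram counts exactly the planted distribution", {
  spec <- histogram_spec(1:15)
  empty <- reconcile_topology(protein_table(character(0), integer(0)))
  expect_true(all(tm_count_histogram(empty, spec) == 0))

  five <- bind_proteins(
    make_protein("a", tm = list(c(30, 50))),
    make_protein("b", tm = list(c(30, 50))),
    make_protein("c", tm = list(c(30, 50))),
    make_protein("d", tm = list(c(30, 50))),
    make_protein("e", tm = list(c(30, 50))))
  h <- tm_count_histogram(reconcile_topology(five), spec)
  expect_identical(unname(h[1]), 5L)
  expect_identical(sum(h), 5L)

  sim <- generate_proteome(simulation_config(n_proteins = 2000, seed = 42))
  topo <- reconcile_topology(sim$proteins)
  h <- tm_count_histogram(topo, histogram_spec(1:20))
  planted <- sim$truth$per_protein$effective_tm_count
  planted <- planted[planted >= 1]
  expect_identical(sum(h), length(planted))
  for (k in 1:19) {
    expect_identical(unname(h[k]), sum(planted == k))
  }
})

test_that("size distribution bins, normalizes, and rejects unknown subsets", {
  p <- make_protein(len = 150L, sp = c(1, 20))
  topo <- reconcile_topology(p)
  h <- size_distribution(p, topo, "all",
                         histogram_spec(c(100, 200, 300), normalized = TRUE))
  expect_identical(unname(h["[100,200)"]), 1)
  expect_identical(sum(h), 1)

  empty <- protein_table(character(0), integer(0))
  h0 <- size_distribution(empty, reconcile_topology(empty), "TM",
                          histogram_spec(c(100, 200), normalized = TRUE))
  expect_false(anyNA(h0))
  expect_equal(sum(h0), 0)

  expect_error(size_distribution(p, topo, "membrane"), "unknown subset")
})

test_that("planted bimodal size mixture is recovered within 3 SE per bin", {
  cfg <- simulation_config(n_proteins = 2000, seed = 7)
  sim <- generate_proteome(cfg)
  topo <- reconcile_topology(sim$proteins)
  spec <- histogram_spec(seq(1, 1001, by = 100), normalized = TRUE)
  obs <- size_distribution(sim$proteins, topo, "secreted", spec,
                           secretome = sim$truth$secretome)
  # independent binomial oracle: replay the stated length law at large N
  sz <- cfg$size_distribution
  set.seed(990)
  N <- 2e5
  small <- stats::runif(N) < sz$w_small_secreted
  lens <- pmax(round(ifelse(small,
                            stats::rlnorm(N, sz$meanlog_small, sz$sdlog_small),
                            stats::rlnorm(N, sz$meanlog_large,
                                          sz$sdlog_large))), 60)
  p_ref <- secretomeSurvey:::bin_values(lens, spec)  # already fractions
  n_sec <- length(sim$truth$secretome)
  for (b in seq_along(obs)) {
    se <- sqrt(p_ref[b] * (1 - p_ref[b]) / n_sec)
    expect_lt(abs(obs[b] - p_ref[b]), 3 * se + 1e-9)
  }
  # the planted small-secreted overrepresentation is visible
  obs_tm <- size_distribution(sim$proteins, topo, "TM_non_sr", spec,
                              chemoreceptor_ids = sim$truth$chemoreceptor_ids)
  expect_gt(sum(obs[1:2]), sum(obs_tm[1:2]))
})

test_that("single-pass receptor candidates respect the exclusion lists", {
  p <- bind_proteins(make_protein("sp1", tm = list(c(30, 50))),
                     make_protein("sp2", tm = list(c(30, 50))),
                     make_protein("multi", tm = list(c(30, 50), c(70, 90))))
  topo <- reconcile_topology(p)
  expect_setequal(single_pass_candidates(topo), c("sp1", "sp2"))
  expect_setequal(single_pass_candidates(topo, organelle_assigned = "sp2"),
                  "sp1")
  expect_setequal(single_pass_candidates(topo, excluded_function_ids = "sp1",
                                         organelle_assigned = "sp2"),
                  character(0))

  sim <- generate_proteome(simulation_config(n_proteins = 600, seed = 5))
  cand <- single_pass_candidates(reconcile_topology(sim$proteins),
                                 sim$truth$excluded_function_ids,
                                 sim$truth$organelle_assigned)
  truth <- sim$truth$per_protein
  expect_setequal(cand, truth$protein_id[truth$receptor_candidate])
})
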