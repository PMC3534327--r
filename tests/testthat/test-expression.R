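# Stage/sex/infection enrichment calls.

test_that("stage enrichment: fold formula, thresholds, zero denominator", {
  r <- stage_enrichment(c(10, 1, 1, 1, 1), stage_index = 1)
  expect_equal(r$fold, 10)
  expect_true(r$upregulated)

  r <- stage_enrichment(c(3, 3, 3, 3), stage_index = 2)
  expect_equal(r$fold, 1)
  expect_false(r$upregulated)

  # below tau: never upregulated regardless of fold
  r <- stage_enrichment(c(0.03, 0.001, 0.001), stage_index = 1)
  expect_gt(r$fold, 5)
  expect_false(r$expressed)
  expect_false(r$upregulated)

  # expressed in exactly one stage: maximally enriched
  r <- stage_enrichment(c(0.2, 0, 0), stage_index = 1)
  expect_identical(r$fold, Inf)
  expect_true(r$upregulated)
  r <- stage_enrichment(c(0, 0, 0), stage_index = 1)
  expect_false(r$upregulated)

  expect_error(stage_enrichment(c(1), stage_index = 1), "at least two")
})

test_that("matrix form matches the per-gene form, excludes male columns", {
  em <- tiny_expression(c(10, 1, 1, 1, 50,
                          2, 2, 2, 2, 2),
                        conds = c("embryo", "L2", "L3", "herm_L4", "male_L4"),
                        tags = c("stage", "stage", "stage", "herm_L4",
                                 "male_L4"))
  st <- stage_enrichment(em)
  # male_L4 never enters stage folds
  expect_false("male_L4" %in% st$condition)
  g1_embryo <- st[st$gene_id == "g1" & st$condition == "embryo", ]
  expect_equal(g1_embryo$fold, 10 / 1)
  expect_true(g1_embryo$upregulated)
  one <- stage_enrichment(c(10, 1, 1, 1), stage_index = 1)
  expect_equal(one$fold, g1_embryo$fold)

  me <- male_enrichment(em)
  expect_equal(me$fold, c(50 / 1, 1))
  expect_identical(me$upregulated, c(TRUE, FALSE))
})

test_that("male enrichment vector form covers the threshold cases", {
  r <- male_enrichment(c(1.0, 0.2, 0.03), herm_L4 = c(0.1, 0, 0.001))
  expect_equal(r$fold[1], 10)
  expect_true(r$upregulated[1])
  expect_identical(r$fold[2], Inf)
  expect_true(r$upregulated[2])
  expect_false(r$expressed[3])
  expect_false(r$upregulated[3])
})

test_that("fold values are exactly scale invariant", {
  set.seed(100)
  n <- 50
  conds <- c("embryo", "L1", "L2", "L3", "herm_L4", "male_L4")
  # dyadic-grid dcpm values so that c*x is itself exactly representable
  vals <- matrix(sample(1:8192, n * length(conds), replace = TRUE) / 256,
                 nrow = n, dimnames = list(paste0("g", 1:n), conds))
  tags <- stats::setNames(c(rep("stage", 4), "herm_L4", "male_L4"), conds)
  base <- stage_enrichment(expression_matrix(vals, tags))
  base_m <- male_enrichment(expression_matrix(vals, tags))
  for (c_scale in c(0.5, 2, 10)) {
    sc <- stage_enrichment(expression_matrix(vals * c_scale, tags))
    expect_identical(sc$fold, base$fold)
    sc_m <- male_enrichment(expression_matrix(vals * c_scale, tags))
    expect_identical(sc_m$fold, base_m$fold)
  }
})

test_that("infection upregulation: flags AND threshold; set-algebra oracle", {
  conds <- c("embryo", "L1", "bact1", "bact2", "bact3", "fung1", "fung2")
  tags <- stats::setNames(c("stage", "stage",
                            paste0("infection:", conds[3:7])), conds)
  vals <- matrix(1, nrow = 3, ncol = 7,
                 dimnames = list(c("g1", "g2", "g3"), conds))
  vals["g2", "bact1"] <- 0.02   # flagged but below tau
  em <- expression_matrix(vals, tags)
  flags <- data.frame(gene_id = c("g1", "g1", "g2"),
                      condition = c("bact1", "fung2", "bact1"),
                      stringsAsFactors = FALSE)
  up <- infection_upregulated(em, flags)
  expect_setequal(up$per_gene[["g1"]], c("bact1", "fung2"))
  expect_null(up$per_gene[["g2"]])
  expect_identical(up$union, "g1")
  expect_error(infection_upregulated(em, data.frame(gene_id = "g1",
                                                    condition = "embryo")),
               "not in matrix")

  # exhaustive brute-force oracle on a small cohort
  set.seed(41)
  n <- 50
  genes <- sprintf("g%02d", 1:n)
  vals <- matrix(stats::runif(n * 7), nrow = n,
                 dimnames = list(genes, conds))
  em <- expression_matrix(vals, tags, tau = 0.4)
  flag_m <- matrix(stats::runif(n * 5) < 0.4, nrow = n)
  idx <- which(flag_m, arr.ind = TRUE)
  flags <- data.frame(gene_id = genes[idx[, 1]],
                      condition = conds[3:7][idx[, 2]],
                      stringsAsFactors = FALSE)
  up <- infection_upregulated(em, flags)
  oracle_sets <- lapply(3:7, function(j) {
    genes[flag_m[, j - 2] & vals[, j] > 0.4]
  })
  oracle_union <- Reduce(union, oracle_sets)
  expect_setequal(up$union, oracle_union)
  for (k in 1:5) {
    in_cond <- names(Filter(function(x) conds[k + 2] %in% x, up$per_gene))
    expect_setequal(in_cond, oracle_sets[[k]])
  }
})

test_that("class overlap fractions partition the upregulated sets", {
  cls <- data.frame(gene_id = sprintf("g%03d", 1:500),
                    class = rep(c("secreted", "TM", "other"),
                                length.out = 500),
                    stringsAsFactors = FALSE)
  up_sec <- cls$gene_id[cls$class == "secreted"][1:20]
  ov <- class_overlap_summary(list(embryo = up_sec), cls)
  expect_equal(ov$frac_of_upregulated[ov$class == "secreted"], 1)
  expect_equal(sum(ov$frac_of_upregulated), 1)

  ov0 <- class_overlap_summary(list(embryo = character(0)), cls)
  expect_true(all(is.na(ov0$frac_of_upregulated)))

  # 200 upregulated genes of which 74 secreted -> fraction 0.37
  up <- c(cls$gene_id[cls$class == "secreted"][1:74],
          cls$gene_id[cls$class != "secreted"][1:126])
  ov2 <- class_overlap_summary(list(infection = up), cls)
  expect_equal(ov2$frac_of_upregulated[ov2$class == "secreted"], 0.37)

  expect_warning(
    class_overlap_summary(list(x = c("unknown-gene", up_sec[1])), cls),
    "absent from the classification")
})

test_that("planted 8-fold enrichment is recovered under log-normal noise", {
  cfg <- simulation_config(n_proteins = 2000, seed = 21)
  res <- run_end_to_end_recovery(cfg)
  expect_gte(res$expression$sensitivity, 0.95)
  expect_lte(res$expression$false_positive_rate, 0.01)
  expect_true(res$expression$infection_exact)
})
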