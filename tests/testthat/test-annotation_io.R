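# Readers, writers, validation, round-trips.

test_that("header-only protein file yields an empty table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(secretomeSurvey:::PROTEIN_COLUMNS, collapse = "\t"), f)
  tab <- read_protein_table(f)
  expect_s3_class(tab, "protein_table")
  expect_identical(nrow(tab), 0L)
})

test_that("protein table round-trips field-by-field", {
  sim <- generate_proteome(simulation_config(n_proteins = 40, seed = 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(sim$proteins, f)
  back <- read_protein_table(f)
  expect_identical(back$protein_id, sim$proteins$protein_id)
  expect_identical(back$gene_name, sim$proteins$gene_name)
  expect_identical(back$length, sim$proteins$length)
  expect_identical(back$sp_start, sim$proteins$sp_start)
  expect_identical(back$sp_end, sim$proteins$sp_end)
  for (i in seq_len(nrow(back))) {
    expect_equal(unname(back$tm_segments[[i]]),
                 unname(sim$proteins$tm_segments[[i]]))
    expect_identical(back$domain_hits[[i]]$accession,
                     sim$proteins$domain_hits[[i]]$accession)
    expect_identical(back$go_terms[[i]], sim$proteins$go_terms[[i]])
  }
  expect_identical(back$description, sim$proteins$description)
  # reader never silently drops rows
  expect_identical(nrow(back), length(readLines(f)) - 1L)
})

test_that("invalid rows are hard errors naming the offender", {
  hdr <- paste(secretomeSurvey:::PROTEIN_COLUMNS, collapse = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "P1\t\t200\t\t\t140-120\t\t\t"), f)
  expect_error(read_protein_table(f), "P1")
  writeLines(c(hdr,
               "P1\t\t200\t\t\t\t\t\t",
               "P1\t\t300\t\t\t\t\t\t"), f)
  expect_error(read_protein_table(f), "duplicate protein_id: P1")
  writeLines(c(hdr, "P2\t\t100\t1\t150\t\t\t\t"), f)   # SP end > length
  expect_error(read_protein_table(f), "P2")
  writeLines(c(hdr, "P3\t\t100\t\t\t10-30;10-30\t\t\t"), f)
  expect_error(read_protein_table(f), "identical TM segments")
})

test_that("expression matrix round-trips and rejects bad input", {
  em <- tiny_expression(c(1, 2, 3, 0.5, 0, 4),
                        conds = c("embryo", "L2", "herm_L4"),
                        tags = c("stage", "stage", "herm_L4"))
  f <- withr::local_tempfile(fileext = ".tsv")
  side <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, f, side)
  back <- read_expression_matrix(f, side)
  expect_identical(dim(back$values), c(2L, 3L))
  expect_equal(back$values, em$values)
  expect_identical(back$tags, em$tags)

  writeLines(c("gene_id\ta\tb", "g1\t-1.0\t2"), f)
  writeLines(c("condition\ttag", "a\tstage", "b\tstage"), side)
  expect_error(read_expression_matrix(f, side), "negative")
  writeLines(c("gene_id\ta\tb", "\t1\t2"), f)
  expect_error(read_expression_matrix(f, side), "row 1")
  writeLines(c("gene_id\ta\tb", "g1\t1\t2"), f)
  writeLines(c("condition\ttag", "a\tstage", "b\tlarval"), side)
  expect_error(read_expression_matrix(f, side), "unknown condition tag")
})

test_that("matrix constructor enforces the herm_L4/male_L4 pairing", {
  expect_error(
    tiny_expression(c(1, 2), conds = c("a", "male_L4"),
                    tags = c("stage", "male_L4")),
    "herm_L4")
  expect_error(expression_matrix(matrix(1, 1, 1,
                                        dimnames = list("g", "c")),
                                 c(c = "stage"), tau = 0),
               "tau")
})

test_that("classification table: empty, round-trip, deterministic", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_classification_table(data.frame(protein_id = character(0)), f)
  expect_identical(length(readLines(f)), 1L)

  res <- data.frame(protein_id = c("b", "a"),
                    topology_class = c("SP_only", "TM_only"),
                    effective_tm_count = c(0L, 3L),
                    origin = c("nematoda", NA),
                    stringsAsFactors = FALSE)
  write_classification_table(res, f)
  back <- read_classification_table(f)
  expect_identical(back$protein_id, c("a", "b"))  # deterministic order
  expect_identical(back$topology_class, c("TM_only", "SP_only"))
  expect_identical(back$effective_tm_count, c(3L, 0L))
  expect_identical(back$origin, c(NA, "nematoda"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_classification_table(res, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("evidence tables round-trip", {
  sim <- generate_proteome(simulation_config(n_proteins = 60, seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_origin_evidence(sim$origin, f)
  back <- read_origin_evidence(f)
  expect_identical(back$gene_id, sim$origin$gene_id)
  expect_identical(back$treefam_species, sim$origin$treefam_species)
  expect_identical(back$inparanoid_classes, sim$origin$inparanoid_classes)
  expect_identical(back$blast_species, sim$origin$blast_species)

  write_localization_evidence(sim$localization, f)
  lback <- read_localization_evidence(f)
  expect_identical(lback$compartment, sim$localization$compartment)
  expect_identical(lback$ortholog_gene_ids,
                   sim$localization$ortholog_gene_ids)
})
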