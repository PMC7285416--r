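test_that("canonical expression TSV parses with validated group counts", {
  study <- read_expression_study(toy_study_file(),
                                 study_metadata("TOY1", 2, 2))
  expect_s3_class(study, "expression_study")
  expect_equal(study$metadata$n_control, 2L)
  expect_equal(study$metadata$n_case, 2L)
  expect_equal(study$genes, c("G1", "G2"))
  expect_equal(unname(study$values["G1", ]), c(0, 2, 3, 5))
  expect_equal(study$scale, "log2")
})

test_that("malformed expression files are rejected with useful errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ts1\ts2\ts3\ts4",
               "group\tcontrol\tcontrol\ttumor\tcase",
               "G1\t0\t2\t3\t5", "G2\t1\t1\t1\t1"), path)
  expect_error(read_expression_study(path, study_metadata("X", 2, 2)),
               "tumor", class = "megax_validation_error")

  writeLines(c("sample_id\ts1\ts2", "group\tcontrol\tcase",
               "G1\t1\t2\t3"), path)
  expect_error(read_expression_study(path, study_metadata("X", 1, 1)),
               class = "megax_format_error")
})

test_that("expression studies round-trip through the canonical dialect", {
  studies <- simulate_collection(
    simulation_truth(c(A = 1, B = -2, C = 0), tau2 = 0.1, seed = 11),
    simulated_study_table(k = 2, n_control = 4, n_case = 3))
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_study(studies[[1]], f1)
  back <- read_expression_study(f1, studies[[1]]$metadata)
  expect_identical(back$values, studies[[1]]$values)
  expect_identical(back$group, studies[[1]]$group)
  # write(read(write(x))) is byte-identical
  write_expression_study(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the packaged study table matches its printed totals", {
  tab <- read_study_table(lscc_fixture("study_table"))
  expect_equal(nrow(tab), 12L)
  expect_equal(sum(tab$n_control), 285L)
  expect_equal(sum(tab$n_case), 375L)
  expect_false(anyDuplicated(tab$study_id) > 0)
})

test_that("study tables validate counts and handle the empty case", {
  path <- tempfile(fileext = ".tsv")
  writeLines("study_id\tn_control\tn_case\tcountry\tstudy_age_years\torganism",
             path)
  expect_equal(nrow(read_study_table(path)), 0L)

  writeLines(c("study_id\tn_control\tn_case",
               "S1\ttwo\t3"), path)
  expect_error(read_study_table(path), class = "megax_format_error")
})

test_that("relation tables parse polarity dialects and enforce uniqueness", {
  rel <- read_relation_table(lscc_fixture("diagnostic_relations"))
  expect_equal(nrow(rel), 24L)
  expect_setequal(unique(rel$polarity), c(1L, -1L))

  pro <- read_relation_table(lscc_fixture("prognostic_relations"))
  stk <- pro[pro$source == "PPARG" & pro$target == "STK11", ]
  expect_equal(nrow(stk), 1L)
  expect_equal(stk$polarity, 1L)

  path <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tpolarity\trelation_kind\tprovenance",
               "A\tB\t+\tregulation\tx",
               "A\tB\t-\tregulation\ty"), path)
  expect_error(read_relation_table(path), class = "megax_validation_error")

  writeLines(c("source\ttarget\tpolarity\trelation_kind\tprovenance",
               "A\tB\tup\tregulation\tx"), path)
  expect_error(read_relation_table(path), class = "megax_format_error")
})

test_that("GMT parsing deduplicates members and rejects bad lines", {
  path <- tempfile(fileext = ".gmt")
  writeLines("S1\tGO:1\tA\tB\tC", path)
  sets <- read_gene_sets(path)
  expect_equal(sets[["S1"]]$members, c("A", "B", "C"))
  expect_equal(sets[["S1"]]$external_id, "GO:1")

  writeLines("S1\tGO:1\tA\tA", path)
  expect_warning(sets <- read_gene_sets(path), "duplicated")
  expect_equal(sets[["S1"]]$members, "A")

  writeLines("S1\tGO:1", path)
  expect_error(read_gene_sets(path), class = "megax_format_error")
  writeLines("S1\tGO:1\t\t", path)
  expect_error(read_gene_sets(path), class = "megax_format_error")
})
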