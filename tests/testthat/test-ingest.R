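test_that("a well-formed biomarker table yields one record per row", {
  bm <- bm_table(drug = c("A", "B", "C"),
                 target = c("G1(M1)", "G1(M2)", "G2"),
                 effect = c("responsive", "resistant", "responsive"),
                 evidence = c("guidelines", "pre_clinical", "late_trials"),
                 tumor_types = c("T1;T2", "T1", ""))
  res <- parse_biomarker_table(bm)
  expect_s3_class(res, "ingest_result")
  expect_identical(nrow(res$records), 3L)
  expect_identical(nrow(res$errors), 0L)
  expect_identical(res$records$tumor_types[[1]], c("T1", "T2"))
  expect_identical(res$records$tumor_types[[3]], character(0))
  expect_true(res$records$is_wild_type[3])
})

test_that("effect and evidence labels match case-insensitively with aliases", {
  bm <- bm_table(drug = c("A", "B", "C"),
                 target = "G1(M1)",
                 effect = c("Responsive", "RESISTANT", "responsive"),
                 evidence = c("FDA guidelines", "Pre-Clinical", "late trials"))
  res <- parse_biomarker_table(bm)
  expect_identical(res$records$effect, c("responsive", "resistant", "responsive"))
  expect_identical(res$records$evidence_level,
                   c("guidelines", "pre_clinical", "late_trials"))
})

test_that("unknown labels become row-level errors naming the allowed values", {
  bm <- bm_table(drug = c("A", "B"), target = "G1(M1)",
                 effect = c("responsive", "responsive"),
                 evidence = c("phase4", "guidelines"))
  res <- parse_biomarker_table(bm)
  expect_identical(nrow(res$records), 1L)
  expect_identical(res$errors$row, 1L)
  expect_match(res$errors$message, "pre_clinical.*guidelines")

  bm2 <- bm_table(drug = "A", target = "G1(M1)", effect = "sensitive",
                  evidence = "guidelines")
  res2 <- parse_biomarker_table(bm2)
  expect_match(res2$errors$message, "responsive, resistant")
})

test_that("a missing required column is a hard error naming the column", {
  bm <- bm_table(drug = "A", target = "G1(M1)", effect = "responsive",
                 evidence = "guidelines")
  bm$effect <- NULL
  expect_error(parse_biomarker_table(bm), "effect")
})

test_that("bioactivity values convert units to nM", {
  ba <- ba_table(drug = c("A", "A", "A", "A"), target = "G1(M1)",
                 value = c("25", "0.5", "1,500", "0.001"),
                 unit = c("nM", "uM", "nM", "mM"))
  res <- parse_bioactivity_table(ba)
  expect_identical(nrow(res$errors), 0L)
  expect_equal(res$records$value_nM, c(25, 500, 1500, 1000))
})

test_that("missing unit column means values are already nM", {
  ba <- ba_table(drug = "A", target = "G1(M1)", value = "42")
  ba$unit <- NULL
  res <- parse_bioactivity_table(ba)
  expect_equal(res$records$value_nM, 42)
})

test_that("bad values and units are row-level errors; rows are conserved", {
  ba <- ba_table(drug = c("A", "B", "C", "D"), target = "G1(M1)",
                 value = c("-3", "abc", "10", "10"),
                 unit = c("nM", "nM", "furlongs", "nM"))
  res <- parse_bioactivity_table(ba)
  expect_identical(nrow(res$records), 1L)
  expect_identical(res$errors$row, c(1L, 2L, 3L))
  expect_match(res$errors$message[1], "positive")
  expect_match(res$errors$message[2], "non-numeric")
  expect_match(res$errors$message[3], "unsupported unit")
  expect_identical(nrow(res$records) + nrow(res$errors), res$n_input)
})

test_that("row conservation holds on generated fixtures", {
  fix <- generate_fixture(fixture_spec(seed = 11))
  bm <- parse_biomarker_table(fix$biomarkers)
  ba <- parse_bioactivity_table(fix$bioactivities)
  expect_identical(nrow(bm$records) + nrow(bm$errors), nrow(fix$biomarkers))
  expect_identical(nrow(ba$records) + nrow(ba$errors), nrow(fix$bioactivities))
  expect_identical(nrow(bm$errors), 0L)
  expect_identical(nrow(ba$errors), 0L)
})

test_that("reading from disk round-trips through the TSV dialect", {
  fix <- generate_fixture(fixture_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_fixture(fix, dir)
  bm <- read_biomarkers(file.path(dir, "biomarkers.tsv"))
  ba <- read_bioactivities(file.path(dir, "bioactivities.tsv"))
  expect_identical(nrow(bm$records), nrow(fix$biomarkers))
  expect_identical(nrow(ba$records), nrow(fix$bioactivities))
  # same store whether built from memory or from disk
  s1 <- fixture_store(fix)
  s2 <- build_store(bm, ba)
  expect_equal(merge_statistics(s1), merge_statistics(s2))
})

test_that("case-folded effect labels round-trip through write and read", {
  bm <- bm_table(drug = "A", target = "G1(M1)", effect = "Responsive",
                 evidence = "guidelines", tumor_types = "T1")
  res <- parse_biomarker_table(bm)
  expect_identical(res$records$effect, "responsive")
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- res$records
  tab <- data.frame(drug = out$drug_name, target = out$target_id,
                    effect = out$effect, evidence_level = out$evidence_level,
                    tumor_types = vapply(out$tumor_types, paste,
                                         character(1), collapse = ";"),
                    source_title = "t", source_doi = "d",
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  again <- read_biomarkers(path)
  expect_identical(again$records$effect, "responsive")
})
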