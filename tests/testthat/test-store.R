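test_that("median aggregation resists outliers and pools measurement types", {
  recs <- data.frame(value_nM = c(1, 10, 100000),
                     measurement_type = c("Kd", "Ki", "IC50"),
                     stringsAsFactors = FALSE)
  recs$sources <- replicate(3, NULL, simplify = FALSE)
  s <- aggregate_activities(recs)
  expect_equal(s$median_value_nM, 10)
  expect_identical(s$potency, "highly_potent")
  expect_identical(s$n_measurements, 3L)

  even <- recs[1:2, ]; even$value_nM <- c(40, 60)
  s2 <- aggregate_activities(even)
  expect_equal(s2$median_value_nM, 50)
  expect_identical(s2$potency, "potent")

  one <- recs[1, , drop = FALSE]; one$value_nM <- 7
  expect_equal(aggregate_activities(one)$median_value_nM, 7)
  expect_error(aggregate_activities(recs[0, ]), "at least one")
})

test_that("aggregation equals the sort-and-pick oracle and is permutation invariant", {
  set.seed(9)
  for (n in 1:8) {
    v <- round(10^stats::runif(n, 0, 5), 2)
    recs <- data.frame(value_nM = v, measurement_type = "Kd",
                       stringsAsFactors = FALSE)
    recs$sources <- replicate(n, NULL, simplify = FALSE)
    perm <- recs[sample.int(n), , drop = FALSE]
    expect_equal(aggregate_activities(recs)$median_value_nM, oracle_median(v))
    expect_equal(aggregate_activities(perm)$median_value_nM, oracle_median(v))
  }
})

test_that("build_store links both sources and conserves every record", {
  bm <- bm_table(drug = "D", target = "G1(M1)", effect = "responsive",
                 evidence = "guidelines", tumor_types = "T1")
  ba <- ba_table(drug = c("D", "d "), target = "G1(M1)", value = c("20", "80"))
  st <- store_from_tables(bm, ba)
  expect_identical(nrow(st$activity_summaries), 1L)
  expect_equal(st$activity_summaries$median_value_nM, 50)
  expect_identical(st$activity_summaries$n_measurements, 2L)
  # the pair exists in both sources under one canonical drug key
  expect_identical(st$biomarkers$drug_key, st$activity_summaries$drug_key)
  expect_identical(nrow(st$drugs), 1L)
})

test_that("duplicate biomarker rows are both retained in their cell", {
  bm <- bm_table(drug = c("D", "D"), target = "G1(M1)",
                 effect = "responsive", evidence = "guidelines")
  st <- store_from_tables(bm, ba_table(character(0), character(0), character(0)))
  expect_identical(nrow(st$biomarkers), 2L)
})

test_that("store conservation holds on generated fixtures", {
  fix <- generate_fixture(fixture_spec(seed = 5))
  st <- fixture_store(fix)
  expect_identical(nrow(st$biomarkers), nrow(fix$biomarkers))
  expect_identical(sum(st$activity_summaries$n_measurements),
                   nrow(fix$bioactivities))
  # per-pair summaries agree with aggregate_activities on each group
  ba <- st$bioactivities
  for (i in seq_len(nrow(st$activity_summaries))) {
    rowset <- ba[ba$drug_key == st$activity_summaries$drug_key[i] &
                   ba$target_key == st$activity_summaries$target_key[i], ]
    expect_equal(aggregate_activities(rowset)$median_value_nM,
                 st$activity_summaries$median_value_nM[i])
  }
})

test_that("disjoint drugs give disjoint source cells", {
  bm <- bm_table(drug = "A", target = "G1(M1)", effect = "responsive",
                 evidence = "guidelines")
  ba <- ba_table(drug = "B", target = "G1(M1)", value = "10")
  st <- store_from_tables(bm, ba)
  expect_length(intersect(st$biomarkers$drug_key,
                          st$activity_summaries$drug_key), 0)
})

test_that("merge statistics match a brute-force set oracle", {
  for (seed in c(2, 13)) {
    fix <- generate_fixture(small_spec(seed))
    st <- fixture_store(fix)
    got <- as.data.frame(merge_statistics(st))
    want <- oracle_merge_stats(fix$biomarkers, fix$bioactivities)
    expect_equal(got, want, ignore_attr = TRUE)
    # inclusion-exclusion invariant
    expect_identical(got$count_union, got$count_cgi + got$count_dtc - got$count_both)
  }
})

test_that("an empty store has all-zero merge statistics", {
  st <- store_from_tables(bm_table(character(0), character(0), character(0),
                                   character(0)),
                          ba_table(character(0), character(0), character(0)))
  ms <- merge_statistics(st)
  expect_true(all(ms$count_union == 0))
})

test_that("a store round-trips through JSON exactly", {
  fix <- generate_fixture(fixture_spec(seed = 21))
  st <- fixture_store(fix)
  path <- withr::local_tempfile(fileext = ".json")
  write_store(st, path)
  back <- read_store(path)
  norm <- function(s) {
    lapply(s, function(x) {
      if (is.data.frame(x)) { rownames(x) <- NULL; x } else x
    })
  }
  expect_equal(norm(unclass(back)), norm(unclass(st)))

  # empty store round-trips too
  st0 <- store_from_tables(bm_table(character(0), character(0), character(0),
                                    character(0)),
                           ba_table(character(0), character(0), character(0)))
  write_store(st0, path)
  back0 <- read_store(path)
  expect_identical(nrow(back0$biomarkers), 0L)
  expect_identical(nrow(back0$bioactivities), 0L)
})

test_that("corrupted or mismatched store files are hard errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"foo\": 1}", path)
  expect_error(read_store(path), "schema_version")
  writeLines("{\"schema_version\": \"other/9\"}", path)
  expect_error(read_store(path), "version mismatch")
  writeLines("not json at all {", path)
  expect_error(read_store(path), "cannot parse")
})
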