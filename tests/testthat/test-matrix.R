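test_that("selected mutations become columns and related drugs become rows", {
  bm <- bm_table(drug = c("D1", "D2"), target = "G1(M1)",
                 effect = "responsive", evidence = "guidelines",
                 tumor_types = c("T1", "T2"))
  ba <- ba_table(drug = c("D2", "D3"), target = c("G1(M1)", "G1"),
                 value = c("10", "100"))
  st <- store_from_tables(bm, ba)
  m <- assemble_matrix(st, "G1(M1)")
  # wild-type gene present in the data is auto-appended as a column
  expect_identical(m$columns$key, c("G1(M1)", "G1"))
  expect_identical(m$columns$is_selected, c(TRUE, FALSE))
  # D3 relates only via the wild-type column but is still a row
  expect_setequal(m$drug_rows, c("d1", "d2", "d3"))
  expect_setequal(m$tumor_rows, c("t1", "t2"))
})

test_that("a mutation without wild-type data yields a single column", {
  st <- tiny_store()
  m <- assemble_matrix(st, "GENE1(A1B)")
  expect_identical(m$columns$key, "GENE1(A1B)")
})

test_that("two mutations of one gene append the wild-type column once", {
  bm <- bm_table(drug = c("D1", "D2"), target = c("G1(M1)", "G1(M2)"),
                 effect = "responsive", evidence = "guidelines")
  ba <- ba_table(drug = "D1", target = "G1", value = "10")
  st <- store_from_tables(bm, ba)
  m <- assemble_matrix(st, c("G1(M1)", "G1(M2)"))
  expect_identical(m$columns$key, c("G1(M1)", "G1(M2)", "G1"))
})

test_that("unknown or wild-type selections are rejected with hints", {
  st <- tiny_store()
  expect_error(assemble_matrix(st, "GENE1(A9X)"), "unknown target")
  expect_error(assemble_matrix(st, "GENE1(A1C)"), "nearest matches.*GENE1\\(A1B\\)")
  bm <- bm_table(drug = "D", target = "G1", effect = "responsive",
                 evidence = "guidelines")
  st2 <- store_from_tables(bm, ba_table(character(0), character(0), character(0)))
  expect_error(assemble_matrix(st2, "G1"), "wild-type")
})

test_that("every cell carries a state and states partition the grid", {
  st <- tiny_store()
  m <- assemble_matrix(st, c("GENE1(A1B)", "GENE2(C2D)"))
  expect_identical(nrow(m$cells), length(m$drug_rows) * nrow(m$columns))
  expect_false(any(is.na(m$cells$state)))
  tab <- table(m$cells$state)
  expect_identical(sum(tab), length(m$drug_rows) * nrow(m$columns))
  # tiny store: one consistent, one conflicting, one dtc-only, one cgi-only
  states <- m$cells$state
  expect_identical(sum(states == "consistent"), 1L)
  expect_identical(sum(states == "conflicting"), 1L)
  expect_identical(sum(states == "dtc_only"), 1L)
  expect_identical(sum(states == "cgi_only"), 1L)
  expect_identical(sum(states == "missing"), 2L)
})

test_that("missing cells equal grid size minus non-empty cells", {
  fix <- generate_fixture(small_spec(8))
  st <- fixture_store(fix)
  muts <- st$targets$key[!st$targets$is_wild_type][1:3]
  m <- assemble_matrix(st, muts)
  n_missing <- sum(m$cells$state == "missing")
  n_nonempty <- sum(m$cells$has_cgi | m$cells$has_dtc)
  expect_identical(n_missing,
                   length(m$drug_rows) * nrow(m$columns) - n_nonempty)
})

test_that("sort_by_target puts both-source first, then single-source by potency", {
  bm <- bm_table(drug = c("Both", "CgiOnly"), target = "G1(M1)",
                 effect = "responsive", evidence = "guidelines")
  ba <- ba_table(drug = c("Both", "DtcFast", "DtcSlow", "Elsewhere"),
                 target = c("G1(M1)", "G1(M1)", "G1(M1)", "G1(M2)"),
                 value = c("100", "5", "50", "1"))
  bm <- rbind(bm, bm_table(drug = "Elsewhere", target = "G1(M2)",
                           effect = "responsive", evidence = "guidelines"))
  st <- store_from_tables(bm, ba)
  m <- assemble_matrix(st, c("G1(M1)", "G1(M2)"))
  ord <- sort_by_target(m, "G1(M1)")
  expect_identical(ord[1:4], c("both", "cgionly", "dtcfast", "dtcslow"))
  expect_identical(ord[5], "elsewhere")
  expect_error(sort_by_target(m, "G9(Z9Z)"), "not a column")
})

test_that("sort_by_target leaves unrelated drugs in stable original order", {
  fix <- generate_fixture(small_spec(17))
  st <- fixture_store(fix)
  muts <- st$targets$key[!st$targets$is_wild_type][1:2]
  m <- assemble_matrix(st, muts)
  ord <- sort_by_target(m, muts[1])
  cc <- m$cells[m$cells$target_key == muts[1], ]
  unrelated <- m$drug_rows[!(m$drug_rows %in%
                               cc$drug_key[cc$has_cgi | cc$has_dtc])]
  expect_identical(ord[ord %in% unrelated], unrelated)
})

test_that("sort_by_potency_sum scores by summed pActivity, descending", {
  bm <- bm_table(drug = "A", target = "G1(M1)", effect = "responsive",
                 evidence = "guidelines")
  ba <- ba_table(drug = c("A", "A", "B"),
                 target = c("G1(M1)", "G1(M2)", "G1(M1)"),
                 value = c("10", "100", "10"))
  st <- store_from_tables(bm, ba)
  m <- assemble_matrix(st, c("G1(M1)", "G1(M2)"))
  # A: 8 + 7 = 15; B: 8
  expect_identical(sort_by_potency_sum(m), c("a", "b"))
  # raw-sum fidelity mode sorts by summed nM instead
  expect_identical(sort_by_potency_sum(m, mode = "raw_nM"), c("a", "b"))
})

test_that("drugs with no bioactivity data sort alphabetically at score zero", {
  bm <- bm_table(drug = c("Zeta", "Alpha"), target = "G1(M1)",
                 effect = "responsive", evidence = "guidelines")
  st <- store_from_tables(bm, ba_table(character(0), character(0), character(0)))
  m <- assemble_matrix(st, "G1(M1)")
  expect_identical(sort_by_potency_sum(m), c("alpha", "zeta"))
})

test_that("sort_by_responsive_count counts responsive selected columns", {
  bm <- bm_table(drug = c("A", "A", "B", "C"),
                 target = c("G1(M1)", "G1(M2)", "G1(M1)", "G1(M1)"),
                 effect = c("responsive", "responsive", "responsive", "resistant"),
                 evidence = "guidelines")
  st <- store_from_tables(bm, ba_table(character(0), character(0), character(0)))
  m <- assemble_matrix(st, c("G1(M1)", "G1(M2)"))
  expect_identical(sort_by_responsive_count(m), c("a", "b", "c"))
})

test_that("all three sorts are permutations of the drug rows", {
  fix <- generate_fixture(small_spec(23))
  st <- fixture_store(fix)
  muts <- st$targets$key[!st$targets$is_wild_type][1:3]
  m <- assemble_matrix(st, muts)
  for (ord in list(sort_by_target(m, muts[1]), sort_by_potency_sum(m),
                   sort_by_responsive_count(m))) {
    expect_setequal(ord, m$drug_rows)
    expect_identical(length(ord), length(m$drug_rows))
  }
})

test_that("highlight sets follow drug, cell and tumor focus rules", {
  bm <- bm_table(drug = "D1", target = "G1(M1)", effect = "responsive",
                 evidence = "guidelines", tumor_types = "T1")
  ba <- ba_table(drug = c("D1", "D2"), target = c("G1(M1)", "G1"),
                 value = c("10", "10"))
  st <- store_from_tables(bm, ba)
  m <- assemble_matrix(st, "G1(M1)")

  h <- highlight_sets(m, drug = "D1")
  expect_identical(h$targets, "G1(M1)")
  expect_identical(h$tumors, "t1")

  h2 <- highlight_sets(m, cell = c("D1", "G1(M1)"))
  expect_setequal(h2$targets, c("G1(M1)", "G1"))
  expect_identical(h2$drugs, "d1")

  h3 <- highlight_sets(m, tumor = "T1")
  expect_identical(h3$targets, "G1(M1)")

  expect_error(highlight_sets(m, drug = "nope"), "not in the matrix")
  expect_error(highlight_sets(m), "exactly one")
})

test_that("a tumor type with no linked mutations in view highlights nothing", {
  st <- tiny_store()
  m <- assemble_matrix(st, "GENE1(A1B)")
  # GENE2(C2D) is not selected, so its tumor links are out of view
  expect_false("GENE2(C2D)" %in% m$columns$key)
  h <- highlight_sets(m, tumor = "Lung carcinoma")
  expect_identical(h$targets, "GENE1(A1B)")
})
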