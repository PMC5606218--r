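# Small in-code fixtures and independent brute-force oracles.

bm_table <- function(drug, target, effect, evidence, tumor_types = "",
                     title = NULL, doi = NULL) {
  n <- max(length(drug), length(target), length(effect), length(evidence))
  if (length(drug) == 0) n <- 0
  data.frame(
    drug = rep_len(drug, n), target = rep_len(target, n),
    effect = rep_len(effect, n), evidence_level = rep_len(evidence, n),
    tumor_types = rep_len(tumor_types, n),
    source_title = if (is.null(title)) sprintf("cgi study %d", seq_len(n)) else title,
    source_doi = if (is.null(doi)) sprintf("10.1/cgi.%d", seq_len(n)) else doi,
    stringsAsFactors = FALSE
  )
}

ba_table <- function(drug, target, value, unit = "nM", mtype = "Kd",
                     title = NULL, doi = NULL) {
  n <- max(length(drug), length(target), length(value))
  if (length(drug) == 0) n <- 0
  data.frame(
    drug = rep_len(drug, n), target = rep_len(target, n),
    measurement_type = rep_len(mtype, n),
    value = rep_len(as.character(value), n), unit = rep_len(unit, n),
    source_title = if (is.null(title)) sprintf("dtc assay %d", seq_len(n)) else title,
    source_doi = if (is.null(doi)) sprintf("10.2/dtc.%d", seq_len(n)) else doi,
    stringsAsFactors = FALSE
  )
}

store_from_tables <- function(bm, ba) {
  build_store(parse_biomarker_table(bm), parse_bioactivity_table(ba))
}

# 3 drugs x 2 mutations covering consistent, conflicting, dtc-only inactive,
# cgi-only, and missing cells; no wild-type genes present.
tiny_store <- function() {
  bm <- bm_table(
    drug = c("Drug One", "Drug Two", "Drug Three"),
    target = c("GENE1(A1B)", "GENE1(A1B)", "GENE2(C2D)"),
    effect = c("responsive", "resistant", "responsive"),
    evidence = c("guidelines", "late_trials", "pre_clinical"),
    tumor_types = c("Lung carcinoma", "Lung carcinoma;Melanoma", "")
  )
  bm$drug <- c("Drug One", "Drug Two", "Drug Three")
  ba <- ba_table(
    drug = c("Drug One", "Drug Two", "Drug Three"),
    target = c("GENE1(A1B)", "GENE1(A1B)", "GENE1(A1B)"),
    value = c("5", "500", "20000"),
    mtype = c("Kd", "IC50", "Ki")
  )
  store_from_tables(bm, ba)
}

# sort-and-pick median oracle
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# enumerate all multisets of size n from a value grid
multisets <- function(grid, n) {
  rec <- function(n, start) {
    if (n == 0) return(list(numeric(0)))
    out <- list()
    for (i in start:length(grid)) {
      for (tail in rec(n - 1, i)) out[[length(out) + 1]] <- c(grid[i], tail)
    }
    out
  }
  rec(n, 1)
}

# brute-force merge statistics straight from the raw dialect tables
oracle_merge_stats <- function(bm_tab, ba_tab) {
  cgi_t <- vapply(bm_tab$target, function(t) parse_target(t)$key, character(1))
  dtc_t <- vapply(ba_tab$target, function(t) parse_target(t)$key, character(1))
  cgi_wt <- vapply(bm_tab$target, function(t) parse_target(t)$is_wild_type, logical(1))
  dtc_wt <- vapply(ba_tab$target, function(t) parse_target(t)$is_wild_type, logical(1))
  cgi_d <- tolower(trimws(bm_tab$drug))
  dtc_d <- tolower(trimws(ba_tab$drug))
  tumors <- unlist(strsplit(bm_tab$tumor_types, ";", fixed = TRUE))
  tumors <- tolower(trimws(tumors[nzchar(tumors)]))
  sets <- list(
    mutations = list(unique(cgi_t[!cgi_wt]), unique(dtc_t[!dtc_wt])),
    wild_type_genes = list(unique(cgi_t[cgi_wt]), unique(dtc_t[dtc_wt])),
    drugs = list(unique(cgi_d), unique(dtc_d)),
    drug_target_pairs = list(unique(paste(cgi_d, cgi_t)),
                             unique(paste(dtc_d, dtc_t))),
    tumor_types = list(unique(tumors), character(0))
  )
  do.call(rbind, lapply(names(sets), function(cl) {
    a <- sets[[cl]][[1]]; b <- sets[[cl]][[2]]
    data.frame(class = cl, count_cgi = length(a), count_dtc = length(b),
               count_both = length(intersect(a, b)),
               count_union = length(union(a, b)), stringsAsFactors = FALSE)
  }))
}

# brute-force comparators for the three sorting procedures, computed from
# the raw store record tables rather than the matrix cells
oracle_sort_by_target <- function(store, m, tkey) {
  bm <- store$biomarkers; ba <- store$bioactivities
  info <- lapply(m$drug_rows, function(d) {
    in_cgi <- any(bm$drug_key == d & bm$target_key == tkey)
    rows <- ba$drug_key == d & ba$target_key == tkey
    in_dtc <- any(rows)
    med <- if (in_dtc) oracle_median(ba$value_nM[rows]) else NA_real_
    grp <- if (in_cgi && in_dtc) 1 else if (in_cgi) 2 else if (in_dtc) 3 else 4
    list(drug = d, grp = grp, med = med)
  })
  df <- data.frame(drug = vapply(info, `[[`, character(1), "drug"),
                   grp = vapply(info, `[[`, numeric(1), "grp"),
                   med = vapply(info, `[[`, numeric(1), "med"),
                   pos = seq_along(info), stringsAsFactors = FALSE)
  df$med[!df$grp %in% c(1, 3)] <- 0
  df$pos[df$grp != 4] <- 0L
  df$drug[order(df$grp, df$med, df$pos, df$drug)]
}

oracle_sort_by_potency_sum <- function(store, m) {
  ba <- store$bioactivities
  score <- vapply(m$drug_rows, function(d) {
    sum(vapply(m$selected, function(t) {
      rows <- ba$drug_key == d & ba$target_key == t
      if (!any(rows)) 0 else 9 - log10(oracle_median(ba$value_nM[rows]))
    }, numeric(1)))
  }, numeric(1))
  m$drug_rows[order(-score, m$drug_rows)]
}

oracle_sort_by_responsive_count <- function(store, m) {
  bm <- store$biomarkers
  cnt <- vapply(m$drug_rows, function(d) {
    sum(vapply(m$selected, function(t) {
      any(bm$drug_key == d & bm$target_key == t & bm$effect == "responsive")
    }, logical(1)))
  }, numeric(1))
  m$drug_rows[order(-cnt, m$drug_rows)]
}

# small randomized fixture spec for property tests (<= 10 drugs, <= 4
# selectable targets per matrix)
small_spec <- function(seed) {
  fixture_spec(
    n_mut_cgi = 5, n_mut_dtc = 5, n_mut_both = 2,
    n_drug_cgi = 6, n_drug_dtc = 6, n_drug_both = 2,
    n_pairs_cgi = 10, n_pairs_dtc = 14, n_pairs_both = 3,
    n_pairs_dtc_wt = 3,
    n_tumor_types = 4, n_wild_type_genes = 2,
    conflict_fraction = 0.5, seed = seed
  )
}
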