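# Synthetic source-table generator with controlled cardinalities, overlap
# and planted conflicts, plus a ground-truth manifest so downstream
# assertions (merge accounting, conflict recall) have an oracle.

#' Specification for a synthetic fixture
#'
#' Controls the per-source and shared cardinalities of mutations, drugs and
#' (drug, target) pairs, the number of tumor types and wild-type genes, the
#' fraction of shared pairs planted as conflicts, the activity-value range
#' of each intended potency class, and the replicate-count pool. All counts
#' are validated for satisfiability. Shared entities and pairs are realized
#' through the same canonical names in both tables, so merge statistics on
#' the generated fixture reproduce the spec's implied union counts exactly.
#'
#' Defaults describe a small, fully exercisable scenario: a handful of
#' genes, two shared mutations and drugs, one planted conflict.
#'
#' @param n_mut_cgi,n_mut_dtc,n_mut_both point-mutation counts per source
#'   and shared (shared included in each source count).
#' @param n_drug_cgi,n_drug_dtc,n_drug_both drug counts (drug combinations
#'   count as single drugs).
#' @param n_pairs_cgi,n_pairs_dtc,n_pairs_both distinct (drug, target) pair
#'   counts; `n_pairs_dtc` includes `n_pairs_dtc_wt` pairs on wild-type
#'   targets.
#' @param n_pairs_dtc_wt bioactivity pairs whose target is a wild-type gene.
#' @param n_tumor_types tumor types (biomarker source only).
#' @param n_wild_type_genes wild-type genes (bioactivity source only).
#' @param conflict_fraction fraction of shared pairs planted as conflicts
#'   (resistant effect with potent/highly potent activity); the planted
#'   count is `round(conflict_fraction * n_pairs_both)`.
#' @param activity_ranges named list of `c(lo, hi)` nM ranges for the four
#'   potency classes; replicate values of a pair are drawn uniformly inside
#'   its class range, so the median stays in class.
#' @param replicate_counts pool the per-pair replicate count is drawn from.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mut_cgi = 12, n_mut_dtc = 9, n_mut_both = 4,
                         n_drug_cgi = 8, n_drug_dtc = 7, n_drug_both = 3,
                         n_pairs_cgi = 20, n_pairs_dtc = 24, n_pairs_both = 5,
                         n_pairs_dtc_wt = 6,
                         n_tumor_types = 5, n_wild_type_genes = 3,
                         conflict_fraction = 0.4,
                         activity_ranges = list(
                           highly_potent = c(0.5, 10),
                           potent = c(20, 1000),
                           weakly_potent = c(1500, 10000),
                           inactive = c(15000, 500000)),
                         replicate_counts = c(1, 2, 3, 5),
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "fixture_spec")
  counts <- grep("^n_", names(spec), value = TRUE)
  spec[counts] <- lapply(spec[counts], as.integer)
  spec$replicate_counts <- as.integer(spec$replicate_counts)
  spec$seed <- as.integer(spec$seed)
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(s) {
  fail <- function(msg) stop(sprintf("unsatisfiable fixture spec: %s", msg),
                             call. = FALSE)
  chk_both <- function(b, a, d, what) {
    if (b > min(a, d)) fail(sprintf(
      "n_%s_both (%d) exceeds min(n_%s_cgi, n_%s_dtc) = %d", what, b, what, what,
      min(a, d)))
  }
  chk_both(s$n_mut_both, s$n_mut_cgi, s$n_mut_dtc, "mut")
  chk_both(s$n_drug_both, s$n_drug_cgi, s$n_drug_dtc, "drug")
  chk_both(s$n_pairs_both, s$n_pairs_cgi, s$n_pairs_dtc, "pairs")
  if (s$conflict_fraction < 0 || s$conflict_fraction > 1) {
    fail("conflict_fraction must be in [0, 1]")
  }
  if (s$n_pairs_dtc_wt > s$n_pairs_dtc) fail("n_pairs_dtc_wt exceeds n_pairs_dtc")
  n_pairs_dtc_mut <- s$n_pairs_dtc - s$n_pairs_dtc_wt
  if (s$n_pairs_both > s$n_drug_both * s$n_mut_both) {
    fail(sprintf("n_pairs_both (%d) exceeds the shared drug x mutation grid (%d)",
                 s$n_pairs_both, s$n_drug_both * s$n_mut_both))
  }
  if (s$n_pairs_both > 0 && s$n_pairs_both < max(s$n_drug_both, s$n_mut_both)) {
    fail(sprintf("n_pairs_both (%d) cannot cover all %d shared drugs and %d shared mutations",
                 s$n_pairs_both, s$n_drug_both, s$n_mut_both))
  }
  if ((s$n_mut_both > 0 || s$n_drug_both > 0) && s$n_pairs_both == 0) {
    fail("shared entities require at least one shared pair")
  }
  # the shared subgrid is reserved for the planted shared pairs, so each
  # source draws its remaining pairs from its grid minus that subgrid
  reserved <- s$n_drug_both * s$n_mut_both - s$n_pairs_both
  if (s$n_pairs_cgi > s$n_drug_cgi * s$n_mut_cgi - reserved) {
    fail("n_pairs_cgi exceeds the CGI drug x mutation grid")
  }
  if (n_pairs_dtc_mut > s$n_drug_dtc * s$n_mut_dtc - reserved) {
    fail("DTC mutation pairs exceed the DTC drug x mutation grid")
  }
  if (s$n_pairs_dtc_wt > s$n_drug_dtc * s$n_wild_type_genes) {
    fail("n_pairs_dtc_wt exceeds the DTC drug x wild-type-gene grid")
  }
  if (s$n_pairs_cgi < s$n_pairs_both +
      max(s$n_mut_cgi - s$n_mut_both, s$n_drug_cgi - s$n_drug_both)) {
    fail("n_pairs_cgi too small to cover every CGI drug and mutation")
  }
  if (n_pairs_dtc_mut < s$n_pairs_both +
      max(s$n_mut_dtc - s$n_mut_both, s$n_drug_dtc - s$n_drug_both)) {
    fail("DTC mutation pairs too small to cover every DTC drug and mutation")
  }
  if (s$n_wild_type_genes > 0 && s$n_pairs_dtc_wt < s$n_wild_type_genes) {
    fail("n_pairs_dtc_wt too small to cover every wild-type gene")
  }
  if (s$n_tumor_types > 0 && s$n_pairs_cgi < s$n_tumor_types) {
    fail("n_pairs_cgi too small to cover every tumor type")
  }
  ranges <- s$activity_ranges
  if (!all(potency_levels() %in% names(ranges))) {
    fail("activity_ranges must name all four potency classes")
  }
  for (cl in names(ranges)) {
    r <- ranges[[cl]]
    if (length(r) != 2 || r[1] <= 0 || r[2] < r[1]) {
      fail(sprintf("activity range for %s must be a positive c(lo, hi)", cl))
    }
    implied <- as.character(classify_potency(r))
    if (!all(implied == cl)) {
      fail(sprintf("activity range for %s crosses a potency boundary", cl))
    }
  }
  invisible(s)
}

#' Fixture spec with the published dataset cardinalities
#'
#' Returns a [fixture_spec()] whose marginals match the reported statistics
#' of the two real curated resources: 350/217/31 point mutations
#' (CGI/DTC/shared, union 536), 16 wild-type genes (bioactivity source
#' only), 166/116/24 drugs (union 258), 546/1859/42 distinct pairs (665 of
#' the bioactivity pairs on wild-type targets; distinct union 2363, summed
#' 2405) and 52 tumor types (biomarker source only).
#'
#' @param seed integer seed.
#' @param conflict_fraction fraction of the 42 shared pairs planted as
#'   conflicts (default 0.25).
#' @return a `fixture_spec`.
#' @export
table2_spec <- function(seed = 1L, conflict_fraction = 0.25) {
  fixture_spec(
    n_mut_cgi = 350, n_mut_dtc = 217, n_mut_both = 31,
    n_drug_cgi = 166, n_drug_dtc = 116, n_drug_both = 24,
    n_pairs_cgi = 546, n_pairs_dtc = 1859, n_pairs_both = 42,
    n_pairs_dtc_wt = 665,
    n_tumor_types = 52, n_wild_type_genes = 16,
    conflict_fraction = conflict_fraction,
    seed = seed
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Choose k distinct cells of an nd x nm grid (as linear indices), containing
# `required`, covering every column, and every row when cover_rows. Cells in
# `forbidden` are never chosen beyond `required` (used to keep the shared
# drug x mutation subgrid free of accidental extra cross-source pairs).
build_pair_set <- function(nd, nm, k, required = integer(0), cover_rows = TRUE,
                           forbidden = integer(0)) {
  idx_of <- function(d, m) (d - 1L) * nm + m
  used <- as.integer(required)
  used_d <- unique((used - 1L) %/% nm + 1L)
  used_m <- unique((used - 1L) %% nm + 1L)
  for (m in setdiff(seq_len(nm), used_m)) {
    uncov <- setdiff(seq_len(nd), used_d)
    d <- if (cover_rows && length(uncov)) {
      uncov[sample.int(length(uncov), 1L)]
    } else {
      sample.int(nd, 1L)
    }
    used <- c(used, idx_of(d, m))
    used_d <- unique(c(used_d, d))
  }
  if (cover_rows) {
    for (d in setdiff(seq_len(nd), used_d)) {
      repeat {
        m <- sample.int(nm, 1L)
        cand <- idx_of(d, m)
        if (!cand %in% used && !cand %in% forbidden) { used <- c(used, cand); break }
      }
    }
  }
  if (length(used) > k) {
    stop(sprintf("cannot place %d pairs while covering %d x %d entities", k, nd, nm),
         call. = FALSE)
  }
  avail <- setdiff(seq_len(nd * nm), c(used, forbidden))
  extra <- if (k > length(used)) {
    avail[sample.int(length(avail), k - length(used))]
  } else integer(0)
  out <- c(used, extra)
  cbind(drug = (out - 1L) %/% nm + 1L, mut = (out - 1L) %% nm + 1L)
}

pad_width <- function(n) max(3L, nchar(as.character(max(n, 1L))))

#' Generate a synthetic fixture
#'
#' Produces a biomarker table and a bioactivity table in the default
#' dialects (see [biomarker_dialect()] and [bioactivity_dialect()]) plus a
#' ground-truth manifest. Entity names are synthetic but format-faithful
#' (`GENE007(A123B)` mutations, `DRUG042` drugs, including a few `"A + B"`
#' drug combinations). The planted-conflict count is
#' `round(conflict_fraction * n_pairs_both)`; conflicts pair a resistant
#' biomarker with activity values whose median falls in (0, 1000] nM, and
#' all remaining shared pairs are planted consistent. Generation is
#' deterministic given the spec (including its seed).
#'
#' @param spec a [fixture_spec()].
#' @return a list of class `dt_fixture` with `biomarkers` and
#'   `bioactivities` (character data.frames in dialect layout) and
#'   `manifest` (true union counts, planted conflicting/consistent pairs,
#'   per-pair replicate values in nM).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(s) {
  n_mut_union <- s$n_mut_cgi + s$n_mut_dtc - s$n_mut_both
  n_drug_union <- s$n_drug_cgi + s$n_drug_dtc - s$n_drug_both
  n_pairs_dtc_mut <- s$n_pairs_dtc - s$n_pairs_dtc_wt

  # gene pool: wild-type genes first so mutated genes overlap them
  n_genes <- max(s$n_wild_type_genes, ceiling(n_mut_union / 8), 1L)
  gw <- pad_width(n_genes)
  genes <- sprintf(paste0("GENE%0", gw, "d"), seq_len(n_genes))
  wt_genes <- genes[seq_len(s$n_wild_type_genes)]

  # mutation pool (unique tokens), split shared / cgi-only / dtc-only
  mi <- seq_len(n_mut_union)
  mut_names <- sprintf("%s(%s%d%s)",
                       genes[(mi - 1L) %% n_genes + 1L],
                       LETTERS[(mi - 1L) %% 26L + 1L],
                       100L + mi,
                       LETTERS[(mi * 7L) %% 26L + 1L])
  ord <- sample.int(n_mut_union)
  mut_both <- mut_names[ord[seq_len(s$n_mut_both)]]
  rest <- ord[-seq_len(s$n_mut_both)]
  mut_cgi_only <- mut_names[rest[seq_len(s$n_mut_cgi - s$n_mut_both)]]
  mut_dtc_only <- mut_names[rest[(s$n_mut_cgi - s$n_mut_both) +
                                   seq_len(s$n_mut_dtc - s$n_mut_both)]]

  # drug pool; every 10th biomarker-only drug is a combination
  dw <- pad_width(n_drug_union * 2L)
  drug_names <- sprintf(paste0("DRUG%0", dw, "d"), seq_len(n_drug_union))
  dord <- sample.int(n_drug_union)
  drug_both <- drug_names[dord[seq_len(s$n_drug_both)]]
  drest <- dord[-seq_len(s$n_drug_both)]
  cgi_only_idx <- drest[seq_len(s$n_drug_cgi - s$n_drug_both)]
  drug_cgi_only <- drug_names[cgi_only_idx]
  combo <- seq_along(drug_cgi_only) %% 10L == 0L
  drug_cgi_only[combo] <- sprintf(
    paste0("%s + DRUG%0", dw, "d"), drug_cgi_only[combo],
    n_drug_union + seq_len(sum(combo)))
  drug_dtc_only <- drug_names[drest[(s$n_drug_cgi - s$n_drug_both) +
                                      seq_len(s$n_drug_dtc - s$n_drug_both)]]

  drugs_cgi <- c(drug_both, drug_cgi_only)
  drugs_dtc <- c(drug_both, drug_dtc_only)
  muts_cgi <- c(mut_both, mut_cgi_only)
  muts_dtc <- c(mut_both, mut_dtc_only)

  # shared pairs on the shared subgrid: a "diagonal" covering both sides
  # (distinct because lcm(n_drug_both, n_mut_both) >= max of the two)
  if (s$n_pairs_both > 0) {
    diag_len <- max(s$n_drug_both, s$n_mut_both)
    di <- (seq_len(diag_len) - 1L) %% s$n_drug_both + 1L
    mi2 <- (seq_len(diag_len) - 1L) %% s$n_mut_both + 1L
    both_idx <- (di - 1L) * s$n_mut_both + mi2
    if (s$n_pairs_both > diag_len) {
      avail <- setdiff(seq_len(s$n_drug_both * s$n_mut_both), both_idx)
      both_idx <- c(both_idx,
                    avail[sample.int(length(avail), s$n_pairs_both - diag_len)])
    }
    both_pairs <- cbind(drug = (both_idx - 1L) %/% s$n_mut_both + 1L,
                        mut = (both_idx - 1L) %% s$n_mut_both + 1L)
  } else {
    both_pairs <- cbind(drug = integer(0), mut = integer(0))
  }

  # full pair sets per source (indices into the per-source entity lists;
  # shared entities occupy the leading positions in both lists)
  shared_grid <- function(nm_total) {
    if (s$n_drug_both == 0L || s$n_mut_both == 0L) return(integer(0))
    as.vector(outer((seq_len(s$n_drug_both) - 1L) * nm_total,
                    seq_len(s$n_mut_both), `+`))
  }
  req_cgi <- (both_pairs[, "drug"] - 1L) * s$n_mut_cgi + both_pairs[, "mut"]
  cgi_pairs <- build_pair_set(s$n_drug_cgi, s$n_mut_cgi, s$n_pairs_cgi, req_cgi,
                              forbidden = setdiff(shared_grid(s$n_mut_cgi), req_cgi))
  req_dtc <- (both_pairs[, "drug"] - 1L) * s$n_mut_dtc + both_pairs[, "mut"]
  dtc_mut_pairs <- build_pair_set(s$n_drug_dtc, s$n_mut_dtc, n_pairs_dtc_mut, req_dtc,
                                  forbidden = setdiff(shared_grid(s$n_mut_dtc), req_dtc))
  dtc_wt_pairs <- if (s$n_pairs_dtc_wt > 0) {
    build_pair_set(s$n_drug_dtc, s$n_wild_type_genes, s$n_pairs_dtc_wt,
                   cover_rows = FALSE)
  } else cbind(drug = integer(0), mut = integer(0))

  # plant conflict / consistent scenarios on the shared pairs
  n_conf <- as.integer(round(s$conflict_fraction * s$n_pairs_both))
  shared_drug <- drugs_cgi[both_pairs[, "drug"]]
  shared_mut <- muts_cgi[both_pairs[, "mut"]]
  conf_sel <- if (s$n_pairs_both > 0) sample.int(s$n_pairs_both, n_conf) else integer(0)
  scenario <- rep(NA_character_, s$n_pairs_both)
  scenario[conf_sel] <- sample(c("conflict_high", "conflict_pot"),
                               n_conf, replace = TRUE)
  cons_sel <- setdiff(seq_len(s$n_pairs_both), conf_sel)
  scenario[cons_sel] <- sample(c("resp_high", "resp_pot", "res_inactive"),
                               length(cons_sel), replace = TRUE)
  shared_effect <- ifelse(scenario %in% c("conflict_high", "conflict_pot"),
                          "resistant",
                          ifelse(scenario == "res_inactive", "resistant",
                                 "responsive"))
  shared_class <- c(conflict_high = "highly_potent", conflict_pot = "potent",
                    resp_high = "highly_potent", resp_pot = "potent",
                    res_inactive = "inactive")[scenario]
  shared_key <- pair_key(canonicalize(shared_drug, "drug"), shared_mut)

  # ---- biomarker table ----------------------------------------------------
  bm_drug <- drugs_cgi[cgi_pairs[, "drug"]]
  bm_mut <- muts_cgi[cgi_pairs[, "mut"]]
  bm_key <- pair_key(canonicalize(bm_drug, "drug"), bm_mut)
  sh <- match(bm_key, shared_key)
  bm_effect <- ifelse(!is.na(sh), shared_effect[sh],
                      sample(EFFECT_LEVELS, s$n_pairs_cgi, replace = TRUE))
  bm_evidence <- sample(evidence_levels(), s$n_pairs_cgi, replace = TRUE)

  tw <- pad_width(s$n_tumor_types)
  tumor_pool <- sprintf(paste0("Tumor type %0", tw, "d"), seq_len(s$n_tumor_types))
  bm_tumors <- vapply(seq_len(s$n_pairs_cgi), function(i) {
    picks <- if (s$n_tumor_types == 0) character(0) else {
      base <- if (i <= s$n_tumor_types) tumor_pool[i] else character(0)
      n_extra <- sample.int(3L, 1L) - 1L
      unique(c(base, sample(tumor_pool, min(n_extra, s$n_tumor_types))))
    }
    paste(picks, collapse = ";")
  }, character(1))
  biomarkers <- data.frame(
    drug = bm_drug, target = bm_mut, effect = bm_effect,
    evidence_level = bm_evidence, tumor_types = bm_tumors,
    source_title = sprintf("Curated biomarker study %04d", seq_len(s$n_pairs_cgi)),
    source_doi = sprintf("10.1000/cgi.%04d", seq_len(s$n_pairs_cgi)),
    stringsAsFactors = FALSE
  )

  # ---- bioactivity table --------------------------------------------------
  ba_drug <- c(drugs_dtc[dtc_mut_pairs[, "drug"]], drugs_dtc[dtc_wt_pairs[, "drug"]])
  ba_target <- c(muts_dtc[dtc_mut_pairs[, "mut"]], wt_genes[dtc_wt_pairs[, "mut"]])
  n_pairs <- length(ba_drug)
  ba_key <- pair_key(canonicalize(ba_drug, "drug"), ba_target)
  shd <- match(ba_key, shared_key)
  pair_class <- ifelse(!is.na(shd), shared_class[shd],
                       sample(potency_levels(), n_pairs, replace = TRUE,
                              prob = c(0.15, 0.2, 0.4, 0.25)))
  reps <- s$replicate_counts[sample.int(length(s$replicate_counts), n_pairs,
                                        replace = TRUE)]

  pair_rows <- vector("list", n_pairs)
  pair_values <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    r <- reps[p]
    rng <- s$activity_ranges[[pair_class[p]]]
    unit <- ifelse(stats::runif(r) < 0.1 & rng[1] >= 1000, "uM", "nM")
    fac <- ifelse(unit == "uM", 1000, 1)
    v_unit <- round(stats::runif(r, rng[1] / fac, rng[2] / fac), 3)
    v_nM <- v_unit * fac
    pair_values[[p]] <- v_nM
    pair_rows[[p]] <- data.frame(
      drug = rep(ba_drug[p], r), target = rep(ba_target[p], r),
      measurement_type = sample(c("Kd", "Ki", "IC50"), r, replace = TRUE),
      value = sprintf("%.3f", v_unit),
      unit = unit,
      source_title = sprintf("Bioactivity assay %05d.%d", p, seq_len(r)),
      source_doi = sprintf("10.2000/dtc.%05d.%d", p, seq_len(r)),
      stringsAsFactors = FALSE
    )
  }
  bioactivities <- do.call(rbind, pair_rows)
  rownames(bioactivities) <- NULL

  manifest <- list(
    seed = s$seed,
    conflict_rule = "n_conflicts = round(conflict_fraction * n_pairs_both)",
    n_conflicts = n_conf,
    counts = list(
      mutations = c(cgi = s$n_mut_cgi, dtc = s$n_mut_dtc,
                    both = s$n_mut_both, union = n_mut_union),
      wild_type_genes = c(cgi = 0L, dtc = s$n_wild_type_genes,
                          both = 0L, union = s$n_wild_type_genes),
      drugs = c(cgi = s$n_drug_cgi, dtc = s$n_drug_dtc,
                both = s$n_drug_both, union = n_drug_union),
      drug_target_pairs = c(cgi = s$n_pairs_cgi, dtc = s$n_pairs_dtc,
                            both = s$n_pairs_both,
                            union = s$n_pairs_cgi + s$n_pairs_dtc - s$n_pairs_both,
                            sum = s$n_pairs_cgi + s$n_pairs_dtc),
      tumor_types = c(cgi = s$n_tumor_types, dtc = 0L, both = 0L,
                      union = s$n_tumor_types)
    ),
    conflicts = data.frame(
      drug = shared_drug[conf_sel], target = shared_mut[conf_sel],
      effect = shared_effect[conf_sel],
      intended_class = unname(shared_class[conf_sel]),
      stringsAsFactors = FALSE),
    consistent = data.frame(
      drug = shared_drug[cons_sel], target = shared_mut[cons_sel],
      effect = shared_effect[cons_sel],
      intended_class = unname(shared_class[cons_sel]),
      stringsAsFactors = FALSE),
    pairs = {
      df <- data.frame(drug = ba_drug, target = ba_target,
                       intended_class = unname(pair_class),
                       n_replicates = as.integer(reps), stringsAsFactors = FALSE)
      df$values_nM <- pair_values
      df$median_nM <- vapply(pair_values, stats::median, numeric(1))
      df
    }
  )

  structure(list(biomarkers = biomarkers, bioactivities = bioactivities,
                 manifest = manifest, spec = s),
            class = "dt_fixture")
}

#' @export
print.dt_fixture <- function(x, ...) {
  cat(sprintf("<dt_fixture> %d biomarker rows, %d bioactivity rows (%d pairs), %d planted conflicts\n",
              nrow(x$biomarkers), nrow(x$bioactivities),
              nrow(x$manifest$pairs), x$manifest$n_conflicts))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `biomarkers.tsv`, `bioactivities.tsv` and `manifest.json` into a
#' directory.
#'
#' @param fixture a `dt_fixture` from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "dt_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fixture$biomarkers, file.path(dir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(fixture$bioactivities, file.path(dir, "bioactivities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(fixture$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Build a linked store directly from a fixture
#'
#' Convenience wrapper: runs the fixture's two tables through the standard
#' parsers and [build_store()].
#'
#' @param fixture a `dt_fixture`.
#' @return a `linked_store`.
#' @export
fixture_store <- function(fixture) {
  stopifnot(inherits(fixture, "dt_fixture"))
  bm <- parse_biomarker_table(fixture$biomarkers)
  ba <- parse_bioactivity_table(fixture$bioactivities)
  if (nrow(bm$errors) || nrow(ba$errors)) {
    stop("generated fixture failed validation; this is a bug", call. = FALSE)
  }
  build_store(bm, ba)
}
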