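# Cross-source consistency states, evidence credibility and provenance.
#
# Consistency compares the curated effect (responsive/resistant) against the
# median-derived potency class of the same (drug, target) pair:
#
#   effect \ potency | highly_potent/potent | weakly_potent | inactive
#   -----------------+----------------------+---------------+------------
#   responsive       | consistent           | ambiguous     | conflicting
#   resistant        | conflicting          | ambiguous     | consistent
#
# Cells present in a single source are cgi_only / dtc_only; cells absent
# from both are missing. Weak potency neither reinforces nor contradicts a
# curated effect, hence its own "ambiguous" state.

#' Evidence levels, lowest to highest
#'
#' The five clinical evidence levels attached to treatment biomarkers, in
#' increasing order of approval status: pre-clinical, case report, early
#' trials, late trials, guidelines (e.g. FDA guidelines).
#'
#' @return character vector of the five levels in rank order.
#' @export
evidence_levels <- function() {
  c("pre_clinical", "case_report", "early_trials", "late_trials", "guidelines")
}

#' Ordinal rank of an evidence level
#'
#' @param level character vector of evidence levels.
#' @return integer vector of ranks 1 (pre_clinical) to 5 (guidelines).
#' @examples
#' evidence_rank("guidelines")  # 5
#' @export
evidence_rank <- function(level) {
  r <- match(level, evidence_levels())
  if (anyNA(r)) {
    stop(sprintf("unknown evidence level '%s'; allowed: %s",
                 paste(level[is.na(r)], collapse = "', '"),
                 paste(evidence_levels(), collapse = ", ")), call. = FALSE)
  }
  r
}

CONSISTENCY_STATES <- c("consistent", "conflicting", "ambiguous",
                        "cgi_only", "dtc_only", "missing")

#' Consistency state of a matrix cell
#'
#' Total, deterministic mapping from the curated effect (or absence) and the
#' potency class (or absence) of one (drug, target) cell to one of six
#' states; see the table in the package overview. Vectorized; `NA` encodes
#' absence.
#'
#' @param cgi_effect character vector in `{"responsive", "resistant", NA}`.
#' @param dtc_potency character vector of potency class labels or `NA`.
#' @return character vector of states in
#'   `{consistent, conflicting, ambiguous, cgi_only, dtc_only, missing}`.
#' @examples
#' classify_consistency("resistant", "potent")       # conflicting
#' classify_consistency("responsive", "highly_potent")  # consistent
#' classify_consistency(NA, NA)                      # missing
#' @export
classify_consistency <- function(cgi_effect, dtc_potency) {
  eff <- as.character(cgi_effect)
  pot <- as.character(dtc_potency)
  n <- max(length(eff), length(pot))
  eff <- rep_len(eff, n)
  pot <- rep_len(pot, n)
  bad_eff <- !is.na(eff) & !eff %in% EFFECT_LEVELS
  bad_pot <- !is.na(pot) & !pot %in% potency_levels()
  if (any(bad_eff)) stop(sprintf("unknown effect '%s'", eff[bad_eff][1]), call. = FALSE)
  if (any(bad_pot)) stop(sprintf("unknown potency level '%s'", pot[bad_pot][1]), call. = FALSE)

  out <- character(n)
  out[is.na(eff) & is.na(pot)] <- "missing"
  out[!is.na(eff) & is.na(pot)] <- "cgi_only"
  out[is.na(eff) & !is.na(pot)] <- "dtc_only"
  both <- !is.na(eff) & !is.na(pot)
  active <- pot %in% c("highly_potent", "potent")
  out[both & pot == "weakly_potent"] <- "ambiguous"
  out[both & eff == "responsive" & active] <- "consistent"
  out[both & eff == "resistant" & active] <- "conflicting"
  out[both & eff == "responsive" & pot == "inactive"] <- "conflicting"
  out[both & eff == "resistant" & pot == "inactive"] <- "consistent"
  out
}

# One row per curated (drug, target) cell. When a cell holds several
# biomarker records, the effect of the highest-evidence record represents
# the cell; an evidence tie with disagreeing effects resolves to
# "resistant" (the cautious reading for treatment selection).
resolve_cgi_cells <- function(store) {
  bm <- store$biomarkers
  if (nrow(bm) == 0L) {
    return(data.frame(drug_key = character(0), target_key = character(0),
                      effect = character(0), evidence_level = character(0),
                      evidence_rank = integer(0), dois = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- pair_key(bm$drug_key, bm$target_key)
  rank <- evidence_rank(bm$evidence_level)
  groups <- split(seq_len(nrow(bm)), key)
  groups <- groups[order(names(groups))]
  pick <- vapply(groups, function(i) {
    top <- i[rank[i] == max(rank[i])]
    res <- top[bm$effect[top] == "resistant"]
    if (length(res)) res[1] else top[1]
  }, integer(1))
  dois <- vapply(groups, function(i) {
    d <- unlist(lapply(bm$sources[i], function(s) s$doi), use.names = FALSE)
    paste(unique(d[!is.na(d)]), collapse = ";")
  }, character(1))
  out <- data.frame(
    drug_key = bm$drug_key[pick],
    target_key = bm$target_key[pick],
    effect = bm$effect[pick],
    evidence_level = bm$evidence_level[pick],
    evidence_rank = rank[pick],
    dois = unname(dois),
    stringsAsFactors = FALSE
  )
  out$sources <- lapply(groups, function(i) dedup_sources(bm$sources[i]))
  rownames(out) <- NULL
  out
}

#' Machine-readable conflict report
#'
#' Lists every (drug, target) pair curated in both sources whose
#' cross-source state is `conflicting` or `ambiguous`. Rows are ordered
#' conflicting-first, then by descending evidence rank of the curated
#' record, then alphabetically by drug, so the highest-credibility
#' contradictions surface first.
#'
#' @param store a `linked_store`.
#' @param targets optional character vector of target tokens restricting the
#'   report to those targets.
#' @return a data.frame with columns `drug`, `target`, `state`,
#'   `cgi_effect`, `cgi_evidence`, `dtc_median_nM`, `dtc_potency`,
#'   `cgi_doi`, `dtc_doi`, plus list columns `cgi_sources` and
#'   `dtc_sources` carrying full provenance.
#' @export
conflict_report <- function(store, targets = NULL) {
  stopifnot(inherits(store, "linked_store"))
  cgi <- resolve_cgi_cells(store)
  dtc <- store$activity_summaries
  ck <- pair_key(cgi$drug_key, cgi$target_key)
  dk <- pair_key(dtc$drug_key, dtc$target_key)
  shared <- intersect(ck, dk)
  ci <- match(shared, ck)
  di <- match(shared, dk)

  state <- classify_consistency(cgi$effect[ci], dtc$potency[di])
  keep <- state %in% c("conflicting", "ambiguous")
  ci <- ci[keep]; di <- di[keep]; state <- state[keep]

  dtc_dois <- vapply(dtc$sources[di], function(s) {
    d <- s$doi[!is.na(s$doi)]
    paste(unique(d), collapse = ";")
  }, character(1))

  out <- data.frame(
    drug = display_of(store$drugs, cgi$drug_key[ci]),
    target = cgi$target_key[ci],
    state = state,
    cgi_effect = cgi$effect[ci],
    cgi_evidence = cgi$evidence_level[ci],
    dtc_median_nM = dtc$median_value_nM[di],
    dtc_potency = dtc$potency[di],
    cgi_doi = cgi$dois[ci],
    dtc_doi = dtc_dois,
    stringsAsFactors = FALSE
  )
  out$cgi_sources <- cgi$sources[ci]
  out$dtc_sources <- dtc$sources[di]

  if (!is.null(targets)) {
    want <- canonicalize(targets, "target")
    out <- out[out$target %in% want, , drop = FALSE]
  }
  rank <- evidence_rank(out$cgi_evidence)
  ord <- order(match(out$state, c("conflicting", "ambiguous")), -rank,
               canonicalize(out$drug, "drug"))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

display_of <- function(entities, keys) {
  d <- entities$display[match(keys, entities$key)]
  ifelse(is.na(d), keys, d)
}

#' Write a conflict report as TSV
#'
#' @param report output of [conflict_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_conflict_report <- function(report, path) {
  flat <- report[, setdiff(names(report), c("cgi_sources", "dtc_sources")),
                 drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

doi_url <- function(doi) {
  ifelse(is.na(doi), NA_character_, paste0("https://doi.org/", doi))
}

#' Provenance details of one cell in one dataset
#'
#' Details-on-demand lookup: for a (drug, target) cell and a named source
#' dataset, returns the dataset label, a human-readable description of the
#' curated relation, and the publication sources with resolvable DOI URLs.
#' A cell absent from the named dataset raises a not-found error (condition
#' class `dtsynth_not_found`), distinguishing true missing data from a
#' mistyped lookup.
#'
#' @param store a `linked_store`.
#' @param drug drug name (any casing/spacing).
#' @param target target token, e.g. `"ABL1(T315I)"`.
#' @param dataset `"CGI"` (biomarkers) or `"DTC"` (bioactivities).
#' @return a list with `dataset`, `relation` (character description) and
#'   `sources` (data.frame with `title`, `abstract`, `doi`, `doi_url`,
#'   `dataset`).
#' @export
provenance_lookup <- function(store, drug, target, dataset = c("CGI", "DTC")) {
  stopifnot(inherits(store, "linked_store"))
  dataset <- match.arg(dataset)
  dkey <- canonicalize(drug, "drug")
  tkey <- canonicalize(target, "target")
  not_found <- function() {
    stop(errorCondition(
      sprintf("no %s record for drug '%s' and target '%s'", dataset, drug, target),
      class = c("dtsynth_not_found", "error", "condition")))
  }
  if (dataset == "CGI") {
    bm <- store$biomarkers
    sel <- which(bm$drug_key == dkey & bm$target_key == tkey)
    if (!length(sel)) not_found()
    rel <- vapply(sel, function(i) {
      tt <- bm$tumor_types[[i]]
      sprintf("%s (%s)%s", bm$effect[i], bm$evidence_level[i],
              if (length(tt)) paste0("; tumor types: ", paste(tt, collapse = ", ")) else "")
    }, character(1))
    src <- dedup_sources(bm$sources[sel])
  } else {
    ba <- store$bioactivities
    sel <- which(ba$drug_key == dkey & ba$target_key == tkey)
    if (!length(sel)) not_found()
    summ <- aggregate_activities(ba[sel, , drop = FALSE])
    rel <- c(sprintf("%s = %g nM", ba$measurement_type[sel], ba$value_nM[sel]),
             sprintf("median %g nM (%s), n = %d", summ$median_value_nM,
                     summ$potency, summ$n_measurements))
    src <- summ$sources
  }
  src$doi_url <- doi_url(src$doi)
  list(dataset = dataset, relation = paste(rel, collapse = "; "), sources = src)
}
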