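# The linked store: both sources harmonized onto canonical (drug, target)
# keys, with replicate bioactivities aggregated by their median.

STORE_SCHEMA_VERSION <- "dtsynth-store/1"

pair_key <- function(drug_key, target_key) paste(drug_key, target_key, sep = "\r")

#' Aggregate replicate bioactivities for one (drug, target) pair
#'
#' Multiple measured activities for the same pair are summarized by their
#' median, pooled across measurement types (Kd, Ki, IC50), which damps the
#' influence of outlying measurements. For an even number of values the
#' median is the arithmetic mean of the two central values. The potency
#' class is derived from the median; sources are de-duplicated by DOI
#' (falling back to title when the DOI is absent).
#'
#' @param records data.frame of bioactivity records for a single canonical
#'   pair (as in the `records` element of [parse_bioactivity_table()]).
#' @return a list with `median_value_nM`, `n_measurements`,
#'   `measurement_types` (character vector, one entry per measurement),
#'   `potency` (ordered factor level as character) and `sources`
#'   (data.frame).
#' @examples
#' recs <- data.frame(value_nM = c(1, 10, 1e5),
#'                    measurement_type = c("Kd", "Ki", "IC50"))
#' recs$sources <- replicate(3, NULL, simplify = FALSE)
#' aggregate_activities(recs)$median_value_nM  # 10
#' @export
aggregate_activities <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("aggregate_activities() requires at least one measurement", call. = FALSE)
  }
  med <- stats::median(records$value_nM)
  src <- dedup_sources(records$sources)
  list(median_value_nM = med,
       n_measurements = nrow(records),
       measurement_types = records$measurement_type,
       potency = as.character(classify_potency(med)),
       sources = src)
}

dedup_sources <- function(source_list) {
  src <- do.call(rbind, Filter(Negate(is.null), source_list))
  if (is.null(src) || nrow(src) == 0L) return(source_df(character(0), character(0), character(0)))
  id <- ifelse(is.na(src$doi), paste0("title:", src$title), src$doi)
  src[!duplicated(id), , drop = FALSE]
}

#' Build a linked store from validated record sets
#'
#' Canonicalizes drugs, targets and tumor types, groups the biomarker rows
#' into per-pair cells, aggregates the bioactivity rows into per-pair
#' activity summaries, and collects mutation-to-tumor-type links. No record
#' is lost: every valid biomarker row sits in exactly one cell, and the
#' summed `n_measurements` equals the number of valid bioactivity rows.
#'
#' @param biomarkers an `ingest_result` from [read_biomarkers()] /
#'   [parse_biomarker_table()], or its `records` data.frame.
#' @param bioactivities an `ingest_result` from [read_bioactivities()] /
#'   [parse_bioactivity_table()], or its `records` data.frame.
#' @return an object of class `linked_store` with elements `drugs`,
#'   `targets`, `tumor_types` (entity tables with canonical `key` and
#'   `display`), `biomarkers`, `bioactivities` (records keyed by canonical
#'   keys), `activity_summaries` (one row per DTC pair) and
#'   `mutation_tumor_links`.
#' @export
build_store <- function(biomarkers, bioactivities) {
  bm <- if (inherits(biomarkers, "ingest_result")) biomarkers$records else biomarkers
  ba <- if (inherits(bioactivities, "ingest_result")) bioactivities$records else bioactivities

  bm_drug_key <- canonicalize(bm$drug_name, "drug")
  ba_drug_key <- canonicalize(ba$drug_name, "drug")
  drugs <- entity_table(c(bm_drug_key, ba_drug_key),
                        c(bm$drug_name, ba$drug_name))

  tgt_keys <- c(bm$target_id, ba$target_id)
  tgt_df <- data.frame(
    key = tgt_keys, display = tgt_keys,
    gene = c(bm$target_gene, ba$target_gene),
    mutation = c(bm$target_mutation, ba$target_mutation),
    is_wild_type = c(bm$is_wild_type, ba$is_wild_type),
    stringsAsFactors = FALSE
  )
  tgt_df <- tgt_df[!duplicated(tgt_df$key), , drop = FALSE]
  targets <- tgt_df[order(tgt_df$key), , drop = FALSE]

  tumor_display <- unlist(bm$tumor_types, use.names = FALSE)
  if (is.null(tumor_display)) tumor_display <- character(0)
  tumors <- entity_table(canonicalize(tumor_display, "tumor"), tumor_display)

  biomarker_rows <- bm
  biomarker_rows$drug_key <- bm_drug_key
  biomarker_rows$target_key <- bm$target_id
  biomarker_rows$tumor_keys <- lapply(bm$tumor_types, canonicalize, type = "tumor")

  bioactivity_rows <- ba
  bioactivity_rows$drug_key <- ba_drug_key
  bioactivity_rows$target_key <- ba$target_id

  new_linked_store(drugs, targets, tumors, biomarker_rows, bioactivity_rows)
}

new_linked_store <- function(drugs, targets, tumor_types, biomarkers, bioactivities) {
  structure(list(
    drugs = drugs,
    targets = targets,
    tumor_types = tumor_types,
    biomarkers = biomarkers,
    bioactivities = bioactivities,
    activity_summaries = summarize_activities(bioactivities),
    mutation_tumor_links = mutation_tumor_links(biomarkers)
  ), class = "linked_store")
}

summarize_activities <- function(ba) {
  if (nrow(ba) == 0L) {
    out <- data.frame(drug_key = character(0), target_key = character(0),
                      median_value_nM = numeric(0), n_measurements = integer(0),
                      potency = character(0), stringsAsFactors = FALSE)
    out$measurement_types <- list()
    out$sources <- list()
    return(out)
  }
  key <- pair_key(ba$drug_key, ba$target_key)
  groups <- split(seq_len(nrow(ba)), key)
  groups <- groups[order(names(groups))]
  first <- vapply(groups, `[`, integer(1), 1L)
  med <- vapply(groups, function(i) stats::median(ba$value_nM[i]), numeric(1))
  out <- data.frame(
    drug_key = ba$drug_key[first],
    target_key = ba$target_key[first],
    median_value_nM = unname(med),
    n_measurements = unname(lengths(groups)),
    potency = as.character(classify_potency(unname(med))),
    stringsAsFactors = FALSE
  )
  out$measurement_types <- lapply(groups, function(i) ba$measurement_type[i])
  out$sources <- lapply(groups, function(i) dedup_sources(ba$sources[i]))
  rownames(out) <- NULL
  out
}

mutation_tumor_links <- function(bm) {
  if (nrow(bm) == 0L) {
    return(data.frame(target_key = character(0), tumor_key = character(0),
                      stringsAsFactors = FALSE))
  }
  n_tt <- lengths(bm$tumor_keys)
  df <- data.frame(
    target_key = rep(bm$target_key, n_tt),
    tumor_key = unlist(bm$tumor_keys, use.names = FALSE),
    is_wild_type = rep(bm$is_wild_type, n_tt),
    stringsAsFactors = FALSE
  )
  df <- df[!df$is_wild_type, c("target_key", "tumor_key"), drop = FALSE]
  df <- unique(df)
  df <- df[order(df$target_key, df$tumor_key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.linked_store <- function(x, ...) {
  cat(sprintf(paste0("<linked_store> %d drugs, %d targets, %d tumor types\n",
                     "  biomarker records: %d (%d pairs)\n",
                     "  bioactivity records: %d (%d pairs)\n"),
              nrow(x$drugs), nrow(x$targets), nrow(x$tumor_types),
              nrow(x$biomarkers),
              length(unique(pair_key(x$biomarkers$drug_key, x$biomarkers$target_key))),
              nrow(x$bioactivities), nrow(x$activity_summaries)))
  invisible(x)
}

#' Merge statistics of a linked store
#'
#' Counts, per entity class, how many distinct entities come from the
#' biomarker source (CGI), the bioactivity source (DTC), both, and the
#' union. Classes: point mutations, wild-type genes, drugs (drug
#' combinations count as single drugs), distinct (drug, target) pairs, and
#' tumor types. The inclusion-exclusion identity
#' `count_union = count_cgi + count_dtc - count_both` holds for every class;
#' the summed per-source pair count (`count_cgi + count_dtc` of the pair
#' class) is exposed via `pair_rows_sum()` on the result.
#'
#' @param store a `linked_store`.
#' @return a data.frame of class `merge_stats` with columns `class`,
#'   `count_cgi`, `count_dtc`, `count_both`, `count_union`.
#' @export
merge_statistics <- function(store) {
  stopifnot(inherits(store, "linked_store"))
  bm <- store$biomarkers
  ba <- store$bioactivities
  cgi <- list(
    mutations = unique(bm$target_key[!bm$is_wild_type]),
    wild_type_genes = unique(bm$target_key[bm$is_wild_type]),
    drugs = unique(bm$drug_key),
    drug_target_pairs = unique(pair_key(bm$drug_key, bm$target_key)),
    tumor_types = unique(unlist(bm$tumor_keys, use.names = FALSE))
  )
  dtc <- list(
    mutations = unique(ba$target_key[!ba$is_wild_type]),
    wild_type_genes = unique(ba$target_key[ba$is_wild_type]),
    drugs = unique(ba$drug_key),
    drug_target_pairs = unique(pair_key(ba$drug_key, ba$target_key)),
    tumor_types = character(0)
  )
  classes <- names(cgi)
  n_cgi <- vapply(cgi, length, integer(1))
  n_dtc <- vapply(dtc, length, integer(1))
  n_both <- mapply(function(a, b) length(intersect(a, b)), cgi, dtc)
  out <- data.frame(class = classes,
                    count_cgi = unname(n_cgi),
                    count_dtc = unname(n_dtc),
                    count_both = unname(n_both),
                    count_union = unname(n_cgi + n_dtc - n_both),
                    stringsAsFactors = FALSE)
  class(out) <- c("merge_stats", class(out))
  out
}

#' Summed per-source pair count
#'
#' The number of (drug, target) pair rows summed over the two sources,
#' i.e. pairs present in both sources counted twice. Complements the
#' distinct-union pair count in [merge_statistics()].
#'
#' @param stats a `merge_stats` data.frame.
#' @return integer.
#' @export
pair_rows_sum <- function(stats) {
  stopifnot(inherits(stats, "merge_stats"))
  i <- match("drug_target_pairs", stats$class)
  stats$count_cgi[i] + stats$count_dtc[i]
}

#' Write merge statistics as TSV
#'
#' @param stats a `merge_stats` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_merge_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# --- serialization -----------------------------------------------------

sources_to_list <- function(src) {
  lapply(seq_len(nrow(src)), function(i) {
    list(title = na_null(src$title[i]), abstract = na_null(src$abstract[i]),
         doi = na_null(src$doi[i]), dataset = src$dataset[i])
  })
}

na_null <- function(x) if (is.na(x)) NULL else x
null_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

sources_from_list <- function(lst) {
  if (length(lst) == 0L) return(source_df(character(0), character(0), character(0)))
  data.frame(
    title = vapply(lst, function(s) null_na(s$title), character(1)),
    abstract = vapply(lst, function(s) null_na(s$abstract), character(1)),
    doi = vapply(lst, function(s) null_na(s$doi), character(1)),
    dataset = vapply(lst, function(s) null_na(s$dataset), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a linked store to a JSON document
#'
#' The raw harmonized records are written together with the entity tables
#' and a schema-version field; derived structures (activity summaries,
#' mutation-tumor links) are recomputed on load, so
#' `read_store(write_store(s))` reproduces `s` exactly.
#'
#' @param store a `linked_store`.
#' @param path output path for the JSON file.
#' @return the path, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "linked_store"))
  bm <- store$biomarkers
  ba <- store$bioactivities
  obj <- list(
    schema_version = STORE_SCHEMA_VERSION,
    drugs = store$drugs,
    targets = store$targets,
    tumor_types = store$tumor_types,
    biomarkers = lapply(seq_len(nrow(bm)), function(i) list(
      drug_name = bm$drug_name[i], drug_key = bm$drug_key[i],
      target_key = bm$target_key[i], gene = bm$target_gene[i],
      mutation = bm$target_mutation[i], is_wild_type = bm$is_wild_type[i],
      effect = bm$effect[i], evidence_level = bm$evidence_level[i],
      tumor_types = as.list(bm$tumor_types[[i]]),
      tumor_keys = as.list(bm$tumor_keys[[i]]),
      sources = sources_to_list(bm$sources[[i]])
    )),
    bioactivities = lapply(seq_len(nrow(ba)), function(i) list(
      drug_name = ba$drug_name[i], drug_key = ba$drug_key[i],
      target_key = ba$target_key[i], gene = ba$target_gene[i],
      mutation = ba$target_mutation[i], is_wild_type = ba$is_wild_type[i],
      measurement_type = ba$measurement_type[i], value_nM = ba$value_nM[i],
      sources = sources_to_list(ba$sources[[i]])
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

chr_or_empty <- function(lst, field) {
  vapply(lst, function(r) null_na(r[[field]]), character(1))
}

#' Read a linked store from a JSON document
#'
#' @param path path to a file written by [write_store()].
#' @return a `linked_store`.
#' @export
read_store <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf(
                    "cannot parse store file %s: %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (is.null(obj$schema_version)) {
    stop("corrupted store file: missing schema_version", call. = FALSE)
  }
  if (!identical(obj$schema_version, STORE_SCHEMA_VERSION)) {
    stop(sprintf("store schema version mismatch: found '%s', expected '%s'",
                 obj$schema_version, STORE_SCHEMA_VERSION), call. = FALSE)
  }
  ent <- function(x, cols) {
    if (length(x) == 0L) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                          stringsAsFactors = FALSE)
      return(df)
    }
    as.data.frame(lapply(setNames(cols, cols), function(cl) {
      v <- sapply(x, `[[`, cl)
      if (cl == "is_wild_type") as.logical(v) else as.character(v)
    }), stringsAsFactors = FALSE)
  }
  drugs <- ent(obj$drugs, c("key", "display"))
  targets <- ent(obj$targets, c("key", "display", "gene", "mutation", "is_wild_type"))
  tumors <- ent(obj$tumor_types, c("key", "display"))

  bml <- obj$biomarkers
  bm <- data.frame(
    drug_name = chr_or_empty(bml, "drug_name"),
    target_id = chr_or_empty(bml, "target_key"),
    target_gene = chr_or_empty(bml, "gene"),
    target_mutation = chr_or_empty(bml, "mutation"),
    is_wild_type = vapply(bml, function(r) isTRUE(r$is_wild_type), logical(1)),
    effect = chr_or_empty(bml, "effect"),
    evidence_level = chr_or_empty(bml, "evidence_level"),
    drug_key = chr_or_empty(bml, "drug_key"),
    target_key = chr_or_empty(bml, "target_key"),
    stringsAsFactors = FALSE
  )
  bm$tumor_types <- lapply(bml, function(r) as.character(unlist(r$tumor_types)))
  bm$tumor_keys <- lapply(bml, function(r) as.character(unlist(r$tumor_keys)))
  bm$sources <- lapply(bml, function(r) sources_from_list(r$sources))
  if (length(bml) == 0L) {
    bm <- empty_biomarker_records()
    bm$drug_key <- character(0); bm$target_key <- character(0)
    bm$tumor_keys <- list()
  }

  bal <- obj$bioactivities
  ba <- data.frame(
    drug_name = chr_or_empty(bal, "drug_name"),
    target_id = chr_or_empty(bal, "target_key"),
    target_gene = chr_or_empty(bal, "gene"),
    target_mutation = chr_or_empty(bal, "mutation"),
    is_wild_type = vapply(bal, function(r) isTRUE(r$is_wild_type), logical(1)),
    measurement_type = chr_or_empty(bal, "measurement_type"),
    value_nM = vapply(bal, function(r) as.numeric(r$value_nM), numeric(1)),
    drug_key = chr_or_empty(bal, "drug_key"),
    target_key = chr_or_empty(bal, "target_key"),
    stringsAsFactors = FALSE
  )
  ba$sources <- lapply(bal, function(r) sources_from_list(r$sources))
  if (length(bal) == 0L) {
    ba <- empty_bioactivity_records()
    ba$drug_key <- character(0); ba$target_key <- character(0)
  }

  # same column order as build_store() so round-trips compare field-by-field
  bm <- bm[, c("drug_name", "target_id", "target_gene", "target_mutation",
               "is_wild_type", "effect", "evidence_level", "tumor_types",
               "sources", "drug_key", "target_key", "tumor_keys")]
  ba <- ba[, c("drug_name", "target_id", "target_gene", "target_mutation",
               "is_wild_type", "measurement_type", "value_nM", "sources",
               "drug_key", "target_key")]
  new_linked_store(drugs, targets, tumors, bm, ba)
}
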