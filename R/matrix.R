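# The drug-by-target matrix model: user-selected mutation columns plus
# auto-added wild-type columns, drug rows, tumor-type rows, and per-cell
# consistency states. Three sorting procedures reorder the drug rows.

#' Assemble a drug-by-target matrix
#'
#' Each selected mutation becomes a column; the wild-type gene of a selected
#' mutation, if present in the store, is appended once as an extra column
#' (useful for anticipating off-target effects: comparable potency toward
#' the wild type suggests side effects). Rows are exactly the drugs related
#' to at least one column target, in alphabetical order of their canonical
#' key (the base order that the sorting procedures permute); tumor-type rows
#' are the tumor types linked to at least one selected mutation. Every
#' (drug, column) cell carries a consistency state, so missing data are
#' explicit cells, not absences.
#'
#' @param store a `linked_store`.
#' @param selected_mutations character vector of mutation tokens, e.g.
#'   `c("ABL1(T315I)", "ABL1(E255K)")`. Must exist in the store and must not
#'   be wild-type genes.
#' @return an object of class `matrix_model` with elements `columns`
#'   (data.frame: key, display, gene, is_wild_type, is_selected),
#'   `drug_rows` (canonical keys), `drugs` (key/display), `tumor_rows`,
#'   `tumors`, `cells` (full rows-by-columns grid with per-cell payloads and
#'   `state`), `tumor_cells` (tumor-mutation links in view) and `selected`.
#' @export
assemble_matrix <- function(store, selected_mutations) {
  stopifnot(inherits(store, "linked_store"))
  if (length(selected_mutations) == 0L) {
    stop("at least one mutation must be selected", call. = FALSE)
  }
  keys <- unique(canonicalize(selected_mutations, "target"))
  known <- store$targets$key
  missing <- setdiff(keys, known)
  if (length(missing)) {
    hints <- unlist(lapply(missing, function(k) {
      known[agrepl(k, known, max.distance = 0.25, ignore.case = TRUE)]
    }))
    stop(sprintf("unknown target(s): %s%s", paste(missing, collapse = ", "),
                 if (length(hints)) paste0("; nearest matches: ",
                                           paste(unique(hints), collapse = ", "))
                 else ""), call. = FALSE)
  }
  tinfo <- store$targets[match(keys, store$targets$key), , drop = FALSE]
  if (any(tinfo$is_wild_type)) {
    stop(sprintf("selected targets must be mutations, not wild-type genes: %s",
                 paste(keys[tinfo$is_wild_type], collapse = ", ")), call. = FALSE)
  }

  # wild-type columns, appended once per gene and only if present in the data
  wt_keys <- unique(tinfo$gene)
  wt_keys <- wt_keys[wt_keys %in% known]
  wt_keys <- setdiff(wt_keys, keys)
  col_keys <- c(keys, wt_keys)
  columns <- store$targets[match(col_keys, store$targets$key), , drop = FALSE]
  columns$is_selected <- columns$key %in% keys
  rownames(columns) <- NULL

  bm <- store$biomarkers
  ba <- store$activity_summaries
  related <- sort(unique(c(bm$drug_key[bm$target_key %in% col_keys],
                           ba$drug_key[ba$target_key %in% col_keys])))

  links <- store$mutation_tumor_links
  tumor_rows <- sort(unique(links$tumor_key[links$target_key %in% keys]))
  tumor_cells <- links[links$target_key %in% keys &
                         links$tumor_key %in% tumor_rows, , drop = FALSE]
  rownames(tumor_cells) <- NULL

  cells <- build_cells(store, related, col_keys)

  structure(list(
    columns = columns,
    drug_rows = related,
    drugs = store$drugs[store$drugs$key %in% related, , drop = FALSE],
    tumor_rows = tumor_rows,
    tumors = store$tumor_types[store$tumor_types$key %in% tumor_rows, , drop = FALSE],
    cells = cells,
    tumor_cells = tumor_cells,
    selected = keys
  ), class = "matrix_model")
}

build_cells <- function(store, drug_keys, col_keys) {
  grid <- expand.grid(drug_key = drug_keys, target_key = col_keys,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cgi <- resolve_cgi_cells(store)
  dtc <- store$activity_summaries
  gi <- match(pair_key(grid$drug_key, grid$target_key),
              pair_key(cgi$drug_key, cgi$target_key))
  di <- match(pair_key(grid$drug_key, grid$target_key),
              pair_key(dtc$drug_key, dtc$target_key))
  grid$has_cgi <- !is.na(gi)
  grid$has_dtc <- !is.na(di)
  grid$cgi_effect <- cgi$effect[gi]
  grid$cgi_evidence <- cgi$evidence_level[gi]
  grid$cgi_rank <- cgi$evidence_rank[gi]
  grid$dtc_median_nM <- dtc$median_value_nM[di]
  grid$dtc_potency <- dtc$potency[di]
  grid$n_measurements <- dtc$n_measurements[di]
  grid$state <- classify_consistency(grid$cgi_effect, grid$dtc_potency)
  grid
}

#' @export
print.matrix_model <- function(x, ...) {
  cat(sprintf("<matrix_model> %d drugs x %d targets (%d selected), %d tumor rows\n",
              length(x$drug_rows), nrow(x$columns), length(x$selected),
              length(x$tumor_rows)))
  tab <- table(factor(x$cells$state, levels = CONSISTENCY_STATES))
  cat("  cell states:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

cell_row <- function(m, drug_key, target_key) {
  m$cells[m$cells$drug_key == drug_key & m$cells$target_key == target_key, ,
          drop = FALSE]
}

#' Sort drugs by their relation to one target column
#'
#' Drugs related to the chosen target come first in three groups: data in
#' both sources, then biomarker-source only, then bioactivity-source only.
#' Within the both-source and bioactivity-only groups, drugs are ordered
#' most-potent-first (ascending median nM); within the biomarker-only group
#' and for ties, alphabetically. Drugs unrelated to the target follow,
#' keeping their current order (stable).
#'
#' @param m a `matrix_model`.
#' @param target a column target token.
#' @return character vector: a permutation of `m$drug_rows`.
#' @export
sort_by_target <- function(m, target) {
  stopifnot(inherits(m, "matrix_model"))
  tkey <- canonicalize(target, "target")
  if (!tkey %in% m$columns$key) {
    stop(sprintf("target '%s' is not a column of the matrix", target), call. = FALSE)
  }
  cc <- m$cells[m$cells$target_key == tkey, , drop = FALSE]
  cc <- cc[match(m$drug_rows, cc$drug_key), , drop = FALSE]
  group <- ifelse(cc$has_cgi & cc$has_dtc, 1L,
                  ifelse(cc$has_cgi, 2L, ifelse(cc$has_dtc, 3L, 4L)))
  by_median <- group %in% c(1L, 3L)
  med <- ifelse(by_median, cc$dtc_median_nM, 0)
  orig <- ifelse(group == 4L, seq_along(m$drug_rows), 0L)
  m$drug_rows[order(group, med, orig, m$drug_rows)]
}

#' Sort drugs by total potency over the selected mutations
#'
#' Scores each drug by the sum, over the selected mutation columns with
#' bioactivity data, of the pActivity of the median activity value
#' (`-log10` molar; 10 nM contributes 8). Columns without data contribute
#' 0. Drugs are returned in descending score order, ties alphabetical. The
#' `mode = "raw_nM"` variant sums the raw median nM values instead (for
#' sensitivity checks); it also sorts descending.
#'
#' @param m a `matrix_model`.
#' @param mode `"pactivity"` (default) or `"raw_nM"`.
#' @return character vector: a permutation of `m$drug_rows`.
#' @export
sort_by_potency_sum <- function(m, mode = c("pactivity", "raw_nM")) {
  stopifnot(inherits(m, "matrix_model"))
  mode <- match.arg(mode)
  cc <- m$cells[m$cells$target_key %in% m$selected & m$cells$has_dtc, , drop = FALSE]
  contrib <- if (mode == "pactivity") pactivity(cc$dtc_median_nM) else cc$dtc_median_nM
  score <- vapply(m$drug_rows, function(d) sum(contrib[cc$drug_key == d]),
                  numeric(1))
  m$drug_rows[order(-score, m$drug_rows)]
}

#' Sort drugs by number of responsive mutations
#'
#' Counts, for each drug, the selected mutation columns whose curated effect
#' is responsive, and sorts descending; ties alphabetical.
#'
#' @param m a `matrix_model`.
#' @return character vector: a permutation of `m$drug_rows`.
#' @export
sort_by_responsive_count <- function(m) {
  stopifnot(inherits(m, "matrix_model"))
  cc <- m$cells[m$cells$target_key %in% m$selected, , drop = FALSE]
  resp <- cc$has_cgi & !is.na(cc$cgi_effect) & cc$cgi_effect == "responsive"
  count <- vapply(m$drug_rows, function(d) sum(resp[cc$drug_key == d]),
                  numeric(1))
  m$drug_rows[order(-count, m$drug_rows)]
}

#' Entities related to a focused drug, cell or tumor type
#'
#' Computes the highlight sets a front end would light up on hover: focusing
#' a drug yields its related targets plus the tumor types of those targets;
#' focusing a cell yields its mutation, its drug, and the wild-type column
#' of the mutation's gene when present; focusing a tumor type yields its
#' related mutations in view.
#'
#' @param m a `matrix_model`.
#' @param drug,cell,tumor exactly one focus: a drug name, a
#'   `c(drug, target)` pair, or a tumor-type name.
#' @return a list with character-vector elements `drugs`, `targets`,
#'   `tumors` (canonical keys).
#' @export
highlight_sets <- function(m, drug = NULL, cell = NULL, tumor = NULL) {
  stopifnot(inherits(m, "matrix_model"))
  n_focus <- sum(!is.null(drug), !is.null(cell), !is.null(tumor))
  if (n_focus != 1L) stop("give exactly one of drug=, cell=, tumor=", call. = FALSE)

  if (!is.null(drug)) {
    dkey <- canonicalize(drug, "drug")
    if (!dkey %in% m$drug_rows) stop(sprintf("drug '%s' is not in the matrix", drug), call. = FALSE)
    cc <- m$cells[m$cells$drug_key == dkey & (m$cells$has_cgi | m$cells$has_dtc), , drop = FALSE]
    tgts <- unique(cc$target_key)
    tums <- unique(m$tumor_cells$tumor_key[m$tumor_cells$target_key %in% tgts])
    list(drugs = dkey, targets = sort(tgts), tumors = sort(tums))
  } else if (!is.null(cell)) {
    if (length(cell) != 2L) stop("cell focus must be c(drug, target)", call. = FALSE)
    dkey <- canonicalize(cell[1], "drug")
    tkey <- canonicalize(cell[2], "target")
    if (nrow(cell_row(m, dkey, tkey)) == 0L) {
      stop(sprintf("cell (%s, %s) is not in the matrix", cell[1], cell[2]), call. = FALSE)
    }
    gene <- m$columns$gene[m$columns$key == tkey]
    wt <- m$columns$key[m$columns$is_wild_type & m$columns$gene == gene]
    list(drugs = dkey, targets = sort(unique(c(tkey, wt))), tumors = character(0))
  } else {
    tkey <- canonicalize(tumor, "tumor")
    if (!tkey %in% m$tumor_rows) stop(sprintf("tumor type '%s' is not in the matrix", tumor), call. = FALSE)
    tgts <- unique(m$tumor_cells$target_key[m$tumor_cells$tumor_key == tkey])
    list(drugs = character(0), targets = sort(tgts), tumors = tkey)
  }
}

#' Serialize a matrix model to JSON
#'
#' Sidecar document for a rendered matrix: schema-versioned JSON holding the
#' column/row orders and the full cell grid with consistency states.
#'
#' @param m a `matrix_model`.
#' @param path output path.
#' @param drug_order optional permutation of `m$drug_rows` (e.g. from a
#'   sorting procedure) recorded as the display order.
#' @return the path, invisibly.
#' @export
write_matrix_json <- function(m, path, drug_order = NULL) {
  stopifnot(inherits(m, "matrix_model"))
  if (is.null(drug_order)) drug_order <- m$drug_rows
  stopifnot(setequal(drug_order, m$drug_rows))
  cells <- m$cells
  obj <- list(
    schema_version = "dtsynth-matrix/1",
    columns = m$columns,
    drug_rows = drug_order,
    tumor_rows = m$tumor_rows,
    tumor_cells = m$tumor_cells,
    cells = cells
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
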