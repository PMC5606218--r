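# Reading the two source-table dialects with row-level validation.
#
# Both upstream resources export delimited tables with named headers, so
# column order is irrelevant. Rows that fail validation are collected into
# an error table (row, column, message) rather than silently dropped; every
# input row ends up either as a record or as exactly one error row.

EFFECT_LEVELS <- c("responsive", "resistant")

# Normalize a free-text label to a snake_case token for alias matching.
norm_label <- function(x) {
  x <- tolower(canonical_text(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

default_evidence_aliases <- function() {
  c(pre_clinical = "pre_clinical",
    preclinical = "pre_clinical",
    case_report = "case_report",
    early_trials = "early_trials",
    late_trials = "late_trials",
    guidelines = "guidelines",
    fda_guidelines = "guidelines",
    clinical_guidelines = "guidelines")
}

#' Table dialect for biomarker exports
#'
#' Describes how a curated cancer-treatment-biomarker table is laid out:
#' field separator, the separator used inside the tumor-type list column,
#' the header names of the required columns, and an alias map for evidence
#' labels (e.g. `"FDA guidelines"` is read as `guidelines`).
#'
#' @param sep field separator (default tab).
#' @param list_sep separator inside the `tumor_types` column (default `";"`).
#' @param columns named character vector mapping the roles `drug`, `target`,
#'   `effect`, `evidence`, `tumor_types`, `source_title`, `source_doi` to
#'   header names in the file.
#' @param evidence_aliases named character vector mapping normalized labels
#'   to canonical evidence levels; merged over the built-in defaults.
#' @return a list of class `table_dialect`.
#' @export
biomarker_dialect <- function(sep = "\t", list_sep = ";",
                              columns = c(drug = "drug", target = "target",
                                          effect = "effect",
                                          evidence = "evidence_level",
                                          tumor_types = "tumor_types",
                                          source_title = "source_title",
                                          source_doi = "source_doi"),
                              evidence_aliases = character(0)) {
  aliases <- default_evidence_aliases()
  aliases[names(evidence_aliases)] <- evidence_aliases
  structure(list(kind = "biomarker", sep = sep, list_sep = list_sep,
                 columns = columns, evidence_aliases = aliases),
            class = "table_dialect")
}

#' Table dialect for bioactivity exports
#'
#' @param sep field separator (default tab).
#' @param columns named character vector mapping the roles `drug`, `target`,
#'   `measurement_type`, `value`, `unit`, `source_title`, `source_doi` to
#'   header names. The `unit` column is optional in the file; when absent,
#'   values are taken to be nanomolar.
#' @param thousands_sep thousands separator stripped from numeric values.
#' @return a list of class `table_dialect`.
#' @export
bioactivity_dialect <- function(sep = "\t",
                                columns = c(drug = "drug", target = "target",
                                            measurement_type = "measurement_type",
                                            value = "value", unit = "unit",
                                            source_title = "source_title",
                                            source_doi = "source_doi"),
                                thousands_sep = ",") {
  structure(list(kind = "bioactivity", sep = sep, columns = columns,
                 thousands_sep = thousands_sep),
            class = "table_dialect")
}

read_delim_table <- function(path, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    quote = "", comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

check_columns <- function(tab, needed, where) {
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

empty_errors <- function() {
  data.frame(row = integer(0), column = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

new_ingest_result <- function(records, errors, n_input) {
  structure(list(records = records, errors = errors, n_input = n_input),
            class = "ingest_result")
}

#' @export
print.ingest_result <- function(x, ...) {
  cat(sprintf("<ingest_result> %d input rows: %d records, %d rejected\n",
              x$n_input, nrow(x$records), nrow(x$errors)))
  invisible(x)
}

source_df <- function(title, doi, dataset) {
  data.frame(title = title,
             abstract = rep(NA_character_, length(title)),
             doi = ifelse(nzchar(doi), doi, NA_character_),
             dataset = rep_len(dataset, length(title)),
             stringsAsFactors = FALSE)
}

#' Parse an in-memory biomarker table
#'
#' Core of [read_biomarkers()]: validates and converts a character
#' data.frame already holding the dialect's columns. One record is produced
#' per valid row; invalid rows produce one error row each, so
#' `nrow(records) + nrow(errors)` equals the number of input rows.
#'
#' @param tab data.frame of character columns (as exported, one row per
#'   curated biomarker).
#' @param dialect a [biomarker_dialect()].
#' @return an `ingest_result`: list with `records` (data.frame with columns
#'   `drug_name`, `target_id`, `target_gene`, `target_mutation`,
#'   `is_wild_type`, `effect`, `evidence_level`, and list columns
#'   `tumor_types`, `sources`), `errors` (row, column, message) and
#'   `n_input`.
#' @export
parse_biomarker_table <- function(tab, dialect = biomarker_dialect()) {
  cols <- dialect$columns
  check_columns(tab, unname(cols), "biomarker")
  n <- nrow(tab)
  if (n == 0L) return(new_ingest_result(empty_biomarker_records(), empty_errors(), 0L))

  drug <- canonical_text(tab[[cols[["drug"]]]])
  target <- parse_targets(tab[[cols[["target"]]]])
  eff_norm <- norm_label(tab[[cols[["effect"]]]])
  eff_ok <- eff_norm %in% EFFECT_LEVELS
  ev_norm <- norm_label(tab[[cols[["evidence"]]]])
  ev_canon <- unname(dialect$evidence_aliases[ev_norm])
  ev_ok <- !is.na(ev_canon)

  # first failing check wins; one error row per bad input row
  err_col <- rep(NA_character_, n)
  err_msg <- rep(NA_character_, n)
  flag <- function(bad, column, msg) {
    sel <- bad & is.na(err_col)
    err_col[sel] <<- column
    err_msg[sel] <<- msg[sel]
  }
  flag(!nzchar(drug), cols[["drug"]], rep("drug name is empty", n))
  flag(!target$ok, cols[["target"]],
       ifelse(nzchar(target$msg), target$msg, "invalid target token"))
  flag(!eff_ok, cols[["effect"]],
       sprintf("unknown effect '%s'; allowed: %s",
               tab[[cols[["effect"]]]], paste(EFFECT_LEVELS, collapse = ", ")))
  flag(!ev_ok, cols[["evidence"]],
       sprintf("unknown evidence level '%s'; allowed: %s",
               tab[[cols[["evidence"]]]],
               paste(evidence_levels(), collapse = ", ")))

  bad <- !is.na(err_col)
  errors <- data.frame(row = which(bad), column = err_col[bad],
                       message = err_msg[bad], stringsAsFactors = FALSE)
  keep <- which(!bad)

  tt_raw <- strsplit(tab[[cols[["tumor_types"]]]][keep], dialect$list_sep,
                     fixed = TRUE)
  tumor_types <- lapply(tt_raw, function(v) {
    v <- canonical_text(v)
    unique(v[nzchar(v)])
  })
  sources <- lapply(keep, function(i) {
    source_df(canonical_text(tab[[cols[["source_title"]]]][i]),
              canonical_text(tab[[cols[["source_doi"]]]][i]), "CGI")
  })

  records <- data.frame(
    drug_name = drug[keep],
    target_id = target$key[keep],
    target_gene = target$gene[keep],
    target_mutation = target$mutation[keep],
    is_wild_type = target$is_wild_type[keep],
    effect = eff_norm[keep],
    evidence_level = ev_canon[keep],
    stringsAsFactors = FALSE
  )
  records$tumor_types <- tumor_types
  records$sources <- sources
  new_ingest_result(records, errors, n)
}

empty_biomarker_records <- function() {
  df <- data.frame(drug_name = character(0), target_id = character(0),
                   target_gene = character(0), target_mutation = character(0),
                   is_wild_type = logical(0), effect = character(0),
                   evidence_level = character(0), stringsAsFactors = FALSE)
  df$tumor_types <- list()
  df$sources <- list()
  df
}

UNIT_TO_NM <- c(nm = 1, um = 1e3, "µm" = 1e3, mm = 1e6, m = 1e9)

#' Parse an in-memory bioactivity table
#'
#' Core of [read_bioactivities()]. Values are parsed honouring the dialect's
#' thousands separator; if a unit column is present, values are converted to
#' nanomolar (accepted units: nM, uM/µM, mM, M). Without a unit column
#' values are assumed to already be nM.
#'
#' @param tab data.frame of character columns.
#' @param dialect a [bioactivity_dialect()].
#' @return an `ingest_result` whose `records` data.frame has columns
#'   `drug_name`, `target_id`, `target_gene`, `target_mutation`,
#'   `is_wild_type`, `measurement_type`, `value_nM` and list column
#'   `sources`.
#' @export
parse_bioactivity_table <- function(tab, dialect = bioactivity_dialect()) {
  cols <- dialect$columns
  required <- unname(cols[setdiff(names(cols), "unit")])
  check_columns(tab, required, "bioactivity")
  n <- nrow(tab)
  if (n == 0L) return(new_ingest_result(empty_bioactivity_records(), empty_errors(), 0L))

  drug <- canonical_text(tab[[cols[["drug"]]]])
  target <- parse_targets(tab[[cols[["target"]]]])
  mtype <- canonical_mtype(tab[[cols[["measurement_type"]]]])

  raw_val <- canonical_text(tab[[cols[["value"]]]])
  if (nzchar(dialect$thousands_sep)) {
    raw_val <- gsub(dialect$thousands_sep, "", raw_val, fixed = TRUE)
  }
  val <- suppressWarnings(as.numeric(raw_val))

  has_unit <- "unit" %in% names(cols) && cols[["unit"]] %in% names(tab)
  if (has_unit) {
    unit <- tolower(canonical_text(tab[[cols[["unit"]]]]))
    unit[!nzchar(unit)] <- "nm"
  } else {
    unit <- rep("nm", n)
  }
  factor_nm <- unname(UNIT_TO_NM[unit])
  value_nM <- val * factor_nm

  err_col <- rep(NA_character_, n)
  err_msg <- rep(NA_character_, n)
  flag <- function(bad, column, msg) {
    sel <- bad & is.na(err_col)
    err_col[sel] <<- column
    err_msg[sel] <<- msg[sel]
  }
  flag(!nzchar(drug), cols[["drug"]], rep("drug name is empty", n))
  flag(!target$ok, cols[["target"]],
       ifelse(nzchar(target$msg), target$msg, "invalid target token"))
  flag(!nzchar(mtype), cols[["measurement_type"]],
       rep("measurement type is empty", n))
  flag(is.na(val), cols[["value"]],
       sprintf("non-numeric activity value '%s'", raw_val))
  flag(is.na(factor_nm), if (has_unit) cols[["unit"]] else "unit",
       sprintf("unsupported unit '%s'; allowed: nM, uM, mM, M", unit))
  flag(!is.na(val) & (val <= 0 | !is.finite(val)), cols[["value"]],
       sprintf("activity value must be positive, got '%s'", raw_val))

  bad <- !is.na(err_col)
  errors <- data.frame(row = which(bad), column = err_col[bad],
                       message = err_msg[bad], stringsAsFactors = FALSE)
  keep <- which(!bad)
  sources <- lapply(keep, function(i) {
    source_df(canonical_text(tab[[cols[["source_title"]]]][i]),
              canonical_text(tab[[cols[["source_doi"]]]][i]), "DTC")
  })

  records <- data.frame(
    drug_name = drug[keep],
    target_id = target$key[keep],
    target_gene = target$gene[keep],
    target_mutation = target$mutation[keep],
    is_wild_type = target$is_wild_type[keep],
    measurement_type = mtype[keep],
    value_nM = value_nM[keep],
    stringsAsFactors = FALSE
  )
  records$sources <- sources
  new_ingest_result(records, errors, n)
}

empty_bioactivity_records <- function() {
  df <- data.frame(drug_name = character(0), target_id = character(0),
                   target_gene = character(0), target_mutation = character(0),
                   is_wild_type = logical(0), measurement_type = character(0),
                   value_nM = numeric(0), stringsAsFactors = FALSE)
  df$sources <- list()
  df
}

# Kd/Ki/IC50 recognized case-insensitively; anything else kept verbatim
# (the measurement-type field is open-ended).
canonical_mtype <- function(x) {
  x <- canonical_text(x)
  known <- c(kd = "Kd", ki = "Ki", ic50 = "IC50")
  hit <- known[tolower(x)]
  ifelse(is.na(hit), x, unname(hit))
}

#' Read a biomarker table from disk
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [biomarker_dialect()].
#' @return an `ingest_result`; see [parse_biomarker_table()].
#' @export
read_biomarkers <- function(path, dialect = biomarker_dialect()) {
  parse_biomarker_table(read_delim_table(path, dialect$sep), dialect)
}

#' Read a bioactivity table from disk
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [bioactivity_dialect()].
#' @return an `ingest_result`; see [parse_bioactivity_table()].
#' @export
read_bioactivities <- function(path, dialect = bioactivity_dialect()) {
  parse_bioactivity_table(read_delim_table(path, dialect$sep), dialect)
}

#' Write an ingest error report as TSV
#'
#' @param result an `ingest_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_error_report <- function(result, path) {
  stopifnot(inherits(result, "ingest_result"))
  utils::write.table(result$errors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
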