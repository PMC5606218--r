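# Entity harmonization: canonical keys for drugs, targets and tumor types.
#
# Matching across the two source tables is purely lexical: trim, collapse
# internal whitespace, case-fold. Display forms preserve the casing of the
# first occurrence. Targets are either a wild-type gene ("ABL1") or a
# mutation ("ABL1(T315I)"); drug combinations such as "DRUG001 + DRUG002"
# are atomic drug entities.

#' Normalize free text (trim and collapse whitespace)
#'
#' @param x character vector.
#' @return character vector with leading/trailing whitespace removed and
#'   internal runs of whitespace collapsed to single spaces.
#' @keywords internal
canonical_text <- function(x) {
  trimws(gsub("[[:space:]]+", " ", as.character(x)))
}

#' Canonical matching key for a drug, target or tumor-type name
#'
#' Drug and tumor keys are the case-folded, whitespace-collapsed form of the
#' name. Target keys are the canonical display form `GENE` (wild type) or
#' `GENE(MUTATION)`, upper-cased.
#'
#' @param x character vector of raw names.
#' @param type one of `"drug"`, `"target"`, `"tumor"`.
#' @return character vector of canonical keys.
#' @examples
#' canonicalize(c(" Axitinib ", "axitinib"), "drug")   # same key twice
#' canonicalize("abl1(t315i)", "target")               # "ABL1(T315I)"
#' @export
canonicalize <- function(x, type = c("drug", "target", "tumor")) {
  type <- match.arg(type)
  switch(type,
    drug  = tolower(canonical_text(x)),
    tumor = tolower(canonical_text(x)),
    target = vapply(x, function(t) parse_target(t)$key, character(1),
                    USE.NAMES = FALSE)
  )
}

#' Parse a target token into its components
#'
#' A target is a wild-type gene symbol (`"ABL1"`) or a gene plus variant in
#' parentheses (`"ABL1(T315I)"`). Gene and mutation are upper-cased; the
#' canonical key is `GENE` or `GENE(MUTATION)`.
#'
#' @param x a single target token.
#' @return a list with elements `gene`, `mutation` (empty string for wild
#'   type), `is_wild_type`, and `key` (canonical display form).
#' @examples
#' parse_target("ABL1(T315I)")
#' parse_target("ABL1")$is_wild_type
#' @export
parse_target <- function(x) {
  txt <- canonical_text(x)
  if (length(txt) != 1L) stop("parse_target() expects a single token", call. = FALSE)
  if (!nzchar(txt)) stop("target token is empty", call. = FALSE)
  m <- regmatches(txt, regexec("^([^()]+)\\(([^()]+)\\)$", txt))[[1]]
  if (length(m) == 3L) {
    gene <- toupper(trimws(m[2]))
    mutation <- toupper(gsub("[[:space:]]+", "", m[3]))
    list(gene = gene, mutation = mutation, is_wild_type = FALSE,
         key = sprintf("%s(%s)", gene, mutation))
  } else if (!grepl("[()]", txt)) {
    gene <- toupper(txt)
    list(gene = gene, mutation = "", is_wild_type = TRUE, key = gene)
  } else {
    stop(sprintf("unparseable target token '%s' (unbalanced parentheses)", txt),
         call. = FALSE)
  }
}

# Vectorized target parsing with per-element error capture; returns a
# data.frame with an `ok` column instead of failing on the first bad token.
parse_targets <- function(x) {
  out <- lapply(x, function(t) {
    tryCatch({
      p <- parse_target(t)
      list(gene = p$gene, mutation = p$mutation,
           is_wild_type = p$is_wild_type, key = p$key, ok = TRUE, msg = "")
    }, error = function(e) {
      list(gene = NA_character_, mutation = NA_character_,
           is_wild_type = NA, key = NA_character_, ok = FALSE,
           msg = conditionMessage(e))
    })
  })
  data.frame(
    gene = vapply(out, `[[`, character(1), "gene"),
    mutation = vapply(out, `[[`, character(1), "mutation"),
    is_wild_type = vapply(out, `[[`, logical(1), "is_wild_type"),
    key = vapply(out, `[[`, character(1), "key"),
    ok = vapply(out, `[[`, logical(1), "ok"),
    msg = vapply(out, `[[`, character(1), "msg"),
    stringsAsFactors = FALSE
  )
}

# Build an entity table (key, display) keeping the display form of the
# first occurrence of each key.
entity_table <- function(keys, displays) {
  keep <- !duplicated(keys) & !is.na(keys)
  df <- data.frame(key = keys[keep], display = displays[keep],
                   stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}
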