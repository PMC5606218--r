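# Potency binning of bioactivity values (nM) and the pActivity transform.

#' Potency levels, weakest to strongest
#'
#' @return character vector of the four potency class labels in increasing
#'   potency order.
#' @export
potency_levels <- function() {
  c("inactive", "weakly_potent", "potent", "highly_potent")
}

#' Classify a bioactivity value into a potency class
#'
#' Bioactivity values (Kd, Ki or IC50, in nanomolar) are binned into four
#' ordinal classes: (0, 10] nM highly potent, (10, 1000] nM potent,
#' (1000, 10000] nM weakly potent, and above 10000 nM inactive. Intervals
#' are left-open/right-closed, so a value exactly on a boundary falls in the
#' more potent class (10 nM is highly potent).
#'
#' @param value_nM numeric vector of positive, finite activity values in nM.
#' @return an ordered factor with levels `inactive < weakly_potent < potent
#'   < highly_potent`. Classification is antitone in the value: larger nM
#'   never yields a more potent class.
#' @examples
#' classify_potency(c(5, 500, 5000, 20000))
#' @export
classify_potency <- function(value_nM) {
  v <- as.numeric(value_nM)
  if (length(v) == 0L) {
    return(factor(character(0), levels = potency_levels(), ordered = TRUE))
  }
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("activity values must be positive, finite numbers (nM)", call. = FALSE)
  }
  lab <- cut(v, breaks = c(0, 10, 1000, 10000, Inf), right = TRUE,
             labels = c("highly_potent", "potent", "weakly_potent", "inactive"))
  factor(as.character(lab), levels = potency_levels(), ordered = TRUE)
}

#' pActivity transform
#'
#' Converts an activity value in nanomolar to `-log10` of the molar value;
#' higher pActivity means more potent (10 nM gives 8, 100 nM gives 7).
#'
#' @param value_nM numeric vector of positive activity values in nM.
#' @return numeric vector of pActivity values.
#' @export
pactivity <- function(value_nM) {
  v <- as.numeric(value_nM)
  if (any(!is.finite(v) | v <= 0)) {
    stop("pactivity() requires positive, finite nM values", call. = FALSE)
  }
  9 - log10(v)
}
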