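# Classed conditions: validation errors (bad data, exit code 2) vs contract
# errors (caller misuse, exit code 3). Format/parse errors are a flavour of
# validation so file-level problems share the same exit path.

abort_validation <- function(msg, class = NULL) {
  stop(errorCondition(msg, class = c(class, "rasmct_validation_error",
                                     "rasmct_error", "error", "condition")))
}

abort_format <- function(msg) {
  abort_validation(msg, class = "rasmct_format_error")
}

abort_contract <- function(msg) {
  stop(errorCondition(msg, class = c("rasmct_contract_error",
                                     "rasmct_error", "error", "condition")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene identifiers
#'
#' Upper-cases and trims whitespace. All identifier comparisons in the
#' package happen after this normalization; no database lookup is performed.
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @keywords internal
normalize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

# Stable key for a sample set, so downstream joins can detect that scores
# were computed on a different cohort (scores are cohort-relative).
sample_key <- function(sample_ids) {
  paste(sort(as.character(sample_ids)), collapse = "|")
}

# Round-half-even at a fixed number of decimals; base round() already uses
# banker's rounding, this wrapper just documents the intent at call sites.
round_even <- function(x, digits) round(x, digits)

stopifnot_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    abort_contract(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
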