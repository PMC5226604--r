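#' KRAS codon 12/13 class from an allele string
#'
#' Collapses the codon-12 activating alleles (G12C/G12D/G12V/...) to the
#' class `G12x`, keeps `G13D` as its own class, and maps `WT` to `WT`. The
#' allele string itself is retained in the [model_table()].
#'
#' @param allele character vector of allele labels (`"WT"`, `"G12D"`, ...).
#' @return character vector over `{WT, G12x, G13D}`.
#' @export
kras_class <- function(allele) {
  allele <- toupper(trimws(as.character(allele)))
  out <- ifelse(allele == "WT", "WT",
         ifelse(grepl("^G12[A-Z]$", allele), "G12x",
         ifelse(allele == "G13D", "G13D", NA_character_)))
  if (anyNA(out))
    abort_validation(sprintf(
      "allele(s) outside the KRAS 12/13 vocabulary: %s",
      paste(unique(allele[is.na(out)]), collapse = ", ")))
  out
}

#' Construct a per-model summary table
#'
#' One record per PDX model joining the signature score, the trial endpoint
#' dT/dC, and KRAS codon 12/13 status. This is the shape of the bundled
#' 25-model reference cohort and the unit of analysis for the association
#' layer.
#'
#' @param df data.frame with columns `model_id`, `ras_score`,
#'   `delta_t_over_delta_c`, `kras_allele`. A `kras_class` column is derived.
#' @return the data.frame with class `model_table`.
#' @export
model_table <- function(df) {
  req <- c("model_id", "ras_score", "delta_t_over_delta_c", "kras_allele")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    abort_format(sprintf("model table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)
  df$model_id <- as.character(df$model_id)
  if (anyDuplicated(df$model_id))
    abort_validation("duplicate model_id in model table")
  df$ras_score <- as.numeric(df$ras_score)
  df$delta_t_over_delta_c <- as.numeric(df$delta_t_over_delta_c)
  if (anyNA(df$ras_score) || anyNA(df$delta_t_over_delta_c))
    abort_validation("model table has missing score or endpoint values")
  df$kras_allele <- toupper(trimws(as.character(df$kras_allele)))
  df$kras_class <- kras_class(df$kras_allele)
  rownames(df) <- NULL
  class(df) <- c("model_table", "data.frame")
  df
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf("Model table: %d PDX models (%d WT / %d KRAS 12/13 mutant)\n",
              nrow(x), sum(x$kras_class == "WT"),
              sum(x$kras_class != "WT")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Load the bundled 25-model cetuximab MCT cohort
#'
#' The package ships the published model-level summary of a cetuximab mouse
#' clinical trial on 25 EGFR-positive colorectal-cancer PDX models: RAS
#' pathway signature score (three decimals), dT/dC (two decimals) and KRAS
#' codon 12/13 status per model, stored exactly as printed (no
#' re-derivation).
#'
#' @return a [model_table()] with 25 records.
#' @examples
#' tbl <- load_cetuximab_mct()
#' nrow(tbl)
#' @export
load_cetuximab_mct <- function() {
  path <- system.file("extdata", "cetuximab_crc_mct_models.csv",
                      package = "rasmct", mustWork = TRUE)
  model_table(read.delim(path, sep = ",", stringsAsFactors = FALSE))
}

#' Read a model-annotation table
#'
#' @param path delimited file with at least `model_id` and `kras_allele`
#'   columns; further columns (e.g. expression or copy-number covariates)
#'   are kept.
#' @return a data.frame with a derived `kras_class` column.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    abort_validation(sprintf("annotation file not found: %s", path))
  df <- read_any_delim(path)
  if (!all(c("model_id", "kras_allele") %in% names(df)))
    abort_format("annotation table needs `model_id` and `kras_allele` columns")
  df$model_id <- as.character(df$model_id)
  if (anyDuplicated(df$model_id))
    abort_validation("duplicate model_id in annotation table")
  df$kras_class <- kras_class(df$kras_allele)
  df
}
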