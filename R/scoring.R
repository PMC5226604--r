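#' Map a signature onto an expression matrix
#'
#' Intersects each direction of the signature with the genes present in the
#' matrix (identifier string matching only — no database lookup) and fills
#' a mapping report with requested/mapped counts and the unmapped lists.
#' With the 147-gene RAS signature against an RNA-seq matrix the reference
#' analysis mapped 97 of 105 Up and 32 of 42 Down genes.
#'
#' @param signature a [gene_signature()].
#' @param matrix an [expression_matrix()].
#' @param platform free-text platform label recorded in the report.
#' @return a `mapped_signature`: fields `name`, `up_mapped`, `down_mapped`,
#'   `report` (class `mapping_report`).
#' @export
map_signature <- function(signature, matrix, platform = "unspecified") {
  stopifnot(inherits(signature, "gene_signature"))
  genes <- rownames(matrix)
  up_mapped <- signature$up[signature$up %in% genes]
  down_mapped <- signature$down[signature$down %in% genes]
  report <- structure(list(
    signature = signature$name,
    platform = platform,
    n_up_requested = length(signature$up),
    n_up_mapped = length(up_mapped),
    n_down_requested = length(signature$down),
    n_down_mapped = length(down_mapped),
    unmapped_up = setdiff(signature$up, up_mapped),
    unmapped_down = setdiff(signature$down, down_mapped)
  ), class = "mapping_report")
  if (length(up_mapped) == 0L || length(down_mapped) == 0L)
    abort_validation(sprintf(
      "scoring impossible: %d Up and %d Down signature genes map to the matrix",
      length(up_mapped), length(down_mapped)))
  structure(list(name = signature$name, up_mapped = up_mapped,
                 down_mapped = down_mapped, report = report),
            class = "mapped_signature")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("Mapping '%s' onto %s: Up %d/%d, Down %d/%d genes mapped\n",
              x$signature, x$platform, x$n_up_mapped, x$n_up_requested,
              x$n_down_mapped, x$n_down_requested))
  invisible(x)
}

#' Z-score normalize genes across samples
#'
#' Centers and scales every gene row to zero mean and unit variance across
#' samples (sample standard deviation, denominator n-1). This is the
#' normalization the signature score is defined on: the axis is per gene,
#' so each gene contributes its relative expression across the cohort.
#' Zero-variance genes cannot be scaled and are dropped with a warning
#' rather than emitted as NaN.
#'
#' @param matrix an [expression_matrix()] with >= 2 samples.
#' @return an [expression_matrix()] with `scale_tag = "zscored"`.
#' @export
zscore_normalize <- function(matrix) {
  if (ncol(matrix) < 2L)
    abort_validation("z-scoring needs >= 2 samples (variance undefined)")
  vals <- unclass(matrix)
  attr(vals, "scale_tag") <- NULL
  sds <- apply(vals, 1L, sd)
  zero_var <- sds == 0
  if (any(zero_var)) {
    warning(sprintf("dropped %d zero-variance gene(s): %s",
                    sum(zero_var),
                    paste(head(rownames(vals)[zero_var], 5L), collapse = ", ")),
            call. = FALSE)
    vals <- vals[!zero_var, , drop = FALSE]
    sds <- sds[!zero_var]
  }
  if (nrow(vals) == 0L)
    abort_validation("no genes left after dropping zero-variance rows")
  z <- (vals - rowMeans(vals)) / sds
  expression_matrix(z, scale_tag = "zscored")
}

#' Score samples with a mapped signature
#'
#' For each sample j the score is
#' `mean(z[up, j]) - mean(z[down, j])` over the mapped gene sets: higher
#' scores indicate stronger pathway activation. The matrix must already be
#' z-scored (contract error otherwise). Mapped genes that were dropped
#' during normalization (zero variance) are excluded; the recorded
#' `n_up_used`/`n_down_used` are the post-drop counts actually averaged.
#'
#' @param matrix a z-scored [expression_matrix()].
#' @param mapped a `mapped_signature` from [map_signature()].
#' @return a `score_table`: data.frame `(sample_id, score)` with a
#'   `provenance` attribute (signature name, genes used, normalization,
#'   sample-set key).
#' @export
score_samples <- function(matrix, mapped) {
  stopifnot(inherits(mapped, "mapped_signature"))
  if (!identical(scale_tag(matrix), "zscored"))
    abort_contract("score_samples requires a z-scored matrix (scale_tag 'zscored')")
  up_use <- intersect(mapped$up_mapped, rownames(matrix))
  down_use <- intersect(mapped$down_mapped, rownames(matrix))
  if (length(up_use) == 0L || length(down_use) == 0L)
    abort_validation("mapped signature genes absent from the normalized matrix")
  vals <- unclass(matrix)
  scores <- colMeans(vals[up_use, , drop = FALSE]) -
    colMeans(vals[down_use, , drop = FALSE])
  out <- data.frame(sample_id = colnames(matrix), score = unname(scores),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(
    signature = mapped$name,
    n_up_used = length(up_use),
    n_down_used = length(down_use),
    normalization = "per-gene z-score (sd denominator n-1)",
    sample_key = sample_key(colnames(matrix)))
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf(
    "Signature scores: %d samples, signature '%s' (%d Up / %d Down genes used)\n",
    nrow(x), prov$signature, prov$n_up_used, prov$n_down_used))
  print.data.frame(x, ...)
  invisible(x)
}

#' Full signature-scoring pipeline
#'
#' Composition [map_signature()] -> restrict to mapped genes ->
#' [zscore_normalize()] -> [score_samples()]. Scores are cohort-relative:
#' adding or removing samples changes every score, because the z-scoring is
#' computed across the cohort. A linear-scale matrix triggers a warning
#' recommending a log transform; the base of the logarithm itself is
#' irrelevant, as z-scoring absorbs any per-gene positive affine transform.
#'
#' @param matrix a raw (non-z-scored) [expression_matrix()].
#' @param signature a [gene_signature()].
#' @param platform platform label passed to [map_signature()].
#' @return list with elements `scores` (`score_table`) and `report`
#'   (`mapping_report`).
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 2, 3, 6, 5, 4), 2, 3, byrow = TRUE,
#'          dimnames = list(c("A", "B"), c("s1", "s2", "s3"))),
#'   scale_tag = "log2")
#' sig <- gene_signature("TOY", up = "A", down = "B")
#' score_pipeline(m, sig)$scores
#' @export
score_pipeline <- function(matrix, signature, platform = "unspecified") {
  if (identical(scale_tag(matrix), "zscored"))
    abort_contract("score_pipeline expects a raw matrix, not a z-scored one")
  if (identical(scale_tag(matrix), "linear"))
    warning("matrix is on a linear scale; a log transform is recommended before scoring",
            call. = FALSE)
  mapped <- map_signature(signature, matrix, platform = platform)
  sub <- unclass(matrix)[c(mapped$up_mapped, mapped$down_mapped), ,
                         drop = FALSE]
  z <- zscore_normalize(expression_matrix(sub, scale_tag = scale_tag(matrix)))
  list(scores = score_samples(z, mapped), report = mapped$report)
}
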