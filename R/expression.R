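#' Construct an expression matrix
#'
#' A genes x samples matrix of log-scale expression values with a scale tag.
#' Row (gene) identifiers are case-normalized; identifiers must be unique on
#' both axes and all values finite — missing values are disallowed at the
#' matrix level (clean upstream with [drop_incomplete_genes()]).
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param scale_tag one of `"log10"`, `"log2"`, `"linear"`, `"zscored"`.
#' @return the matrix with class `expr_matrix` and a `scale_tag` attribute.
#' @export
expression_matrix <- function(values,
                              scale_tag = c("log10", "log2", "linear",
                                            "zscored")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    abort_contract("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    abort_validation("expression matrix must have at least one gene and one sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_validation("expression matrix needs gene rownames and sample colnames")
  rownames(values) <- normalize_gene_ids(rownames(values))
  if (anyDuplicated(rownames(values)))
    abort_validation("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    abort_validation("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(values)))
    abort_validation("expression matrix contains non-finite values; clean with drop_incomplete_genes()")
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(matrix())))
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return the scale tag string.
#' @export
scale_tag <- function(x) attr(x, "scale_tag") %||% "linear"

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), scale_tag(x)))
  invisible(x)
}

#' Drop genes with missing values
#'
#' Cleaning pass applied before matrix construction: removes every gene row
#' containing at least one missing entry, because the signature score has no
#' missing-data rule.
#'
#' @param values numeric matrix possibly containing `NA`/`NaN`.
#' @return the matrix restricted to complete rows; warns when rows drop.
#' @export
drop_incomplete_genes <- function(values) {
  keep <- apply(is.finite(values), 1L, all)
  if (!all(keep))
    warning(sprintf("dropped %d gene(s) with missing values: %s",
                    sum(!keep),
                    paste(head(rownames(values)[!keep], 5L), collapse = ", ")),
            call. = FALSE)
  values[keep, , drop = FALSE]
}

#' Read an expression matrix
#'
#' Accepts plain delimited matrices (first column gene identifiers, header
#' row sample identifiers, tab or comma separated) and the GCT v1.2 dialect
#' (`#1.2` preamble, a dimensions line, and a Description column which is
#' ignored). Duplicate gene rows are resolved by keeping the row with the
#' highest mean, with a warning. Non-numeric cells raise a parse error with
#' their coordinates.
#'
#' @param path file path.
#' @param scale_tag scale the values are on; files carry no scale metadata,
#'   so state it here (default `"log10"`, the usual RNA-seq display scale).
#' @param drop_incomplete if `TRUE`, genes with missing entries are removed
#'   with a warning instead of raising an error.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = "log10",
                            drop_incomplete = FALSE) {
  if (!file.exists(path))
    abort_validation(sprintf("expression file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (identical(trimws(first), "#1.2")) {
    raw <- read_gct_body(path)
  } else {
    df <- read_any_delim(path)
    if (ncol(df) < 2L || nrow(df) == 0L)
      abort_validation(sprintf("empty or degenerate expression matrix: %s", path))
    raw <- list(ids = as.character(df[[1L]]), body = df[-1L])
  }
  body <- raw$body
  num <- as.matrix(as.data.frame(
    lapply(body, function(col) suppressWarnings(as.numeric(col))),
    check.names = FALSE, optional = TRUE))
  # Locate cells that were non-numeric text (not genuinely missing) and
  # report the first few with 1-based data coordinates.
  was_text <- is.na(num) & !is.na(as.matrix(body)) &
    nzchar(trimws(as.matrix(body)))
  if (any(was_text)) {
    idx <- which(was_text, arr.ind = TRUE)[1L, ]
    abort_format(sprintf(
      "non-numeric value '%s' at gene row %d, sample column %d (%s)",
      as.matrix(body)[idx[1L], idx[2L]], idx[1L], idx[2L],
      colnames(body)[idx[2L]]))
  }
  rownames(num) <- normalize_gene_ids(raw$ids)
  num <- resolve_duplicate_genes(num)
  if (anyNA(num)) {
    if (!drop_incomplete) {
      idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
      abort_format(sprintf(
        "missing value at gene %s, sample %s; re-read with drop_incomplete = TRUE to drop such genes",
        rownames(num)[idx[1L]], colnames(num)[idx[2L]]))
    }
    num <- drop_incomplete_genes(num)
  }
  expression_matrix(num, scale_tag = scale_tag)
}

read_gct_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort_format("GCT file truncated")
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    abort_format("GCT dimensions line must give <ngenes>\t<nsamples>")
  df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) abort_format("GCT body needs Name, Description and data columns")
  body <- df[-(1:2)]  # drop Name + Description
  if (nrow(df) != dims[1L] || ncol(body) != dims[2L])
    abort_format(sprintf(
      "GCT declares %d x %d but body is %d x %d",
      dims[1L], dims[2L], nrow(df), ncol(body)))
  list(ids = as.character(df[[1L]]), body = body)
}

resolve_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  ids <- rownames(mat)
  means <- rowMeans(mat, na.rm = TRUE)
  # within each duplicated identifier keep the highest-mean row
  keep <- unlist(lapply(split(seq_len(nrow(mat)), ids), function(rows) {
    rows[which.max(means[rows])]
  }), use.names = FALSE)
  dropped <- nrow(mat) - length(keep)
  warning(sprintf(
    "%d duplicate gene row(s) resolved by keeping the highest-mean row",
    dropped), call. = FALSE)
  mat[sort(keep), , drop = FALSE]
}

#' Write an expression matrix
#'
#' Writes a tab-separated matrix (gene identifiers in the first column) at
#' 17 significant digits so that reading the file back reproduces the
#' doubles exactly.
#'
#' @param x an [expression_matrix()] or plain numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  vals <- formatC(unclass(x), digits = 17, format = "g")
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], vals[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
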