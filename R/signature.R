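#' Construct a gene signature
#'
#' A signature is a pair of disjoint gene-identifier sets: genes expected to
#' go up with pathway activation and genes expected to go down. The RAS
#' pathway signature used throughout the package documentation has 105 Up
#' and 42 Down genes. Identifiers are case-normalized to upper case;
#' duplicates within a direction are collapsed with a warning.
#'
#' @param name signature name (single string).
#' @param up character vector of up-regulated gene identifiers.
#' @param down character vector of down-regulated gene identifiers.
#' @return an object of class `gene_signature` with fields `name`, `up`,
#'   `down`.
#' @examples
#' sig <- gene_signature("TOY", c("A", "B"), "C")
#' sig$up
#' @export
gene_signature <- function(name, up, down) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_contract("`name` must be a non-empty string")
  up <- normalize_gene_ids(up)
  down <- normalize_gene_ids(down)
  up <- up[nzchar(up)]
  down <- down[nzchar(down)]
  if (anyDuplicated(up)) {
    warning(sprintf("signature '%s': %d duplicate Up identifiers collapsed",
                    name, sum(duplicated(up))), call. = FALSE)
    up <- unique(up)
  }
  if (anyDuplicated(down)) {
    warning(sprintf("signature '%s': %d duplicate Down identifiers collapsed",
                    name, sum(duplicated(down))), call. = FALSE)
    down <- unique(down)
  }
  if (length(up) == 0L || length(down) == 0L)
    abort_validation("both Up and Down sets must be non-empty")
  both <- intersect(up, down)
  if (length(both) > 0L)
    abort_validation(sprintf(
      "gene(s) present in both directions: %s",
      paste(both, collapse = ", ")))
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s': %d Up / %d Down genes\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Read a gene signature from disk
#'
#' Two dialects are supported. `"gmt"` expects exactly one record named
#' `<name>_UP` and one named `<name>_DN` (tab-separated: set name,
#' description, then gene identifiers), following the gene-set-enrichment
#' convention for directional signatures. `"two_column"` expects a delimited
#' file with header `gene,direction` and `direction` in `{up, down}`.
#'
#' @param path file path.
#' @param format `"gmt"` or `"two_column"`.
#' @return a [gene_signature()].
#' @export
read_signature <- function(path, format = c("gmt", "two_column")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort_validation(sprintf("signature file not found: %s", path))
  if (format == "gmt") read_signature_gmt(path) else read_signature_2col(path)
}

read_signature_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_format(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  set_names <- vapply(fields, `[`, character(1), 1L)
  is_up <- grepl("_UP$", set_names, ignore.case = TRUE)
  is_dn <- grepl("_DN$", set_names, ignore.case = TRUE)
  if (sum(is_up) != 1L || sum(is_dn) != 1L)
    abort_format(sprintf(
      "GMT file must contain exactly one *_UP and one *_DN record (found %d/%d)",
      sum(is_up), sum(is_dn)))
  up_rec <- fields[[which(is_up)]]
  dn_rec <- fields[[which(is_dn)]]
  if (length(up_rec) < 3L || length(dn_rec) < 3L)
    abort_format("GMT records need a name, a description and at least one gene")
  name <- sub("_UP$", "", up_rec[1L], ignore.case = TRUE)
  gene_signature(name, up = up_rec[-(1:2)], down = dn_rec[-(1:2)])
}

read_signature_2col <- function(path) {
  df <- read_any_delim(path)
  names(df) <- tolower(names(df))
  if (!all(c("gene", "direction") %in% names(df)))
    abort_format("two_column signature file needs header `gene,direction`")
  dir <- tolower(trimws(df$direction))
  bad <- setdiff(unique(dir), c("up", "down"))
  if (length(bad) > 0L)
    abort_format(sprintf("unknown direction value(s): %s",
                         paste(bad, collapse = ", ")))
  name <- sub("\\.[^.]*$", "", basename(path))
  gene_signature(name, up = df$gene[dir == "up"], down = df$gene[dir == "down"])
}

#' Write a gene signature
#'
#' Inverse of [read_signature()]; both dialects round-trip.
#'
#' @param signature a [gene_signature()].
#' @param path output file path.
#' @param format `"gmt"` or `"two_column"`.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path, format = c("gmt", "two_column")) {
  format <- match.arg(format)
  stopifnot(inherits(signature, "gene_signature"))
  if (format == "gmt") {
    lines <- c(
      paste(c(paste0(signature$name, "_UP"), "up-regulated", signature$up),
            collapse = "\t"),
      paste(c(paste0(signature$name, "_DN"), "down-regulated", signature$down),
            collapse = "\t"))
    writeLines(lines, path)
  } else {
    df <- data.frame(
      gene = c(signature$up, signature$down),
      direction = rep(c("up", "down"),
                      c(length(signature$up), length(signature$down))))
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Sniff comma vs tab from the header line, then read as data.frame.
read_any_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}
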