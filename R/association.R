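association_result <- function(subgroup, n, statistic_name, statistic,
                               p_value, df) {
  structure(list(subgroup = subgroup, n = n,
                 statistic_name = statistic_name, statistic = statistic,
                 p_value = p_value, df = df),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  lab <- if (x$statistic_name == "pearson_r") "r" else "t"
  cat(sprintf("%s (n = %d): %s = %.4f, two-sided p = %.4g (df = %.2f)\n",
              x$subgroup, x$n, lab, x$statistic, x$p_value, x$df))
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(subgroup = x$subgroup, n = x$n,
             statistic_name = x$statistic_name, statistic = x$statistic,
             p_value = x$p_value, df = x$df, stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Implemented directly from the moment formula
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`
#' with the p-value from `t = r sqrt((n - 2) / (1 - r^2))` against a
#' Student t distribution on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, neither constant.
#' @param subgroup label recorded in the result.
#' @return an `association_result` with `statistic_name = "pearson_r"`.
#' @export
pearson <- function(x, y, subgroup = "all") {
  if (length(x) != length(y))
    abort_contract("pearson: vectors must have equal length")
  n <- length(x)
  if (n < 3L) abort_contract("pearson requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_contract("pearson: non-finite input")
  dx <- x - mean(x)
  dy <- y - mean(y)
  ssx <- sum(dx^2)
  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0)
    abort_validation("correlation undefined for a constant vector")
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  df <- n - 2
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t_stat), df)
  }
  association_result(subgroup, n, "pearson_r", r, p, df)
}

#' Welch's two-sample t-test
#'
#' Location test without the equal-variance assumption:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided Student-t
#' p-value. Implemented from the formulas; `stats::t.test` serves as an
#' independent cross-check in the test suite only.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param subgroup label recorded in the result.
#' @return an `association_result` with `statistic_name = "welch_t"`.
#' @export
welch_t_test <- function(a, b, subgroup = "all") {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    abort_contract("welch_t_test requires >= 2 observations per group")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    abort_contract("welch_t_test: non-finite input")
  va <- var(a) / na
  vb <- var(b) / nb
  se2 <- va + vb
  if (se2 == 0)
    abort_validation("both groups constant and equal; t undefined")
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  association_result(subgroup, na + nb, "welch_t", t_stat, p, df)
}

# Default stratification: all models / KRAS 12/13 wild type / mutants
# (G12x and G13D combined).
kras_strata <- function(table) {
  list(all = rep(TRUE, nrow(table)),
       WT = table$kras_class == "WT",
       mutant = table$kras_class != "WT")
}

resolve_strata <- function(table, strata) {
  if (is.character(strata) && length(strata) == 1L) {
    if (strata == "kras") return(kras_strata(table))
    if (strata == "kras_fine")
      return(list(all = rep(TRUE, nrow(table)),
                  WT = table$kras_class == "WT",
                  G12x = table$kras_class == "G12x",
                  G13D = table$kras_class == "G13D"))
    if (strata == "none") return(list(all = rep(TRUE, nrow(table))))
    abort_contract(sprintf("unknown strata rule '%s'", strata))
  }
  if (is.list(strata) && !is.null(names(strata)) &&
      all(vapply(strata, is.logical, logical(1))))
    return(strata)
  abort_contract("`strata` must be a rule name or a named list of logical masks")
}

#' Genotype-stratified score-response correlation
#'
#' Runs [pearson()] of signature score against dT/dC within each stratum.
#' The default rule reproduces the reference analysis: all models, KRAS
#' 12/13 wild types, and mutants (codon 12 and 13 combined). Strata too
#' small for a correlation (n < 3) or with a constant variable are skipped
#' with a warning.
#'
#' @param table a [model_table()].
#' @param strata `"kras"` (default), `"kras_fine"`, `"none"`, or a named
#'   list of logical row masks.
#' @return data.frame of association results, one row per stratum kept.
#' @examples
#' stratified_association(load_cetuximab_mct())
#' @export
stratified_association <- function(table, strata = "kras") {
  stopifnot(inherits(table, "model_table"))
  masks <- resolve_strata(table, strata)
  rows <- lapply(names(masks), function(nm) {
    keep <- masks[[nm]]
    if (sum(keep) < 3L) {
      warning(sprintf("stratum '%s' skipped: n = %d < 3", nm, sum(keep)),
              call. = FALSE)
      return(NULL)
    }
    res <- tryCatch(
      pearson(table$ras_score[keep], table$delta_t_over_delta_c[keep],
              subgroup = nm),
      rasmct_validation_error = function(e) {
        warning(sprintf("stratum '%s' skipped: %s", nm, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) NULL else as.data.frame(res)
  })
  do.call(rbind, rows)
}

#' Sign-based score x response contingency counts
#'
#' Within each stratum, cross-classifies models by whether the signature
#' score exceeds `score_threshold` (strictly) and whether dT/dC exceeds
#' `response_threshold` (strictly; above = poor response). Boundary values
#' fall in the non-positive / sensitive margins, which matters because the
#' reference cohort contains a model with dT/dC = 0.01.
#'
#' @param table a [model_table()].
#' @param score_threshold,response_threshold classification cuts (default 0).
#' @param strata stratification rule, as in [stratified_association()].
#' @return a `sign_contingency`: per-stratum 2x2 count matrices
#'   (`score_positive`/`score_non_positive` x `poor`/`sensitive`) plus the
#'   thresholds used.
#' @export
sign_contingency <- function(table, score_threshold = 0,
                             response_threshold = 0, strata = "kras") {
  stopifnot(inherits(table, "model_table"))
  stopifnot_scalar_number(score_threshold, "score_threshold")
  stopifnot_scalar_number(response_threshold, "response_threshold")
  masks <- resolve_strata(table, strata)
  tabs <- lapply(masks, function(keep) {
    sub <- table[keep, , drop = FALSE]
    pos <- sub$ras_score > score_threshold
    poor <- sub$delta_t_over_delta_c > response_threshold
    m <- matrix(c(sum(pos & poor), sum(pos & !poor),
                  sum(!pos & poor), sum(!pos & !poor)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(score = c("score_positive",
                                          "score_non_positive"),
                                response = c("poor", "sensitive")))
    m
  })
  structure(list(tables = tabs,
                 score_threshold = score_threshold,
                 response_threshold = response_threshold),
            class = "sign_contingency")
}

#' @export
print.sign_contingency <- function(x, ...) {
  cat(sprintf("Sign contingency (score > %g vs dT/dC > %g):\n",
              x$score_threshold, x$response_threshold))
  for (nm in names(x$tables)) {
    cat(sprintf("-- %s (n = %d)\n", nm, sum(x$tables[[nm]])))
    print(x$tables[[nm]])
  }
  invisible(x)
}

#' Single-covariate response screen
#'
#' Correlates each numeric covariate column (e.g. log expression or copy
#' number of candidate genes) against dT/dC with [pearson()], reporting raw
#' p-values alongside Benjamini-Hochberg adjusted ones. The reference
#' analysis applied no multiplicity adjustment, so the raw column
#' reproduces it while the adjusted column keeps the screen defensible.
#' Constant covariates are flagged and skipped.
#'
#' @param table a [model_table()] whose extra columns hold the covariates.
#' @param covariates character vector of covariate column names.
#' @return data.frame `(covariate, n, r, p_value, p_bh)`.
#' @export
covariate_screen <- function(table, covariates) {
  stopifnot(inherits(table, "model_table"))
  missing_cols <- setdiff(covariates, names(table))
  if (length(missing_cols) > 0L)
    abort_contract(sprintf("covariate column(s) absent: %s",
                           paste(missing_cols, collapse = ", ")))
  rows <- lapply(covariates, function(cv) {
    x <- table[[cv]]
    if (!is.numeric(x) || anyNA(x))
      abort_validation(sprintf("covariate '%s' must be numeric and complete", cv))
    res <- tryCatch(pearson(x, table$delta_t_over_delta_c, subgroup = cv),
                    rasmct_validation_error = function(e) {
                      warning(sprintf("covariate '%s' skipped: %s",
                                      cv, conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) NULL
    else data.frame(covariate = cv, n = res$n, r = res$statistic,
                    p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
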