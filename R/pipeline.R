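# Reference statistics reported for the bundled 25-model cetuximab MCT
# cohort, with the number of decimals each was printed at. Used only to
# flag agreement in the reproduction report; every computed value comes
# from the fixture at run time.
reference_statistics <- function() {
  list(
    all_r      = list(value = 0.59,   digits = 2L),
    all_p      = list(value = 0.0018, digits = 4L),
    wt_r       = list(value = 0.69,   digits = 2L),
    wt_p       = list(value = 0.004,  digits = 3L),
    mutant_r   = list(value = 0.62,   digits = 2L),
    mutant_p   = list(value = 0.05,   digits = 2L),
    welch_p    = list(value = 0.34,   digits = 2L),
    wt_score_pos_poor = list(value = 6, digits = 0L),
    mutant_score_neg  = list(value = 4, digits = 0L))
}

# Association + contingency + waterfall layer shared by the reproduction
# report and the full pipeline.
analyze_model_table <- function(table, score_threshold = 0,
                                response_threshold = 0, strata = "kras") {
  assoc <- stratified_association(table, strata = strata)
  welch <- welch_t_test(table$ras_score[table$kras_class == "WT"],
                        table$ras_score[table$kras_class != "WT"],
                        subgroup = "WT_vs_mutant")
  counts <- sign_contingency(table, score_threshold = score_threshold,
                             response_threshold = response_threshold,
                             strata = strata)
  list(association = assoc, welch = welch, counts = counts,
       waterfall = waterfall(table))
}

#' Reproduce the reference cohort analysis
#'
#' Recomputes, from the bundled 25-model table alone, every headline
#' statistic of the reference cetuximab MCT analysis: the score-response
#' Pearson correlations (all models, KRAS 12/13 wild types, mutants) with
#' t-based p-values, the Welch test comparing scores between genotypes, the
#' sign-based 6-of-15 / 4-of-10 counts, and the waterfall ordering. Each
#' entry is paired with the reference value and a match flag computed by
#' round-half-even at the reference's printed precision. Runs in
#' milliseconds with no network access.
#'
#' @return an object of class `mct_reproduction`: list with `table` (the
#'   quantity/computed/reference/match data.frame), `waterfall` (ordered
#'   model table) and the underlying `analysis`.
#' @examples
#' rep <- reproduce_reference_analysis()
#' rep$table
#' @export
reproduce_reference_analysis <- function() {
  tbl <- load_cetuximab_mct()
  an <- analyze_model_table(tbl)
  a <- an$association
  get <- function(sub, col) a[a$subgroup == sub, col]
  wt_tab <- an$counts$tables$WT
  mut <- tbl[tbl$kras_class != "WT", ]
  computed <- c(
    all_r = get("all", "statistic"), all_p = get("all", "p_value"),
    wt_r = get("WT", "statistic"),   wt_p = get("WT", "p_value"),
    mutant_r = get("mutant", "statistic"),
    mutant_p = get("mutant", "p_value"),
    welch_p = an$welch$p_value,
    wt_score_pos_poor = wt_tab["score_positive", "poor"],
    mutant_score_neg = sum(mut$ras_score < 0))
  ref <- reference_statistics()
  out <- data.frame(
    quantity = names(ref),
    computed = unname(computed[names(ref)]),
    reference = vapply(ref, `[[`, numeric(1), "value"),
    digits = vapply(ref, `[[`, integer(1), "digits"),
    stringsAsFactors = FALSE)
  out$match <- round_even(out$computed, out$digits) == out$reference
  rownames(out) <- NULL
  structure(list(table = out, waterfall = an$waterfall, analysis = an),
            class = "mct_reproduction")
}

#' @export
print.mct_reproduction <- function(x, ...) {
  cat("Reference-cohort reproduction (computed from the bundled table):\n")
  print.data.frame(x$table, digits = 4)
  cat(sprintf("Waterfall: %s (%.2f) ... %s (%.2f)\n",
              x$waterfall$model_id[1L],
              x$waterfall$delta_t_over_delta_c[1L],
              tail(x$waterfall$model_id, 1L),
              tail(x$waterfall$delta_t_over_delta_c, 1L)))
  invisible(x)
}

#' Run the full scoring-to-association pipeline
#'
#' Composes the stages on user data: signature scoring of the expression
#' matrix, endpoint computation from volumes (or an endpoint column already
#' present in the annotations), the join into a model table, and the
#' stratified association layer. Matrix samples and annotation models must
#' coincide; orphans on either side raise a join error listing them.
#'
#' @param matrix an [expression_matrix()] (one sample per PDX model).
#' @param signature a [gene_signature()].
#' @param annotations data.frame with `model_id`, `kras_allele`, and —
#'   when `volumes` is `NULL` — a `delta_t_over_delta_c` column.
#' @param volumes optional [volume_series()] from which endpoints are
#'   computed at `evaluation_day`.
#' @param evaluation_day passed to [compute_endpoints()].
#' @param score_threshold,response_threshold cuts for [sign_contingency()].
#' @param strata stratification rule (see [stratified_association()]).
#' @return an object of class `mct_report`: list with `model_table`,
#'   `association`, `welch`, `counts`, `waterfall`, `mapping_report`,
#'   `provenance`.
#' @export
run_pipeline <- function(matrix, signature, annotations, volumes = NULL,
                         evaluation_day = NULL, score_threshold = 0,
                         response_threshold = 0, strata = "kras") {
  scored <- score_pipeline(matrix, signature)
  scores <- scored$scores
  if (!all(c("model_id", "kras_allele") %in% names(annotations)))
    abort_format("annotations need `model_id` and `kras_allele` columns")
  annotations$model_id <- as.character(annotations$model_id)
  orphans_m <- setdiff(scores$sample_id, annotations$model_id)
  orphans_a <- setdiff(annotations$model_id, scores$sample_id)
  if (length(orphans_m) > 0L || length(orphans_a) > 0L)
    abort_validation(sprintf(
      "sample/annotation mismatch; matrix-only: [%s], annotation-only: [%s]",
      paste(orphans_m, collapse = ", "),
      paste(orphans_a, collapse = ", ")))
  if (!is.null(volumes)) {
    ep <- compute_endpoints(volumes, evaluation_day = evaluation_day)
    missing_ep <- setdiff(scores$sample_id, ep$model_id)
    if (length(missing_ep) > 0L)
      abort_validation(sprintf("no volume records for model(s): %s",
                               paste(missing_ep, collapse = ", ")))
    response <- ep$delta_t_over_delta_c[match(scores$sample_id, ep$model_id)]
  } else {
    if (!"delta_t_over_delta_c" %in% names(annotations))
      abort_format("annotations must carry `delta_t_over_delta_c` when no volumes are given")
    response <- annotations$delta_t_over_delta_c[
      match(scores$sample_id, annotations$model_id)]
  }
  tbl <- model_table(data.frame(
    model_id = scores$sample_id,
    ras_score = scores$score,
    delta_t_over_delta_c = response,
    kras_allele = annotations$kras_allele[
      match(scores$sample_id, annotations$model_id)],
    stringsAsFactors = FALSE))
  an <- analyze_model_table(tbl, score_threshold = score_threshold,
                            response_threshold = response_threshold,
                            strata = strata)
  structure(list(model_table = tbl, association = an$association,
                 welch = an$welch, counts = an$counts,
                 waterfall = an$waterfall,
                 mapping_report = scored$report,
                 provenance = list(
                   score = attr(scores, "provenance"),
                   score_threshold = score_threshold,
                   response_threshold = response_threshold,
                   evaluation_day = evaluation_day,
                   endpoint_source = if (is.null(volumes)) "annotations"
                                     else "volumes")),
            class = "mct_report")
}

#' @export
print.mct_report <- function(x, ...) {
  cat(sprintf("MCT pipeline report: %d models\n", nrow(x$model_table)))
  print(x$mapping_report)
  cat("\nStratified score-response association:\n")
  print.data.frame(x$association, digits = 4)
  cat("\nGenotype Welch test on scores: ")
  print(x$welch)
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Flatten a pipeline or reproduction report to a plain list
#'
#' Gives a structure directly serializable to JSON/YAML by callers (the
#' bundled command-line wrapper uses it).
#'
#' @param report an `mct_report` or `mct_reproduction`.
#' @return a nested list of plain vectors.
#' @export
report_to_list <- function(report) {
  if (inherits(report, "mct_reproduction")) {
    return(list(statistics = report$table,
                waterfall = report$waterfall$model_id))
  }
  stopifnot(inherits(report, "mct_report"))
  list(n_models = nrow(report$model_table),
       association = report$association,
       welch = unclass(report$welch)[c("subgroup", "n", "statistic",
                                       "p_value", "df")],
       counts = lapply(report$counts$tables, function(m)
         as.list(setNames(as.vector(m), outer(rownames(m), colnames(m),
                                              paste, sep = ".")))),
       waterfall = report$waterfall$model_id,
       mapping = unclass(report$mapping_report),
       provenance = report$provenance)
}
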