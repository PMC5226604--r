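#' Tumor growth inhibition endpoint dT/dC for one model
#'
#' The mouse-clinical-trial endpoint: dT is the mean over treated animals of
#' the volume change from baseline to the evaluation day, dC likewise for
#' controls, and the endpoint is their ratio. Negative values indicate mean
#' regression of treated tumors while controls grow; values above 1 indicate
#' faster-than-control growth. The default evaluation day is the last day
#' measured in both arms of the model.
#'
#' @param volumes a [volume_series()].
#' @param model_id model to evaluate.
#' @param evaluation_day day at which to read the endpoint; `NULL` picks the
#'   last common measurement day across both arms.
#' @return an `endpoint_result`: list with `model_id`, `delta_t`, `delta_c`,
#'   `delta_t_over_delta_c`, `n_treated`, `n_control`, `evaluation_day`.
#' @export
compute_delta_t_delta_c <- function(volumes, model_id, evaluation_day = NULL) {
  stopifnot(inherits(volumes, "volume_series"))
  v <- volumes[volumes$model == model_id, , drop = FALSE]
  if (nrow(v) == 0L)
    abort_validation(sprintf("no volume records for model %s", model_id))
  if (!all(c("control", "treated") %in% v$arm))
    abort_validation(sprintf("model %s lacks one of the two arms", model_id))
  if (is.null(evaluation_day)) {
    common <- intersect(v$day[v$arm == "control"], v$day[v$arm == "treated"])
    evaluation_day <- max(common)
  }
  evaluation_day <- as.integer(evaluation_day)
  if (evaluation_day <= 0L)
    abort_contract("evaluation_day must be a positive day")
  arm_change <- function(arm) {
    a <- v[v$arm == arm, , drop = FALSE]
    animals <- unique(a$animal)
    end <- a[a$day == evaluation_day, , drop = FALSE]
    missing <- setdiff(animals, end$animal)
    if (length(missing) > 0L)
      abort_validation(sprintf(
        "model %s: animal(s) without a day-%d record: %s",
        model_id, evaluation_day, paste(missing, collapse = ", ")))
    base <- a[a$day == 0L, , drop = FALSE]
    end$volume[match(animals, end$animal)] -
      base$volume[match(animals, base$animal)]
  }
  dT <- mean(arm_change("treated"))
  dC <- mean(arm_change("control"))
  if (dC <= 0)
    abort_validation(sprintf(
      "model %s: control arm failed to grow (dC = %.3g); endpoint undefined",
      model_id, dC))
  structure(list(
    model_id = model_id, delta_t = dT, delta_c = dC,
    delta_t_over_delta_c = dT / dC,
    n_treated = length(unique(v$animal[v$arm == "treated"])),
    n_control = length(unique(v$animal[v$arm == "control"])),
    evaluation_day = evaluation_day
  ), class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf(
    "%s: dT/dC = %.3f (dT %.1f / dC %.1f mm^3 at day %d; n = %d treated, %d control)\n",
    x$model_id, x$delta_t_over_delta_c, x$delta_t, x$delta_c,
    x$evaluation_day, x$n_treated, x$n_control))
  invisible(x)
}

#' Endpoints for every model in a volume series
#'
#' @inheritParams compute_delta_t_delta_c
#' @return data.frame with one row per model (fields of `endpoint_result`).
#' @export
compute_endpoints <- function(volumes, evaluation_day = NULL) {
  stopifnot(inherits(volumes, "volume_series"))
  rows <- lapply(sort(unique(volumes$model)), function(m) {
    as.data.frame(unclass(
      compute_delta_t_delta_c(volumes, m, evaluation_day)))
  })
  do.call(rbind, rows)
}

#' Waterfall-order a response table
#'
#' Sorts models ascending by dT/dC, so the strongest responders (most
#' negative values, tumor regression) come first; ties break
#' lexicographically on `model_id`.
#'
#' @param results a data.frame carrying `model_id` and
#'   `delta_t_over_delta_c` columns (a [model_table()], the output of
#'   [compute_endpoints()], or a list of `endpoint_result`s).
#' @return the input rows reordered, plus a `rank` column.
#' @export
waterfall <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "endpoint_result"))) {
    results <- do.call(rbind, lapply(results, function(r)
      as.data.frame(unclass(r))))
  }
  if (!all(c("model_id", "delta_t_over_delta_c") %in% names(results)))
    abort_contract("waterfall needs `model_id` and `delta_t_over_delta_c` columns")
  if (nrow(results) == 0L) abort_contract("waterfall needs >= 1 result")
  ord <- order(results$delta_t_over_delta_c, results$model_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify a model response
#'
#' Sign-based reading of the endpoint: a model responds when its dT/dC is
#' strictly below the threshold. The default threshold 0 calls tumor
#' regression a response; the boundary value itself is a non-response.
#'
#' @param delta_t_over_delta_c endpoint value(s), or an `endpoint_result`.
#' @param threshold classification cut (default 0).
#' @return character vector over `{responder, non_responder}`.
#' @export
classify_response <- function(delta_t_over_delta_c, threshold = 0) {
  if (inherits(delta_t_over_delta_c, "endpoint_result"))
    delta_t_over_delta_c <- delta_t_over_delta_c$delta_t_over_delta_c
  stopifnot_scalar_number(threshold, "threshold")
  if (any(!is.finite(delta_t_over_delta_c)))
    abort_contract("non-finite endpoint value")
  ifelse(delta_t_over_delta_c < threshold, "responder", "non_responder")
}
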