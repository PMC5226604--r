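#' Waterfall plot of model responses
#'
#' Bar chart of dT/dC sorted from best responder (most negative, left) to
#' worst (right), shaded by KRAS codon 12/13 class when available: open
#' bars for wild type, solid for G12x, gray for G13D.
#'
#' @param table a [model_table()] or [compute_endpoints()] output.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return the ordered table, invisibly.
#' @export
plot_waterfall <- function(table, ...) {
  wf <- waterfall(table)
  shade <- if ("kras_class" %in% names(wf)) {
    c(WT = "white", G12x = "black", G13D = gray(0.6))[wf$kras_class]
  } else "gray"
  barplot(wf$delta_t_over_delta_c, names.arg = wf$model_id, las = 2,
          col = shade, ylab = expression(Delta * T / Delta * C),
          cex.names = 0.7, ...)
  abline(h = 0)
  if ("kras_class" %in% names(wf))
    legend("topleft", fill = c("white", "black", gray(0.6)),
           legend = c("KRAS WT", "KRAS G12x", "KRAS G13D"), bty = "n")
  invisible(wf)
}

#' Score-response scatter plot
#'
#' Signature score against dT/dC, optionally restricted to one genotype
#' stratum, with the fitted least-squares line and the Pearson r in the
#' title.
#'
#' @param table a [model_table()].
#' @param stratum `"all"`, `"WT"` or `"mutant"`.
#' @param ... further arguments passed to [plot()].
#' @return the `association_result` for the stratum, invisibly.
#' @export
plot_score_response <- function(table, stratum = "all", ...) {
  stopifnot(inherits(table, "model_table"))
  keep <- resolve_strata(table, "kras")[[stratum]]
  if (is.null(keep)) abort_contract(sprintf("unknown stratum '%s'", stratum))
  x <- table$ras_score[keep]
  y <- table$delta_t_over_delta_c[keep]
  res <- pearson(x, y, subgroup = stratum)
  plot(x, y, xlab = "RAS signature score",
       ylab = expression(Delta * T / Delta * C),
       main = sprintf("%s: r = %.2f, p = %.3g", stratum, res$statistic,
                      res$p_value), ...)
  abline(stats::lm(y ~ x), lty = 2)
  invisible(res)
}
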