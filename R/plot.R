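#' Plot counterfactual survival curves
#'
#' Step-function plot of the "always treated" and "never treated"
#' standardized survival curves of an estimate, optionally overlaying a
#' truth curve.
#'
#' @param x an \code{st_estimate}.
#' @param truth optional \code{truth_curves} to overlay (dashed).
#' @param ... further arguments passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
plot.st_estimate <- function(x, truth = NULL, ...) {
  plot(x$curve1$t, x$curve1$S, type = "s", col = "firebrick", lwd = 2,
       ylim = c(0, 1), xlab = "time since time zero",
       ylab = "counterfactual survival",
       main = if (x$method == "msm_iptw") "MSM-IPTW" else "Sequential trials",
       ...)
  graphics::lines(x$curve0$t, x$curve0$S, type = "s", col = "navy", lwd = 2)
  if (!is.null(truth)) {
    graphics::lines(truth$t, truth$S1, lty = 2, col = "firebrick")
    graphics::lines(truth$t, truth$S0, lty = 2, col = "navy")
  }
  graphics::legend("bottomleft", bty = "n", lwd = 2, col = c("firebrick", "navy"),
                   legend = c("always treated", "never treated"))
  invisible(x)
}

#' Plot per-replicate largest weights by period
#'
#' Boxplots of the largest weight per time period across study replicates,
#' one panel per method — the diagnostic surface for comparing how extreme
#' the IPTW become relative to the IPACW over follow-up.
#'
#' @param study an \code{st_study}.
#' @param log use a log weight axis (default TRUE).
#' @return invisibly, the reshaped data.frame.
#' @export
plot_max_weights <- function(study, log = TRUE) {
  mw <- max_weight_summary(study)
  methods <- unique(mw$method)
  op <- graphics::par(mfrow = c(1, length(methods)))
  on.exit(graphics::par(op))
  for (m in methods) {
    d <- mw[mw$method == m, ]
    graphics::boxplot(max_weight ~ period, data = d,
                      log = if (log) "y" else "",
                      xlab = "time period", ylab = "largest weight",
                      main = if (m == "msm_iptw") "IPTW" else "IPACW")
  }
  invisible(mw)
}
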