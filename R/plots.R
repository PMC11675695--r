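#' Plot information or IFTI curves
#'
#' Base-graphics curve plots in the style used for Heywood-case screening:
#' one line per item, with an optional highlight list drawn bold and the
#' relevant thresholds as dashed horizontal lines.
#'
#' @param x an `info_curves` or `ifti_curves` object.
#' @param highlight character vector of item labels drawn bold.
#' @param thresholds for IFTI plots, a [heywood_thresholds()] whose 2/J and
#'   4/J cuts are drawn; for information plots the peak-information cut.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.info_curves <- function(x, highlight = character(0),
                             thresholds = heywood_thresholds(), ...) {
  plot_curves(as.numeric(x$theta), x$info, x$labels, highlight,
              ylab = expression(I(theta)), hline = thresholds$info_cut, ...)
}

#' @rdname plot.info_curves
#' @export
plot.ifti_curves <- function(x, highlight = character(0),
                             thresholds = heywood_thresholds(), ...) {
  hl <- if (x$scale_J) c(thresholds$ifti_troublesome, thresholds$ifti_problematic)
        else c(thresholds$ifti_troublesome, thresholds$ifti_problematic) / x$J
  plot_curves(as.numeric(x$theta), x$ifti, x$labels, highlight,
              ylab = if (x$scale_J) "IFTI x J" else expression(IFTI(theta)),
              hline = hl, ...)
}

plot_curves <- function(theta, mat, labels, highlight, ylab, hline = NULL, ...) {
  hi <- labels %in% highlight
  pal <- grDevices::hcl.colors(max(sum(hi), 1L), "Dark 3")
  col <- rep("grey55", length(labels))
  lwd <- rep(1, length(labels))
  if (any(hi)) { col[hi] <- pal[seq_len(sum(hi))]; lwd[hi] <- 2.5 }
  graphics::matplot(theta, mat, type = "l", lty = 1, col = col, lwd = lwd,
                    xlab = expression(theta), ylab = ylab, ...)
  if (!is.null(hline)) graphics::abline(h = hline, lty = 2, col = "grey30")
  if (any(hi)) graphics::legend("topleft", legend = labels[hi],
                                col = col[hi], lwd = 2.5, bty = "n")
  invisible(NULL)
}

#' Box plots of score spread by number-correct
#'
#' The scoring-volatility display: EAP scores (or their standard errors)
#' grouped by number-correct. Wide boxes at high number-correct are the
#' scoring signature of a Heywood item — the score depends on *which* item
#' was missed.
#'
#' @param scores a `score_table` from [eap_scores()].
#' @param what `"theta"` or `"se"`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_score_volatility <- function(scores, what = c("theta", "se"), ...) {
  what <- match.arg(what)
  stopifnot(inherits(scores, "score_table"))
  y <- if (what == "theta") scores$theta_hat else scores$se
  graphics::boxplot(y ~ scores$n_correct, xlab = "number correct",
                    ylab = if (what == "theta") expression(hat(theta))
                           else expression(SE(hat(theta))), ...)
  invisible(NULL)
}
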