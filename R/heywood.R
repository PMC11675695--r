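#' Locate local maxima of an information curve
#'
#' A Heywood case is defined through the critical points of the item
#' information function: the set of theta where the first derivative of
#' I(theta) vanishes and the second derivative is non-positive, i.e. local
#' maxima of information. On a discrete grid this is operationalized as an
#' interior grid local maximum found by sign changes of the finite-difference
#' slope; plateau runs report their midpoint. A maximum attained at a grid
#' boundary has no zero derivative and is reported separately in the
#' `boundary` field, never as a theta*.
#'
#' @param info information values on the grid (vector).
#' @param grid a [theta_grid()].
#' @return Object of class `critical_points`: list with `theta_star`
#'   (locations of interior local maxima), `peak_info` (heights),
#'   `boundary` (`"left"`/`"right"` when the global maximum sits on a grid
#'   edge with no interior peak, otherwise `character(0)`), and `plateau`
#'   (TRUE when the curve is flat to numerical tolerance, e.g. the linear
#'   family's constant information).
#' @examples
#' g <- theta_grid()
#' information_peaks(item_information(item_2pl(1, 2), g), g)  # peak near -0.5
#' @export
information_peaks <- function(info, grid = theta_grid()) {
  grid <- as_grid(grid)
  th <- as.numeric(grid)
  y <- as.numeric(info)
  stopifnot(length(y) == length(th))
  tol <- 1e-12 * max(abs(y), 1)
  d <- diff(y)
  s <- sign(d)
  s[abs(d) <= tol] <- 0L

  out <- list(theta_star = numeric(0), peak_info = numeric(0),
              boundary = character(0), plateau = FALSE)
  nz <- which(s != 0L)
  if (length(nz) == 0L) {  # constant curve
    out$plateau <- TRUE
    return(structure(out, class = "critical_points"))
  }
  # transitions from rising (+1) to falling (-1) in the nonzero slope signs;
  # the peak spans grid points (nz[i] + 1) .. nz[i + 1] inclusive
  sn <- s[nz]
  trans <- which(sn[-length(sn)] == 1L & sn[-1L] == -1L)
  for (i in trans) {
    lo <- nz[i] + 1L
    hi <- nz[i + 1L]
    mid <- (lo + hi) %/% 2L  # plateau run reports its midpoint
    out$theta_star <- c(out$theta_star, th[mid])
    out$peak_info <- c(out$peak_info, max(y[lo:hi]))
  }
  if (length(out$theta_star) == 0L) {
    out$boundary <- if (sn[length(sn)] == 1L) "right" else "left"
  } else {
    # monotone tails ending above every interior peak also merit a note
    if (sn[length(sn)] == 1L && y[length(y)] > max(out$peak_info)) {
      out$boundary <- c(out$boundary, "right")
    }
    if (sn[1L] == -1L && y[1L] > max(out$peak_info)) {
      out$boundary <- c(out$boundary, "left")
    }
  }
  structure(out, class = "critical_points")
}

#' @export
print.critical_points <- function(x, ...) {
  if (x$plateau) cat("<critical_points> flat curve (plateau); no interior maxima\n")
  else if (length(x$theta_star) == 0L) {
    cat("<critical_points> no interior maxima; curve maximal at", x$boundary,
        "grid boundary\n")
  } else {
    cat(sprintf("<critical_points> theta* = %s with I(theta*) = %s\n",
                paste(signif(x$theta_star, 4), collapse = ", "),
                paste(signif(x$peak_info, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Item Fraction of Total Information (IFTI)
#'
#' The unitless per-item share of test information at each theta,
#' \deqn{IFTI_j(\theta) = \frac{I_j(\theta)}{\sum_{k=1}^J I_k(\theta)}.}
#' The units of information cancel, so IFTI is a pure proportion in
#' `[0, 1]` summing to 1 across items at every grid point — a leverage-style
#' diagnostic of how much any one item is responsible for predicting theta
#' ("theta theft"). Multiplying by J converts it to an effective number of
#' items.
#'
#' Grid points with zero total information leave the fraction undefined;
#' they are returned as NA and listed in the `masked` field.
#'
#' @param curves an `info_curves` object (see [information_curves()]).
#' @param scale_J if TRUE, return IFTI * J (effective-items scaling).
#' @return Object of class `ifti_curves`: list with `theta`, `ifti`
#'   (grid x J matrix), `labels`, `J`, `scale_J`, `masked` (indices of
#'   undefined grid points).
#' @export
ifti <- function(curves, scale_J = FALSE) {
  stopifnot(inherits(curves, "info_curves"))
  total <- rowSums(curves$info)
  frac <- curves$info / total
  masked <- which(total == 0)
  if (length(masked)) frac[masked, ] <- NA_real_
  if (scale_J) frac <- frac * ncol(frac)
  structure(list(theta = curves$theta, ifti = frac, labels = curves$labels,
                 J = ncol(frac), scale_J = scale_J, masked = masked),
            class = "ifti_curves")
}

#' @export
print.ifti_curves <- function(x, ...) {
  peak <- apply(x$ifti, 2L, max, na.rm = TRUE)
  worst <- which.max(peak)
  cat(sprintf("<ifti_curves> %d items%s; largest share %.3f (%s)\n", x$J,
              if (x$scale_J) " (x J scaling)" else "",
              peak[worst], x$labels[worst]))
  invisible(x)
}

#' Renormalize IFTI after dropping items
#'
#' Removing a flagged item does not require a refit for diagnostic purposes:
#' item information given parameters is per-item, so the surviving items'
#' fractions are simply renormalized. (Whether the *refit* model would
#' behave better is a separate question — dropping a Heywood item often
#' promotes another item into its place.)
#'
#' @param curves an `info_curves` object.
#' @param drop character vector of item labels (or integer indices) to drop.
#' @param scale_J passed to [ifti()].
#' @return An `ifti_curves` object over the surviving items.
#' @export
ifti_drop <- function(curves, drop, scale_J = FALSE) {
  stopifnot(inherits(curves, "info_curves"))
  idx <- if (is.character(drop)) match(drop, curves$labels) else as.integer(drop)
  if (anyNA(idx)) {
    stop("unknown item label(s): ",
         paste(drop[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(seq_along(curves$labels), idx)
  if (length(keep) == 0L) stop("cannot drop every item", call. = FALSE)
  sub <- structure(list(theta = curves$theta,
                        info = curves$info[, keep, drop = FALSE],
                        labels = curves$labels[keep]),
                   class = "info_curves")
  ifti(sub, scale_J = scale_J)
}

#' Flagging thresholds for Heywood-case detection
#'
#' Three criteria, kept separate in the report (no composite score):
#' \describe{
#'   \item{slope}{under a unit-variance trait, `|xi| > 5` is suspect — the
#'     logistic-regression separation heuristic;}
#'   \item{info}{for the plain 2PL this is equivalent to peak information
#'     `I(theta*) > 6.25` (= 5^2/4), which transfers to families without an
#'     interpretable slope;}
#'   \item{ifti}{in analogy to leverage benchmarks, an information share
#'     above `2/J` is troublesome and above `4/J` clearly problematic.}
#' }
#'
#' @param slope_cut slope magnitude cut (default 5).
#' @param info_cut peak information cut (default `slope_cut^2 / 4` = 6.25).
#' @param ifti_troublesome,ifti_problematic multipliers on 1/J (defaults 2, 4).
#' @export
heywood_thresholds <- function(slope_cut = 5, info_cut = slope_cut^2 / 4,
                               ifti_troublesome = 2, ifti_problematic = 4) {
  stopifnot(slope_cut > 0, info_cut > 0, ifti_troublesome > 0,
            ifti_problematic > 0)
  structure(list(slope_cut = slope_cut, info_cut = info_cut,
                 ifti_troublesome = ifti_troublesome,
                 ifti_problematic = ifti_problematic),
            class = "heywood_thresholds")
}

FLAG_LEVELS <- c("none", "troublesome", "suspect", "problematic")

#' Heywood-case report for an item set
#'
#' Evaluates the three criteria of [heywood_thresholds()] per item and
#' reports each item's worst flag (problematic > suspect > troublesome >
#' none) together with every triggering criterion. The IFTI criteria are
#' pointwise: any exceedance inside `theta_window` triggers, and the
#' exceedance interval is reported. IFTI spikes at extreme theta where no
#' examinee plausibly sits can be excluded by narrowing the window.
#'
#' @param items the `item_set` (used for the slope criterion; families
#'   without a single slope, e.g. NRM, skip that criterion).
#' @param grid a [theta_grid()].
#' @param thresholds a [heywood_thresholds()] object.
#' @param theta_window length-2 numeric restricting where the IFTI criteria
#'   apply; default spans the full grid.
#' @param curves optionally precomputed [information_curves()].
#' @return Object of class `heywood_report`: a data.frame with one row per
#'   item and columns `item_id`, `flag`, `criteria` (comma-separated
#'   triggering criteria), `theta_star`, `peak_info`, `ifti_max`,
#'   `ifti_exceed_lo`, `ifti_exceed_hi`.
#' @examples
#' its <- item_set(list(item_2pl(0, 1), item_2pl(0.5, 2), item_2pl(0, 5.5)))
#' heywood_report(its)
#' @export
heywood_report <- function(items, grid = theta_grid(),
                           thresholds = heywood_thresholds(),
                           theta_window = NULL, curves = NULL) {
  stopifnot(inherits(items, "item_set"),
            inherits(thresholds, "heywood_thresholds"))
  grid <- as_grid(grid)
  th <- as.numeric(grid)
  if (is.null(curves)) curves <- information_curves(items, grid)
  fr <- ifti(curves)
  if (is.null(theta_window)) theta_window <- range(th)
  stopifnot(length(theta_window) == 2L, theta_window[1] < theta_window[2])
  win <- th >= theta_window[1] & th <= theta_window[2]
  if (!any(win)) stop("theta_window contains no grid points", call. = FALSE)

  J <- items$V
  cut_t <- thresholds$ifti_troublesome / J
  cut_p <- thresholds$ifti_problematic / J

  rows <- lapply(seq_len(J), function(v) {
    it <- items$items[[v]]
    crit <- character(0)
    flag <- "none"
    bump <- function(f) FLAG_LEVELS[max(match(flag, FLAG_LEVELS), match(f, FLAG_LEVELS))]

    # slope criterion: binary families with a single slope parameter
    if (inherits(it, c("binary2pl_item", "rh_item")) &&
        abs(it$xi) > thresholds$slope_cut) {
      crit <- c(crit, "slope")
      flag <- bump("suspect")
    }

    cp <- information_peaks(curves$info[, v], grid)
    tstar <- if (length(cp$theta_star)) cp$theta_star[which.max(cp$peak_info)] else NA_real_
    peak <- max(curves$info[, v])
    if (!cp$plateau && peak > thresholds$info_cut) {
      crit <- c(crit, "info")
      flag <- bump("suspect")
    }

    f <- fr$ifti[win, v]
    fmax <- if (all(is.na(f))) NA_real_ else max(f, na.rm = TRUE)
    lo <- hi <- NA_real_
    if (isTRUE(fmax > cut_t)) {
      exceed <- which(!is.na(f) & f > cut_t)
      lo <- th[win][min(exceed)]
      hi <- th[win][max(exceed)]
      crit <- c(crit, "ifti")
      flag <- bump("troublesome")
      if (fmax > cut_p) flag <- bump("problematic")
    }

    data.frame(item_id = items$labels[v], flag = flag,
               criteria = paste(crit, collapse = ","),
               theta_star = tstar, peak_info = peak, ifti_max = fmax,
               ifti_exceed_lo = lo, ifti_exceed_hi = hi,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$flag <- factor(rep$flag, levels = FLAG_LEVELS, ordered = TRUE)
  attr(rep, "thresholds") <- thresholds
  attr(rep, "theta_window") <- theta_window
  class(rep) <- c("heywood_report", "data.frame")
  rep
}

#' @export
print.heywood_report <- function(x, ...) {
  thr <- attr(x, "thresholds")
  J <- nrow(x)
  cat(sprintf(
    "Heywood-case report (%d items; cuts: |slope| > %g, peak info > %g, IFTI > %g/J = %.3g and %g/J = %.3g)\n",
    J, thr$slope_cut, thr$info_cut, thr$ifti_troublesome,
    thr$ifti_troublesome / J, thr$ifti_problematic, thr$ifti_problematic / J))
  flagged <- x[x$flag != "none", , drop = FALSE]
  if (nrow(flagged) == 0L) cat("  no items flagged\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
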