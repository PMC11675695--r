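#' Uniform latent-trait grid
#'
#' Information curves, IFTI, and peak detection are evaluated on a uniform
#' theta grid. The default range `[-4, 4]` with step 0.01 covers the bulk of
#' a standardized (unit-variance) trait distribution at a resolution fine
#' enough that finite-difference derivatives of smooth IRFs are accurate to
#' well under 1e-4.
#'
#' @param lower,upper grid endpoints.
#' @param step grid spacing (> 0).
#' @return Numeric vector of class `theta_grid` with attributes `step` and
#'   `standardized` (records the var(Theta) = 1 convention under which the
#'   slope and information thresholds are calibrated).
#' @export
theta_grid <- function(lower = -4, upper = 4, step = 0.01) {
  stopifnot(is.finite(lower), is.finite(upper), is.finite(step),
            step > 0, upper > lower)
  th <- seq(lower, upper, by = step)
  if (length(th) < 3L) stop("grid must contain at least 3 points", call. = FALSE)
  structure(th, step = step, standardized = TRUE, class = "theta_grid")
}

as_grid <- function(grid) {
  if (inherits(grid, "theta_grid")) return(grid)
  check_theta(grid)
  h <- diff(grid)
  if (length(grid) < 3L || any(h <= 0) || max(h) - min(h) > 1e-8 * mean(h)) {
    stop("grid must be a theta_grid or a uniform increasing vector of >= 3 points",
         call. = FALSE)
  }
  structure(as.numeric(grid), step = mean(h), standardized = TRUE,
            class = "theta_grid")
}

#' @export
print.theta_grid <- function(x, ...) {
  cat(sprintf("<theta_grid> [%g, %g] step %g (%d points)\n",
              min(x), max(x), attr(x, "step"), length(x)))
  invisible(x)
}

PI_EPS <- 1e-12  # clip for pi(1-pi) underflow at extreme theta

#' Item Fisher information
#'
#' For a binary item the information function is
#' \deqn{I(\theta) = \frac{(\partial_\theta \pi)^2}{\pi(1-\pi)},}
#' the squared marginal effect of theta standardized by the conditional
#' Bernoulli variance. For the plain 2PL it peaks at
#' \eqn{\theta^* = -\eta/\xi} with height \eqn{\xi^2/4}. For the linear
#' family it is the constant signal-to-noise ratio \eqn{\xi^2/\psi^2}
#' (equivalently \eqn{(1-h^2)/h^2} in the standardized solution). For the
#' nominal response model the per-category terms
#' \eqn{I_k(\theta) = (\partial_\theta \pi_k)^2/\pi_k - \partial^2_\theta \pi_k}
#' sum to the item information; because the second-derivative terms cancel
#' under the normalization constraint, the total also equals
#' \eqn{\sum_k (\partial_\theta\pi_k)^2/\pi_k}.
#'
#' Grid points where \eqn{\pi(1-\pi)} underflows are computed with \eqn{\pi}
#' clipped to `[1e-12, 1-1e-12]` and recorded in the `clipped` attribute.
#'
#' @param item an `irt_item`.
#' @param grid a [theta_grid()].
#' @return Numeric vector of I(theta) on the grid (units 1/theta^2),
#'   nonnegative; for NRM items, with attribute `categories`, a matrix of
#'   per-category information curves whose rows sum to the total.
#' @examples
#' g <- theta_grid()
#' max(item_information(item_2pl(0, 5), g))  # 6.25 = xi^2/4
#' @export
item_information <- function(item, grid = theta_grid()) {
  grid <- as_grid(grid)
  UseMethod("item_information")
}

binary_info <- function(p, d1) {
  clip <- p < PI_EPS | p > 1 - PI_EPS
  p <- pmin(pmax(p, PI_EPS), 1 - PI_EPS)
  out <- d1^2 / (p * (1 - p))
  if (any(clip)) attr(out, "clipped") <- which(clip)
  out
}

#' @export
item_information.binary2pl_item <- function(item, grid = theta_grid()) {
  th <- as.numeric(grid)
  binary_info(irf(item, th), irf_deriv(item, th, 1L))
}

#' @export
item_information.rh_item <- function(item, grid = theta_grid()) {
  th <- as.numeric(grid)
  binary_info(irf(item, th), irf_deriv(item, th, 1L))
}

#' @export
item_information.linear_item <- function(item, grid = theta_grid()) {
  rep(linear_item_information(item), length(as.numeric(grid)))
}

#' @export
item_information.nrm_item <- function(item, grid = theta_grid()) {
  th <- as.numeric(grid)
  p  <- irf(item, th)
  d1 <- irf_deriv(item, th, 1L)
  d2 <- irf_deriv(item, th, 2L)
  cat_info <- d1^2 / pmax(p, PI_EPS) - d2
  total <- rowSums(cat_info)
  attr(total, "categories") <- cat_info
  total
}

#' Constant information of a linear item
#'
#' \eqn{I = \xi^2/\psi^2}; in the standardized solution, \eqn{(1-h^2)/h^2}.
#' Constant in theta, so a scalar is returned.
#' @param item a `linear_item`.
#' @export
linear_item_information <- function(item) {
  stopifnot(inherits(item, "linear_item"))
  item$xi^2 / item$psi2
}

#' Total information of a standardized linear item set
#'
#' Uses the closed form \eqn{\sum_v 1/h_v^2 - V}, valid when every item is
#' standardized (\eqn{\psi^2 = h^2}, \eqn{\xi^2 = 1 - h^2}).
#'
#' @param items an `item_set` of standardized linear items (built with
#'   [linear_item_std()]), or a numeric vector of h-squared values.
#' @export
linear_total_information <- function(items) {
  h2 <- if (is.numeric(items)) items
        else {
          stopifnot(inherits(items, "item_set"),
                    inherits(items$items[[1L]], "linear_item"))
          vapply(items$items, function(i) {
            if (is.null(i$h2)) stop("item '", i$label, "' is not standardized; ",
                                    "build with linear_item_std()", call. = FALSE)
            i$h2
          }, numeric(1))
        }
  if (any(h2 <= 0 | h2 >= 1)) stop("all h2 must lie in (0, 1)", call. = FALSE)
  sum(1 / h2) - length(h2)
}

#' Information curves for every item in a set
#'
#' @param items an `item_set`.
#' @param grid a [theta_grid()].
#' @return Object of class `info_curves`: list with `theta`, `info` (a
#'   `length(grid) x V` matrix, one column per item), `labels`, and for NRM
#'   sets `categories` (per-item matrices of category information).
#' @export
information_curves <- function(items, grid = theta_grid()) {
  grid <- as_grid(grid)
  stopifnot(inherits(items, "item_set"))
  per <- lapply(items$items, item_information, grid = grid)
  info <- do.call(cbind, lapply(per, as.numeric))
  colnames(info) <- items$labels
  out <- list(theta = grid, info = info, labels = items$labels)
  cats <- lapply(per, attr, "categories")
  if (!all(vapply(cats, is.null, logical(1)))) {
    names(cats) <- items$labels
    out$categories <- cats
  }
  structure(out, class = "info_curves")
}

#' @export
print.info_curves <- function(x, ...) {
  cat(sprintf("<info_curves> %d items on [%g, %g] (%d points); peak I = %g\n",
              ncol(x$info), min(x$theta), max(x$theta), length(x$theta),
              signif(max(x$info), 4)))
  invisible(x)
}

#' Test information function
#'
#' Under local independence Fisher information is additive across items, so
#' the test information is the pointwise sum of the item curves.
#'
#' @param curves an `info_curves` object, or a list of equal-length
#'   information vectors sharing one grid.
#' @return Numeric vector I_T(theta) on the grid.
#' @export
test_information <- function(curves) {
  if (inherits(curves, "info_curves")) return(rowSums(curves$info))
  stopifnot(is.list(curves), length(curves) >= 1L)
  n <- lengths(curves)
  if (length(unique(n)) != 1L) stop("curves must share one grid", call. = FALSE)
  rowSums(do.call(cbind, lapply(curves, as.numeric)))
}

#' Information-to-reliability mapping
#'
#' \deqn{rel(\theta) = \frac{I(\theta)}{1 + I(\theta)},}
#' the local analog of classical reliability: I = 10 corresponds to about
#' 0.91, I = 1 to 0.5. Applies at item or test level, to scalars or curves.
#'
#' @param info nonnegative information value(s).
#' @return Values in `[0, 1)`, same shape as `info`.
#' @export
reliability <- function(info) {
  if (!is.numeric(info) || any(!is.finite(info)) || any(info < 0)) {
    stop("information must be finite and nonnegative", call. = FALSE)
  }
  info / (1 + info)
}

#' Optimal scoring weights for a binary item
#'
#' \eqn{w(\theta) = \partial_\theta\pi / (\pi(1-\pi))}: the first derivative
#' rescaled by the conditional variance. For the plain 2PL this is the
#' constant \eqn{\xi}; a Heywood case makes w essentially infinite near
#' theta* and 0 elsewhere. Satisfies \eqn{I = w \cdot \partial_\theta\pi}
#' pointwise.
#'
#' @param item a binary-family item (2PL/3PL/4PL/RH).
#' @param grid a [theta_grid()].
#' @export
optimal_weights <- function(item, grid = theta_grid()) {
  if (!inherits(item, c("binary2pl_item", "rh_item"))) {
    stop("optimal weights are defined for binary items", call. = FALSE)
  }
  th <- as.numeric(as_grid(grid))
  p <- pmin(pmax(irf(item, th), PI_EPS), 1 - PI_EPS)
  irf_deriv(item, th, 1L) / (p * (1 - p))
}
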