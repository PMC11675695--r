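#' Item response functions and their exact derivatives
#'
#' `irf()` evaluates Pr(response | theta) for an item; `irf_deriv()` returns
#' the exact first or second derivative with respect to theta. For the
#' nominal response model both return one column per category.
#'
#' All binary families use the standard logistic CDF
#' \eqn{\Lambda(x) = e^x / (1 + e^x)}. The RH item response function divides
#' the 2PL linear predictor by a logistic residual-scale function
#' \eqn{\sigma(\theta) = 2\Lambda(\delta\theta)}:
#' \deqn{\pi(\theta) = \Lambda\!\left(\frac{\eta + \xi\theta}{2\Lambda(\delta\theta)}\right)
#'   = \Lambda\!\left((\eta + \xi\theta)\,\frac{1 + e^{-\delta\theta}}{2}\right).}
#' The scale equals 1 at \eqn{\delta = 0} (or \eqn{\theta = 0}), so
#' the RH model collapses to the 2PL exactly when \eqn{\delta = 0}. For
#' \eqn{\delta \neq 0} the IRF is asymmetric and, in parts of the parameter
#' space, non-monotone; see [irf_monotone()].
#'
#' @param item an `irt_item`.
#' @param theta finite numeric scalar or vector of latent-trait values.
#' @return `irf()`: probabilities in (0, 1), a vector (binary) or a
#'   `length(theta) x K` matrix (NRM). `irf_deriv()`: same shape.
#' @examples
#' irf(item_2pl(0, 1), c(-1, 0, 1))
#' irf_deriv(item_2pl(0, 4), 0)       # = xi/4 = 1 at theta*
#' @export
irf <- function(item, theta) {
  check_theta(theta)
  UseMethod("irf")
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0L || !all(is.finite(theta))) {
    stop("theta must be finite numeric", call. = FALSE)
  }
  invisible(theta)
}

logistic <- function(x) stats::plogis(x)

#' @export
irf.binary2pl_item <- function(item, theta) {
  item$c + (item$d - item$c) * logistic(item$eta + item$xi * theta)
}

# RH heteroscedastic residual scale sigma(theta) = 2 * Lambda(delta * theta):
# a logistic residual-SD function equal to 1 at delta = 0 (or theta = 0), so
# the model collapses to the 2PL there. Swappable if an alternative algebraic
# reading is ever needed. Returns value and first two theta-derivatives.
rh_scale <- function(delta, theta) {
  lam <- stats::plogis(delta * theta)
  pq <- lam * (1 - lam)
  list(s  = 2 * lam,
       s1 = 2 * delta * pq,
       s2 = 2 * delta^2 * pq * (1 - 2 * lam))
}

rh_linpred <- function(item, theta) {
  u  <- item$eta + item$xi * theta
  sc <- rh_scale(item$delta, theta)
  g  <- u / sc$s
  # quotient-rule derivatives of g = u / s
  g1 <- (item$xi * sc$s - u * sc$s1) / sc$s^2
  g2 <- (-u * sc$s2 * sc$s - 2 * sc$s1 * (item$xi * sc$s - u * sc$s1)) / sc$s^3
  list(g = g, g1 = g1, g2 = g2)
}

#' @export
irf.rh_item <- function(item, theta) {
  logistic(rh_linpred(item, theta)$g)
}

#' @export
irf.nrm_item <- function(item, theta) {
  z <- outer(theta, item$gamma) + rep(item$alpha, each = length(theta))
  z <- z - apply(z, 1L, max)  # guard overflow
  ez <- exp(z)
  p <- ez / rowSums(ez)
  colnames(p) <- paste0("cat", seq_len(item$K))
  p
}

#' @export
irf.linear_item <- function(item, theta) {
  # conditional mean of the continuous response
  item$eta + item$xi * theta
}

#' @rdname irf
#' @param order derivative order, 1 or 2.
#' @export
irf_deriv <- function(item, theta, order = 1L) {
  check_theta(theta)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  UseMethod("irf_deriv")
}

#' @export
irf_deriv.binary2pl_item <- function(item, theta, order = 1L) {
  p <- logistic(item$eta + item$xi * theta)
  a <- item$d - item$c
  if (order == 1L) a * item$xi * p * (1 - p)
  else a * item$xi^2 * p * (1 - p) * (1 - 2 * p)
}

#' @export
irf_deriv.rh_item <- function(item, theta, order = 1L) {
  lp <- rh_linpred(item, theta)
  p <- logistic(lp$g)
  pq <- p * (1 - p)
  if (order == 1L) pq * lp$g1
  else pq * ((1 - 2 * p) * lp$g1^2 + lp$g2)
}

#' @export
irf_deriv.nrm_item <- function(item, theta, order = 1L) {
  p <- irf.nrm_item(item, theta)
  gbar <- drop(p %*% item$gamma)                  # E[gamma | theta]
  dev  <- outer(-gbar, item$gamma, `+`)           # gamma_k - gbar
  d1 <- p * dev
  if (order == 1L) return(d1)
  gvar <- drop(p %*% item$gamma^2) - gbar^2       # var[gamma | theta]
  p * (dev^2 - gvar)
}

#' @export
irf_deriv.linear_item <- function(item, theta, order = 1L) {
  if (order == 1L) rep(item$xi, length(theta)) else rep(0, length(theta))
}

#' Finite-difference differentiation of a curve on a uniform grid
#'
#' Central differences in the interior with one-sided stencils at the ends.
#' On a sufficiently fine grid this approximates derivatives of smooth item
#' response functions to high accuracy, so awkward analytic expressions can
#' be bypassed entirely; the package's analytic derivatives are cross-checked
#' against this routine in the test suite.
#'
#' @param y curve values at `theta` (vector, or matrix with one curve per
#'   column).
#' @param theta strictly increasing, uniformly spaced grid of at least 3
#'   points.
#' @param order 1 or 2.
#' @return Derivative values, same shape as `y`.
#' @export
numerical_derivative <- function(y, theta, order = 1L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (is.matrix(y)) return(apply(y, 2L, numerical_derivative, theta = theta, order = order))
  n <- length(theta)
  if (n < 3L) stop("need at least 3 grid points", call. = FALSE)
  stopifnot(length(y) == n)
  h <- diff(theta)
  if (any(h <= 0) || max(h) - min(h) > 1e-8 * mean(h)) {
    stop("theta grid must be strictly increasing with uniform spacing", call. = FALSE)
  }
  h <- mean(h)
  i <- 2:(n - 1L)
  if (order == 1L) {
    d <- numeric(n)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (2 * h)
    d[1L] <- (-3 * y[1L] + 4 * y[2L] - y[3L]) / (2 * h)
    d[n]  <- (3 * y[n] - 4 * y[n - 1L] + y[n - 2L]) / (2 * h)
  } else {
    d <- numeric(n)
    d[i] <- (y[i + 1L] - 2 * y[i] + y[i - 1L]) / h^2
    d[1L] <- (y[1L] - 2 * y[2L] + y[3L]) / h^2
    d[n]  <- (y[n] - 2 * y[n - 1L] + y[n - 2L]) / h^2
  }
  d
}

#' Check monotonicity of a binary IRF on a grid
#'
#' The RH model's IRF is non-monotone in parts of its parameter space; this
#' helper reports whether the first derivative changes sign on the grid.
#'
#' @param item a binary-family item.
#' @param grid a [theta_grid()] (or numeric grid).
#' @return TRUE if the IRF is monotone over the grid; FALSE (with attribute
#'   `sign_changes` giving grid locations) otherwise.
#' @export
irf_monotone <- function(item, grid = theta_grid()) {
  th <- as.numeric(grid)
  d1 <- irf_deriv(item, th, order = 1L)
  nz <- which(sign(d1) != 0)
  flips <- nz[which(diff(sign(d1)[nz]) != 0)]
  out <- length(flips) == 0L
  if (!out) attr(out, "sign_changes") <- th[flips]
  out
}
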