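#' Item constructors for the supported model families
#'
#' Items are small S3 records holding the parameters of one item response
#' function. Five families are supported:
#' \describe{
#'   \item{linear}{the unidimensional linear factor model
#'     \eqn{Y = \eta + \xi\Theta + U}, \eqn{U \sim N(0, \psi^2)};}
#'   \item{2pl}{the two-parameter logistic in slope-intercept form
#'     \eqn{\pi(\theta) = \Lambda(\eta + \xi\theta)};}
#'   \item{3pl/4pl}{the 2PL with lower asymptote \eqn{c} and/or upper
#'     asymptote \eqn{d}: \eqn{\pi = c + (d-c)\Lambda(\eta + \xi\theta)};}
#'   \item{rh}{the residual heteroscedasticity (RH) model, an asymmetric
#'     2PL extension with parameter \eqn{\delta}, reducing to the 2PL at
#'     \eqn{\delta = 0};}
#'   \item{nrm}{the nominal response model, a multinomial logit over K
#'     unordered categories with sum-to-zero intercepts \eqn{\alpha_k} and
#'     slopes \eqn{\gamma_k}.}
#' }
#'
#' Throughout, \eqn{\eta} is the item easiness (intercept), \eqn{\xi} the
#' slope (discrimination/loading), and the latent trait \eqn{\Theta} is taken
#' standardized, \eqn{var(\Theta) = 1}, so that slopes and information are
#' comparable across items and the usual flagging thresholds apply.
#'
#' @param eta easiness / intercept (latent scale).
#' @param xi slope (loading); unitless under the standardized trait.
#' @param psi2 unique (error) variance, must be strictly positive.
#' @param label item label; defaults are filled in by [item_set()].
#' @return An object of class `c("<family>_item", "irt_item")`.
#' @examples
#' it <- item_2pl(eta = 1, xi = 2)
#' irf(it, 0)
#' @export
linear_item <- function(eta = 0, xi, psi2, label = NULL) {
  stopifnot(is.finite(eta), is.finite(xi), is.finite(psi2))
  if (psi2 <= 0) {
    stop("linear item ", if (is.null(label)) "" else paste0("'", label, "' "),
         "has non-positive unique variance psi2 = ", psi2,
         " (a Heywood case by construction); psi2 must be > 0", call. = FALSE)
  }
  structure(list(eta = eta, xi = xi, psi2 = psi2, label = label),
            class = c("linear_item", "irt_item"))
}

#' Standardized linear item from its h-squared value
#'
#' In the standardized solution the unique variance equals \eqn{h^2} and the
#' squared loading is \eqn{1 - h^2}, so item information is
#' \eqn{(1 - h^2) / h^2} (constant in \eqn{\theta}).
#'
#' @param h2 value in (0, 1): the standardized variance split parameter, with
#'   \eqn{\psi^2 = h^2} and \eqn{\xi^2 = 1 - h^2}.
#' @inheritParams linear_item
#' @export
linear_item_std <- function(h2, eta = 0, label = NULL) {
  stopifnot(is.finite(h2))
  if (h2 <= 0 || h2 >= 1) {
    stop("standardized linear item requires h2 in (0, 1); got ", h2, call. = FALSE)
  }
  it <- linear_item(eta = eta, xi = sqrt(1 - h2), psi2 = h2, label = label)
  it$h2 <- h2
  it
}

#' @rdname linear_item
#' @param c lower asymptote in `[0, 1)` (guessing); 0 gives the 2PL.
#' @param d upper asymptote in `(c, 1]` (slipping); 1 gives the 2PL/3PL.
#' @export
item_2pl <- function(eta, xi, c = 0, d = 1, label = NULL) {
  stopifnot(is.finite(eta), is.finite(xi), is.finite(c), is.finite(d))
  if (c < 0 || c >= 1) stop("lower asymptote c must lie in [0, 1)", call. = FALSE)
  if (d <= c || d > 1) stop("upper asymptote d must lie in (c, 1]", call. = FALSE)
  structure(list(eta = eta, xi = xi, c = c, d = d, label = label),
            class = c("binary2pl_item", "irt_item"))
}

#' @rdname linear_item
#' @param delta heteroscedasticity / asymmetry parameter of the RH model.
#' @export
item_rh <- function(eta, xi, delta, label = NULL) {
  stopifnot(is.finite(eta), is.finite(xi), is.finite(delta))
  structure(list(eta = eta, xi = xi, delta = delta, label = label),
            class = c("rh_item", "irt_item"))
}

#' @rdname linear_item
#' @param alpha numeric K-vector of category intercepts.
#' @param gamma numeric K-vector of category slopes.
#' @param parameterization `"sum"` for sum-to-zero input (the internal
#'   canonical form) or `"baseline"` for baseline-category input (first
#'   category fixed at 0), which is re-centered on construction.
#' @export
item_nrm <- function(alpha, gamma, parameterization = c("sum", "baseline"),
                     label = NULL) {
  parameterization <- match.arg(parameterization)
  stopifnot(length(alpha) == length(gamma), all(is.finite(alpha)),
            all(is.finite(gamma)))
  K <- length(alpha)
  if (K < 2) stop("nominal response item needs at least 2 categories", call. = FALSE)
  if (parameterization == "baseline") {
    alpha <- alpha - mean(alpha)
    gamma <- gamma - mean(gamma)
  } else {
    if (abs(sum(alpha)) > 1e-8 || abs(sum(gamma)) > 1e-8) {
      stop("sum-to-zero identification violated (sum(alpha) = ",
           signif(sum(alpha), 3), ", sum(gamma) = ", signif(sum(gamma), 3),
           "); pass parameterization = \"baseline\" to re-center", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, gamma = gamma, K = K, label = label),
            class = c("nrm_item", "irt_item"))
}

#' Family tag of an item or item set
#' @param x an `irt_item` or `item_set`.
#' @export
item_family <- function(x) {
  if (inherits(x, "item_set")) x <- x$items[[1L]]
  switch(class(x)[1L],
         linear_item    = "linear",
         binary2pl_item = if (x$c == 0 && x$d == 1) "2pl"
                          else if (x$d == 1) "3pl" else "4pl",
         rh_item        = "rh",
         nrm_item       = "nrm",
         stop("not an irt_item"))
}

#' An ordered collection of items from one model family
#'
#' @param items list of `irt_item` objects, all of the same family.
#' @param labels optional character vector of unique labels; item-level labels
#'   win, then this argument, then `item1 ... itemV`.
#' @return An object of class `item_set` with elements `items`, `labels`,
#'   and `V` (the item count, a.k.a. J).
#' @export
item_set <- function(items, labels = NULL) {
  if (inherits(items, "irt_item")) items <- list(items)
  stopifnot(is.list(items), length(items) >= 1L)
  if (!all(vapply(items, inherits, logical(1), "irt_item"))) {
    stop("all elements must be irt_item objects", call. = FALSE)
  }
  fams <- vapply(items, function(i) class(i)[1L], character(1))
  if (length(unique(fams)) != 1L) {
    stop("an item_set holds one family per set; got: ",
         paste(unique(fams), collapse = ", "), call. = FALSE)
  }
  V <- length(items)
  own <- vapply(items, function(i) i$label %||% NA_character_, character(1))
  if (is.null(labels)) {
    labels <- ifelse(is.na(own), paste0("item", seq_len(V)), own)
  }
  stopifnot(length(labels) == V)
  if (anyDuplicated(labels)) stop("item labels must be unique", call. = FALSE)
  for (v in seq_len(V)) items[[v]]$label <- labels[v]
  structure(list(items = items, labels = labels, V = V), class = "item_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.item_set <- function(x) x$V

#' @export
`[.item_set` <- function(x, i) {
  item_set(x$items[i], labels = x$labels[i])
}

#' @export
print.irt_item <- function(x, ...) {
  fam <- item_family(x)
  pars <- x[setdiff(names(x), c("label", "K"))]
  flat <- unlist(pars)
  cat(sprintf("<%s item%s> %s\n", fam,
              if (is.null(x$label)) "" else paste0(" ", x$label),
              paste(names(flat), signif(flat, 4), sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
print.item_set <- function(x, ...) {
  cat(sprintf("<item_set> %d %s items: %s\n", x$V, item_family(x),
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}

#' Location of the 2PL inflection point theta* = -eta/xi
#'
#' For the plain 2PL this is where the IRF crosses (c+d)/2, the first
#' derivative peaks at \eqn{\xi/4}, and information peaks at \eqn{\xi^2/4}.
#' Undefined (NA) when \eqn{\xi = 0}.
#' @param item a `binary2pl_item`.
#' @export
theta_star <- function(item) {
  stopifnot(inherits(item, "binary2pl_item"))
  if (item$xi == 0) return(NA_real_)
  -item$eta / item$xi
}
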