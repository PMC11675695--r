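#' Response matrices
#'
#' Responses are held as a plain integer matrix Y (persons in rows, items in
#' columns): 0/1 for binary families, 1..K for the nominal response model,
#' NA for missing. `response_matrix()` validates codes against an item set.
#'
#' @param Y matrix (or data.frame) of integer response codes, NA allowed.
#' @param items the `item_set` the responses belong to.
#' @return The validated matrix with column names set to the item labels.
#' @export
response_matrix <- function(Y, items) {
  stopifnot(inherits(items, "item_set"))
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (ncol(Y) != items$V) {
    stop("response matrix has ", ncol(Y), " columns but the item set has ",
         items$V, " items", call. = FALSE)
  }
  fam <- item_family(items)
  obs <- Y[!is.na(Y)]
  if (fam == "nrm") {
    K <- items$items[[1L]]$K
    if (any(obs != round(obs) | obs < 1 | obs > K)) {
      stop("NRM responses must be integer codes in 1..", K, call. = FALSE)
    }
  } else if (fam != "linear") {
    if (any(!obs %in% c(0, 1))) {
      stop("binary responses must be coded 0/1", call. = FALSE)
    }
  }
  if (any(rowSums(!is.na(Y)) == 0L)) {
    warning("some persons have no observed responses; EAP returns the prior for them")
  }
  colnames(Y) <- items$labels
  Y
}

# log-likelihood matrix: persons x nodes, missing items skipped
loglik_by_node <- function(items, Y, nodes) {
  fam <- item_family(items)
  N <- nrow(Y); Q <- length(nodes)
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  if (fam == "nrm") {
    ll <- matrix(0, N, Q)
    for (v in seq_len(items$V)) {
      p <- irf(items$items[[v]], nodes)            # Q x K
      lp <- log(pmax(p, 1e-300))
      yv <- Y[, v]
      ok <- which(!is.na(yv))
      ll[ok, ] <- ll[ok, ] + t(lp[, yv[ok], drop = FALSE])
    }
    return(ll)
  }
  if (fam == "linear") {
    ll <- matrix(0, N, Q)
    for (v in seq_len(items$V)) {
      it <- items$items[[v]]
      mu <- it$eta + it$xi * nodes                 # length Q
      yv <- Y[, v]
      ok <- which(!is.na(yv))
      ll[ok, ] <- ll[ok, ] +
        outer(yv[ok], mu, function(y, m) stats::dnorm(y, m, sqrt(it$psi2), log = TRUE))
    }
    return(ll)
  }
  # binary families: vectorized over items
  P <- vapply(items$items, irf, numeric(Q), theta = nodes)  # Q x V
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  lp1 <- log(P); lp0 <- log1p(-P)
  (M * Y0) %*% t(lp1) + (M * (1 - Y0)) %*% t(lp0)
}

#' EAP latent-trait scores
#'
#' Expected a posteriori scoring: a Gaussian prior on theta is updated by the
#' observed responses via Bayes' rule, and the posterior mean and SD are
#' returned. The posterior integral is approximated by a fixed rectangular
#' quadrature over equally spaced nodes — 61 nodes on `[-6, 6]` by default,
#' which matches a 10,001-node dense grid to well under 1e-4 for ordinary
#' item sets. EAP is finite for every response pattern (including all
#' correct), unlike maximum likelihood, and shrinks toward the prior mean.
#' Missing responses are simply skipped in the likelihood (treated as
#' ignorable).
#'
#' @param items an `item_set` (any supported family).
#' @param Y response matrix (see [response_matrix()]).
#' @param prior_mean,prior_sd Gaussian prior on theta (default standard
#'   normal, consistent with the standardized-trait convention).
#' @param n_nodes number of quadrature nodes.
#' @param bounds quadrature range.
#' @return A `score_table` data.frame: `theta_hat`, `se` (posterior SD),
#'   `n_correct` (row sum for binary families, NA otherwise),
#'   `prop_correct`, `n_observed`.
#' @export
eap_scores <- function(items, Y, prior_mean = 0, prior_sd = 1,
                       n_nodes = 61L, bounds = c(-6, 6)) {
  stopifnot(inherits(items, "item_set"), prior_sd > 0, n_nodes >= 3L)
  Y <- response_matrix(Y, items)
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  lw <- stats::dnorm(nodes, prior_mean, prior_sd, log = TRUE)
  ll <- loglik_by_node(items, Y, nodes)
  lpost <- sweep(ll, 2L, lw, `+`)
  m <- apply(lpost, 1L, max)
  if (any(!is.finite(m))) stop("likelihood is non-finite at every node for some person",
                               call. = FALSE)
  w <- exp(lpost - m)
  w <- w / rowSums(w)
  theta_hat <- drop(w %*% nodes)
  second <- drop(w %*% nodes^2)
  se <- sqrt(pmax(second - theta_hat^2, 0))
  fam <- item_family(items)
  nobs <- rowSums(!is.na(Y))
  nc <- if (fam %in% c("2pl", "3pl", "4pl", "rh")) rowSums(Y, na.rm = TRUE) else rep(NA_real_, nrow(Y))
  out <- data.frame(theta_hat = theta_hat, se = se, n_correct = nc,
                    prop_correct = nc / pmax(nobs, 1), n_observed = nobs)
  class(out) <- c("score_table", "data.frame")
  attr(out, "method") <- "eap"
  out
}

#' Bartlett factor scores for the linear family
#'
#' The closed-form weighted least-squares score
#' \deqn{\hat\theta_n = \Big(\sum_v \xi_v^2/\psi_v^2\Big)^{-1}
#'       \sum_v \xi_v y_{nv}/\psi_v^2:}
#' the inverse of the total information times an information-weighted sum of
#' the responses. Items with very small unique variance dominate the score —
#' the linear-model face of a Heywood case. Missing responses are handled by
#' restricting both sums to the observed items.
#'
#' @param items an `item_set` of linear items.
#' @param Y numeric response matrix (continuous responses; NA allowed).
#' @return A `score_table` data.frame with `theta_hat`, `se` (the usual
#'   Bartlett sampling SD, `1/sqrt(total information)` over observed items),
#'   and `n_observed`.
#' @export
bartlett_scores <- function(items, Y) {
  stopifnot(inherits(items, "item_set"),
            inherits(items$items[[1L]], "linear_item"))
  Y <- response_matrix(Y, items)
  xi <- vapply(items$items, `[[`, numeric(1), "xi")
  psi2 <- vapply(items$items, `[[`, numeric(1), "psi2")
  M <- !is.na(Y)
  if (any(rowSums(M) == 0L)) stop("every person needs at least one observed response",
                                  call. = FALSE)
  Y0 <- Y; Y0[!M] <- 0
  num <- drop(Y0 %*% (xi / psi2))
  denom <- drop(M %*% (xi^2 / psi2))
  out <- data.frame(theta_hat = num / denom, se = 1 / sqrt(denom),
                    n_correct = NA_real_, prop_correct = NA_real_,
                    n_observed = rowSums(M))
  class(out) <- c("score_table", "data.frame")
  attr(out, "method") <- "bartlett"
  out
}

#' Score volatility by number-correct
#'
#' Groups persons by their number-correct score and summarizes the spread of
#' the latent-trait estimates and standard errors within each group. In a
#' well-behaved test, examinees with the same number correct receive similar
#' scores; a Heywood item makes the score depend heavily on *which* item was
#' missed, inflating within-group spread at high number-correct.
#'
#' @param scores a `score_table` from [eap_scores()] (binary families, so
#'   `n_correct` is defined).
#' @return Data.frame with one row per number-correct level: `n_correct`,
#'   `n_persons`, and for theta-hat and SE the min, max, IQR, and range.
#' @export
score_volatility <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  if (all(is.na(scores$n_correct))) {
    stop("volatility summary needs number-correct (binary families)", call. = FALSE)
  }
  sp <- split(scores, scores$n_correct)
  rows <- lapply(sp, function(g) {
    iqr <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75))))
    data.frame(n_correct = g$n_correct[1L], n_persons = nrow(g),
               theta_min = min(g$theta_hat), theta_max = max(g$theta_hat),
               theta_iqr = iqr(g$theta_hat),
               theta_range = max(g$theta_hat) - min(g$theta_hat),
               se_min = min(g$se), se_max = max(g$se), se_iqr = iqr(g$se))
  })
  out <- do.call(rbind, rows)
  out[order(out$n_correct), , drop = FALSE]
}
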