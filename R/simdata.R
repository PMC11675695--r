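#' Draw latent traits from the standardized generative model
#'
#' The generative convention throughout is a Gaussian trait with mean 0 and
#' unit variance (the standardization under which all slope/information
#' thresholds are calibrated).
#'
#' @param n number of persons (>= 1).
#' @param seed integer seed; mandatory so that every simulated dataset is
#'   reproducible.
#' @param sd trait standard deviation (default 1).
#' @return Numeric vector of n trait values.
#' @export
simulate_thetas <- function(n, seed, sd = 1) {
  stopifnot(n >= 1, is.numeric(seed), length(seed) == 1L, sd > 0)
  withr_seed(seed, stats::rnorm(n, 0, sd))
}

# run expr under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate item responses given trait values
#'
#' Independent draws per person-item (local independence) with
#' success/category probabilities from the item response function. Binary
#' families yield 0/1, the nominal response model yields codes 1..K, and the
#' linear family yields Gaussian responses with variance psi2.
#'
#' @param items an `item_set`.
#' @param thetas numeric vector of latent-trait values (one per person).
#' @param seed integer seed.
#' @return N x V response matrix with item labels as column names.
#' @export
simulate_responses <- function(items, thetas, seed) {
  stopifnot(inherits(items, "item_set"))
  check_theta(thetas)
  N <- length(thetas); V <- items$V
  fam <- item_family(items)
  withr_seed(seed, {
    Y <- matrix(NA_real_, N, V, dimnames = list(NULL, items$labels))
    for (v in seq_len(V)) {
      it <- items$items[[v]]
      if (fam == "nrm") {
        p <- irf(it, thetas)                       # N x K
        u <- stats::runif(N)
        Y[, v] <- max.col(u < t(apply(p, 1L, cumsum)), ties.method = "first")
      } else if (fam == "linear") {
        Y[, v] <- it$eta + it$xi * thetas + stats::rnorm(N, 0, sqrt(it$psi2))
      } else {
        Y[, v] <- stats::rbinom(N, 1L, irf(it, thetas))
      }
    }
    Y
  })
}

#' The published 16-item RH calibration used as a realistic fixture
#'
#' A published residual-heteroscedasticity calibration of 16 public-domain
#' cognitive-ability items of four types (verbal reasoning RE*, letter
#' series LT*, matrix reasoning MX*, mental rotation MR*). The four mental
#' rotation items have strongly negative asymmetry (delta down to -2.64) and
#' are the motivating Heywood-case exhibit: their information spikes between
#' theta = 1 and 2 and they capture most of the test information there.
#'
#' @return An `item_set` of 16 `rh` items.
#' @export
rh_calibration <- function() {
  path <- system.file("extdata", "rh_items.csv", package = "heywoodIRT",
                      mustWork = TRUE)
  read_item_table(path)
}

#' Deterministic fixture suite for tests and examples
#'
#' Four named scenarios, each an item set plus simulated responses at
#' N = 200 and N = 2000:
#' \describe{
#'   \item{clean_2pl}{16 well-behaved 2PL items (slopes 0.7..1.4, easiness
#'     spread over `[-1.5, 1.5]`): the slope band is kept narrow so that no
#'     item is flagged problematic at the generating values, even by the
#'     extreme-theta IFTI artifact;}
#'   \item{planted_guttman}{the clean set with item 8 replaced by a slope-8
#'     near-Guttman item (information peak 16, far above the 6.25 cut but
#'     not numerically degenerate);}
#'   \item{rh_table1}{the [rh_calibration()] estimates treated as generating
#'     values — a synthetic stand-in for the real multi-type ability data;}
#'   \item{nrm_small}{8 nominal items with K = 5 categories, moderate
#'     sum-to-zero slopes.}
#' }
#' All randomness flows through `seed`; the same seed regenerates the suite
#' bit-identically.
#'
#' @param seed integer seed.
#' @param sizes person counts to simulate at (default 200 and 2000).
#' @return Named list of scenarios, each `list(items, responses)` with
#'   `responses` a named list by sample size.
#' @export
fixture_suite <- function(seed = 2024L, sizes = c(200L, 2000L)) {
  seed <- as.integer(seed)
  clean <- item_set(lapply(1:16, function(v) {
    item_2pl(eta = seq(-1.5, 1.5, length.out = 16)[v],
             xi = 0.7 + 0.7 * ((v * 7L) %% 16L) / 15,
             label = sprintf("C%02d", v))
  }))
  planted_items <- clean$items
  planted_items[[8L]] <- item_2pl(eta = planted_items[[8L]]$eta, xi = 8,
                                  label = "G08")
  planted <- item_set(planted_items)
  rh <- rh_calibration()
  nrm <- item_set(lapply(1:8, function(v) {
    K <- 5L
    a <- seq(-1, 1, length.out = K) * (0.4 + 0.1 * (v %% 3L))
    g <- seq(-1, 1, length.out = K) * (0.5 + 0.15 * (v %% 4L))
    item_nrm(a - mean(a), g - mean(g), label = sprintf("N%02d", v))
  }))
  scen <- list(clean_2pl = clean, planted_guttman = planted,
               rh_table1 = rh, nrm_small = nrm)
  out <- list()
  for (i in seq_along(scen)) {
    nm <- names(scen)[i]
    responses <- list()
    for (n in sizes) {
      sub_seed <- (seed + 1000L * i + n) %% .Machine$integer.max
      th <- simulate_thetas(n, seed = sub_seed)
      responses[[paste0("n", n)]] <-
        simulate_responses(scen[[i]], th, seed = sub_seed + 1L)
    }
    out[[nm]] <- list(items = scen[[i]], responses = responses)
  }
  out
}
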