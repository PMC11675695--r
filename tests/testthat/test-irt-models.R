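test_that("2PL IRF evaluates the slope-intercept logistic exactly", {
  expect_equal(irf(item_2pl(0, 1), 0), 0.5)
  expect_equal(irf(item_2pl(1, 2), -0.5), 0.5)  # theta* = -eta/xi
  expect_equal(irf(item_2pl(0, 2), 1), exp(2) / (1 + exp(2)))
  # monotone when xi > 0
  th <- as.numeric(theta_grid())
  expect_true(all(diff(irf(item_2pl(-1, 1.7), th)) > 0))
  expect_error(irf(item_2pl(0, 1), Inf), "finite")
})

test_that("3PL/4PL asymptotes bound the IRF and collapse to the 2PL", {
  th <- as.numeric(theta_grid())
  it4 <- item_2pl(0.5, 1.5, c = 0.2, d = 0.95)
  p <- irf(it4, th)
  expect_true(all(p > 0.2 & p < 0.95))
  expect_identical(irf(item_2pl(0.5, 1.5, c = 0, d = 1), th),
                   irf(item_2pl(0.5, 1.5), th))
  expect_error(item_2pl(0, 1, c = 1.2), "asymptote")
  expect_error(item_2pl(0, 1, c = 0.5, d = 0.4), "asymptote")
})

test_that("RH model reduces bit-identically to the 2PL at delta = 0", {
  th <- as.numeric(theta_grid())
  for (pars in list(c(0, 1), c(1.03, -1.29), c(-0.4, 2.2))) {
    expect_lt(max(abs(irf(item_rh(pars[1], pars[2], 0), th) -
                      irf(item_2pl(pars[1], pars[2]), th))), 1e-12)
  }
})

test_that("RH scale term equals 1 at theta = 0 for any delta", {
  for (d in c(-2.45, -0.5, 0, 1.3)) {
    expect_equal(irf(item_rh(0.7, 1.1, d), 0), plogis(0.7))
  }
})

test_that("RH curve for a strongly negative delta has the long left tail", {
  # the published mental-rotation exhibit: eta=1.03, xi=-1.29, delta=-2.45
  th <- as.numeric(theta_grid())
  it <- item_rh(1.03, -1.29, -2.45)
  p <- irf(it, th)
  # the right tail underflows to 0 in double precision (the Heywood collapse);
  # probabilities stay strictly interior at moderate theta
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[abs(th) <= 2] > 0 & p[abs(th) <= 2] < 1))
  # left tail decays far more slowly than the right: the IRF at theta = -4
  # is still well inside (0,1) while past theta* it has collapsed
  expect_gt(p[1], 0.5)
  expect_lt(p[length(p)], 0.05)
  # derivative concentrates in a narrow band (steep drop near theta ~ 1.5)
  d1 <- irf_deriv(it, th, 1L)
  expect_gt(max(abs(d1)), 5 * stats::median(abs(d1)))
})

test_that("RH non-monotone region is detected", {
  expect_true(irf_monotone(item_2pl(0, 1)))
  expect_true(irf_monotone(item_rh(0.94, 0.47, -0.12)))
  # strongly negative delta with a small positive slope turns the IRF around
  m <- irf_monotone(item_rh(-2, 0.5, -3))
  expect_false(isTRUE(m))
  expect_true(length(attr(m, "sign_changes")) >= 1L)
})

test_that("NRM probabilities are a proper simplex and reduce to the 2PL at K=2", {
  th <- as.numeric(theta_grid())
  it <- item_nrm(c(-0.5, 0.2, 0.3), c(-1, 0.3, 0.7))
  p <- irf(it, th)
  expect_true(all(p > 0 & p < 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  # equal parameters -> uniform
  u <- irf(item_nrm(rep(0, 4), rep(0, 4)), 0)
  expect_equal(as.numeric(u), rep(0.25, 4))
  # K=2 with (a, g) split reduces to 2PL(eta=a, xi=g) in category 2
  a <- 1.2; g <- 1.7
  n2 <- item_nrm(c(-a / 2, a / 2), c(-g / 2, g / 2))
  expect_lt(max(abs(irf(n2, th)[, 2] - irf(item_2pl(a, g), th))), 1e-12)
  expect_error(item_nrm(0, 0), "categories")
  expect_error(item_nrm(c(1, 1), c(0, 0)), "sum-to-zero")
  # baseline-category input is re-centered
  nb <- item_nrm(c(0, 1), c(0, 2), parameterization = "baseline")
  expect_equal(sum(nb$alpha), 0)
  expect_equal(sum(nb$gamma), 0)
})

test_that("analytic derivatives are exact: 2PL max slope is xi/4 at theta*", {
  expect_equal(irf_deriv(item_2pl(0, 4), 0), 1)
  expect_equal(irf_deriv(item_2pl(0, 5), 0), 1.25)
  # grid search confirms the maximum location
  th <- as.numeric(theta_grid())
  it <- item_2pl(1, 2)
  d1 <- irf_deriv(it, th, 1L)
  expect_lt(abs(th[which.max(d1)] - theta_star(it)), 0.01 + 1e-12)
  expect_equal(max(d1), it$xi / 4, tolerance = 1e-6)
  expect_error(irf_deriv(item_2pl(0, 1), 0, order = 3), "order")
})

test_that("NRM derivative vectors sum to zero (normalization constraint)", {
  th <- seq(-4, 4, by = 0.5)
  for (seed in 1:3) {
    set.seed(seed)
    K <- sample(2:6, 1)
    a <- rnorm(K); g <- rnorm(K)
    it <- item_nrm(a - mean(a), g - mean(g))
    expect_lt(max(abs(rowSums(irf_deriv(it, th, 1L)))), 1e-12)
    expect_lt(max(abs(rowSums(irf_deriv(it, th, 2L)))), 1e-12)
  }
})

test_that("numerical differentiation matches analytic derivatives on a fine grid", {
  th <- as.numeric(theta_grid())
  cases <- list(item_2pl(0, 1), item_2pl(-1, 2.5, c = 0.15),
                item_rh(0.8, 0.5, 0.9))
  interior <- 2:(length(th) - 1L)
  for (it in cases) {
    expect_lt(max(abs(numerical_derivative(irf(it, th), th, 1L) -
                      irf_deriv(it, th, 1L))), 1e-4)
    # second differences: the one-sided end stencils are only O(h) accurate,
    # so full-grid tolerance is looser than the interior one
    e2 <- abs(numerical_derivative(irf(it, th), th, 2L) - irf_deriv(it, th, 2L))
    expect_lt(max(e2), 1e-3)
    expect_lt(max(e2[interior]), 5e-4)
  }
  # NRM, column-wise
  it <- item_nrm(c(-0.3, 0.1, 0.2), c(-0.9, 0.2, 0.7))
  expect_lt(max(abs(numerical_derivative(irf(it, th), th, 1L) -
                    irf_deriv(it, th, 1L))), 1e-4)
  # a near-Heywood RH item is far steeper, so the finite-difference
  # truncation error (~ h^2 x curvature) needs a finer step to reach 1e-4
  it <- item_rh(1.03, -1.29, -2.45)
  err_coarse <- max(abs(numerical_derivative(irf(it, th), th, 1L) -
                        irf_deriv(it, th, 1L)))
  thf <- as.numeric(theta_grid(step = 5e-4))
  err_fine <- max(abs(numerical_derivative(irf(it, thf), thf, 1L) -
                      irf_deriv(it, thf, 1L)))
  expect_lt(err_fine, 1e-4)
  expect_lt(err_fine, err_coarse / 50)  # h^2 convergence
  expect_lt(max(abs(numerical_derivative(irf(it, thf), thf, 2L) -
                    irf_deriv(it, thf, 2L))), 1e-4)
})

test_that("numerical_derivative handles trivial curves and rejects bad grids", {
  th <- seq(-1, 1, by = 0.1)
  expect_equal(numerical_derivative(rep(2, length(th)), th, 1L), rep(0, length(th)))
  d <- numerical_derivative(3 * th + 1, th, 1L)
  expect_equal(d, rep(3, length(th)), tolerance = 1e-10)
  expect_error(numerical_derivative(1:2, c(0, 1)), "3 grid points")
  expect_error(numerical_derivative(1:4, c(0, 1, 1.5, 3)), "uniform")
})

test_that("item_set enforces one family and unique labels", {
  expect_error(item_set(list(item_2pl(0, 1), item_rh(0, 1, 0))), "one family")
  expect_error(item_set(list(item_2pl(0, 1), item_2pl(1, 1)),
                        labels = c("a", "a")), "unique")
  s <- item_set(list(item_2pl(0, 1), item_2pl(1, 1)))
  expect_equal(s$labels, c("item1", "item2"))
  expect_equal(length(s[2]), 1L)
  expect_equal(item_family(s), "2pl")
})

test_that("linear items reject non-positive unique variance with a diagnostic", {
  expect_error(linear_item(0, 1, 0, label = "bad"), "Heywood")
  expect_error(linear_item_std(1.2), "in \\(0, 1\\)")
  it <- linear_item_std(0.5)
  expect_equal(it$xi^2, 0.5)
  expect_equal(it$psi2, 0.5)
})
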