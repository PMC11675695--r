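test_that("information peaks land within one grid step of -eta/xi for the 2PL", {
  g <- theta_grid()
  cp <- information_peaks(item_information(item_2pl(1, 2), g), g)
  expect_length(cp$theta_star, 1L)
  expect_lt(abs(cp$theta_star - (-0.5)), 0.01 + 1e-12)
  expect_equal(cp$peak_info, 1, tolerance = 1e-4)
})

test_that("constant curves report a plateau, monotone curves a boundary maximum", {
  g <- theta_grid(-2, 2, 0.1)
  cp <- information_peaks(rep(4, length(g)), g)
  expect_true(cp$plateau)
  expect_length(cp$theta_star, 0L)
  # 2PL with theta* far outside the grid: information monotone on-grid
  cp2 <- information_peaks(item_information(item_2pl(-8, 1), g), g)
  expect_length(cp2$theta_star, 0L)
  expect_equal(cp2$boundary, "right")
  cp3 <- information_peaks(item_information(item_2pl(8, 1), g), g)
  expect_equal(cp3$boundary, "left")
})

test_that("two well-separated information bumps are both found (brute-force oracle)", {
  g <- theta_grid(-4, 4, 0.01)
  th <- as.numeric(g)
  mix <- function(t) item_information(item_2pl(2, 2), theta_grid(-4, 4, 0.01))
  curve <- item_information(item_2pl(2, 2), g) + item_information(item_2pl(-3, 1.5), g)
  cp <- information_peaks(curve, g)
  expect_length(cp$theta_star, 2L)
  # oracle: scan at 10x resolution
  fn <- function(t) {
    p1 <- irf(item_2pl(2, 2), t); d1 <- irf_deriv(item_2pl(2, 2), t, 1L)
    p2 <- irf(item_2pl(-3, 1.5), t); d2 <- irf_deriv(item_2pl(-3, 1.5), t, 1L)
    d1^2 / (p1 * (1 - p1)) + d2^2 / (p2 * (1 - p2))
  }
  for (ts in cp$theta_star) {
    loc <- brute_peak_scan(fn, ts - 0.2, ts + 0.2, step = 0.001)
    expect_lt(abs(ts - loc$theta), 0.011)
  }
})

test_that("plateau runs report their midpoint", {
  g <- theta_grid(0, 1, 0.1)
  y <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, 0, 0)
  cp <- information_peaks(y, g)
  expect_equal(cp$theta_star, 0.4)  # midpoint of the 3-3-3 run
  expect_equal(cp$peak_info, 3)
})

test_that("IFTI is a unit-sum share with the worked linear scenarios", {
  g <- theta_grid()
  its1 <- item_set(lapply(c(0.1, rep(0.2, 9)), linear_item_std))
  fr1 <- ifti(information_curves(its1, g))
  expect_equal(unique(fr1$ifti[, 1]), 0.2)
  its2 <- item_set(lapply(c(0.05, rep(0.2, 9)), linear_item_std))
  fr2 <- ifti(information_curves(its2, g))
  expect_equal(unique(fr2$ifti[, 1]), 19 / 55)       # = 0.3454... ~ 35%
  expect_equal(round(100 * unname(fr2$ifti[1, 1])), 35)
  # J identical items: 1/J each
  same <- make_2pl_set(rep(0.3, 5), rep(1.2, 5))
  frs <- ifti(information_curves(same, g))
  expect_lt(max(abs(frs$ifti - 0.2)), 1e-12)
  # x J scaling gives effective number of items
  frj <- ifti(information_curves(same, g), scale_J = TRUE)
  expect_lt(max(abs(frj$ifti - 1)), 1e-12)
})

test_that("IFTI normalization and scale invariance hold on random sets", {
  g <- theta_grid(-4, 4, 0.05)
  for (seed in 1:5) {
    set.seed(200 + seed)
    V <- sample(3:12, 1)
    its <- make_2pl_set(runif(V, -2, 2), runif(V, 0.4, 3))
    ic <- information_curves(its, g)
    fr <- ifti(ic)
    expect_lt(max(abs(rowSums(fr$ifti) - 1)), 1e-12)
    expect_true(all(fr$ifti >= 0 & fr$ifti <= 1))
    # common positive rescaling of every item's information leaves IFTI unchanged
    scale_fun <- exp(sin(as.numeric(g)))
    ic2 <- ic
    ic2$info <- ic$info * scale_fun
    expect_equal(ifti(ic2)$ifti, fr$ifti, tolerance = 1e-12)
  }
})

test_that("zero total information is masked, not divided by", {
  g <- theta_grid(-1, 1, 0.5)
  ic <- structure(list(theta = g, info = cbind(a = c(0, 1, 2, 1, 0),
                                               b = c(0, 1, 1, 1, 0)),
                       labels = c("a", "b")), class = "info_curves")
  fr <- ifti(ic)
  expect_equal(fr$masked, c(1L, 5L))
  expect_true(all(is.na(fr$ifti[c(1, 5), ])))
  expect_lt(max(abs(rowSums(fr$ifti[2:4, ]) - 1)), 1e-12)
})

test_that("dropping items renormalizes IFTI over the survivors", {
  g <- theta_grid(-3, 3, 0.05)
  its <- make_2pl_set(c(0, 0.5, -0.5), c(1, 1.5, 2))
  ic <- information_curves(its, g)
  # dropping nothing = identity
  expect_equal(ifti_drop(ic, character(0))$ifti, ifti(ic)$ifti)
  # two equal items, drop one -> survivor gets 1 everywhere
  two <- make_2pl_set(c(0, 0), c(1.3, 1.3))
  surv <- ifti_drop(information_curves(two, g), "item1")
  expect_lt(max(abs(surv$ifti - 1)), 1e-12)
  expect_lt(max(abs(rowSums(ifti_drop(ic, "item2")$ifti) - 1)), 1e-12)
  expect_error(ifti_drop(ic, c("item1", "item2", "item3")), "every item")
  expect_error(ifti_drop(ic, "nope"), "unknown item")
})

test_that("dropping the worst RH items promotes the next mental-rotation items", {
  # published 16-item calibration: drop MR3 and MR4, and MR6/MR8 take their
  # place as the dominant information sources in theta [1, 2]
  its <- rh_calibration()
  g <- theta_grid()
  th <- as.numeric(g)
  ic <- information_curves(its, g)
  full <- ifti(ic)
  red <- ifti_drop(ic, c("MR3", "MR4"))
  win <- th >= 1 & th <= 2
  for (lab in c("MR6", "MR8")) {
    expect_gt(mean(red$ifti[win, lab]), mean(full$ifti[win, lab]))
  }
  # the two survivors own most of the information there
  expect_gt(max(rowSums(red$ifti[win, c("MR6", "MR8")])), 0.8)
})

test_that("threshold object enforces the slope/info equivalence by default", {
  thr <- heywood_thresholds()
  expect_equal(thr$info_cut, thr$slope_cut^2 / 4)
  expect_equal(heywood_thresholds(slope_cut = 4)$info_cut, 4)
  expect_error(heywood_thresholds(slope_cut = -1))
})

test_that("flagging: slope and info criteria agree for plain 2PL items", {
  g <- theta_grid()
  its <- make_2pl_set(c(0, 0.5, 0), c(1, 2, 5.5), labels = c("a", "b", "c"))
  rep <- heywood_report(its, g)
  expect_s3_class(rep, "heywood_report")
  expect_equal(as.character(rep$flag[3]), "suspect")
  expect_true(grepl("slope", rep$criteria[3]) && grepl("info", rep$criteria[3]))
  expect_equal(rep$peak_info[3], 5.5^2 / 4, tolerance = 1e-6)
  expect_false(grepl("slope|info", rep$criteria[1]))
  # slope > 5 iff peak info > 6.25, across a sweep
  set.seed(42)
  for (i in 1:20) {
    xi <- runif(1, 3, 8)
    r1 <- heywood_report(make_2pl_set(0, xi), g)
    expect_equal(grepl("slope", r1$criteria), grepl("info", r1$criteria))
  }
})

test_that("IFTI flags: troublesome at 2/J, problematic at 4/J, worst flag wins", {
  g <- theta_grid()
  # J=16: one dominant item exceeding 4/16 = 0.25 in the centre
  its <- make_2pl_set(rep(0, 16), c(rep(1, 15), 3.4), labels = sprintf("i%02d", 1:16))
  rep <- heywood_report(its, g, theta_window = c(-1, 1))
  expect_equal(as.character(rep$flag[16]), "problematic")
  expect_gt(rep$ifti_max[16], 4 / 16)
  expect_false(any(rep$flag[1:15] == "problematic"))
  # all items identical -> IFTI = 1/J, no ifti flags anywhere
  same <- make_2pl_set(rep(0.2, 8), rep(1.1, 8))
  rs <- heywood_report(same, g)
  expect_true(all(rs$flag == "none"))
  # problematic implies the troublesome condition held (ifti_max > 2/J too)
  expect_true(all(rep$ifti_max[rep$flag == "problematic"] > 2 / 16))
})

test_that("theta_window restricts the IFTI criterion and must be nonempty", {
  g <- theta_grid()
  # low-slope item dominates only at extreme theta (like a weak item on a
  # strong test); ignoring the extremes clears it
  its <- make_2pl_set(c(0, 0, 0), c(0.4, 2, 2), labels = c("weak", "s1", "s2"))
  full <- heywood_report(its, g)
  expect_true(grepl("ifti", full$criteria[1]))
  inner <- heywood_report(its, g, theta_window = c(-1.5, 1.5))
  expect_false(grepl("ifti", inner$criteria[1]))
  expect_error(heywood_report(its, g, theta_window = c(9, 10)), "no grid points")
})

test_that("the published RH calibration flags the mental-rotation items", {
  rep <- heywood_report(rh_calibration())
  flagged <- rep$item_id[grepl("info", rep$criteria)]
  expect_true(all(c("MR3", "MR4") %in% flagged))
  expect_true(all(rep$flag[rep$item_id %in% c("MR3", "MR4")] == "problematic"))
  # the theta-star of the spike sits between 1 and 2
  mr <- rep[rep$item_id == "MR3", ]
  expect_true(mr$theta_star >= 0.99 && mr$theta_star < 2)
  # regular verbal-reasoning items are not info-flagged
  expect_false(any(grepl("info", rep$criteria[rep$item_id %in%
                                              c("RE4", "RE16", "RE17", "RE19")])))
})
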