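# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: dense rectangular posterior integration
# for EAP, and a brute-force fine-grid scan for information peaks.

# posterior mean/sd of theta by 10,001-point rectangular integration
dense_eap_oracle <- function(items, y, n_grid = 10001L, bounds = c(-6, 6)) {
  th <- seq(bounds[1], bounds[2], length.out = n_grid)
  ll <- rep(0, n_grid)
  for (v in seq_len(items$V)) {
    if (is.na(y[v])) next
    p <- irf(items$items[[v]], th)
    ll <- ll + if (y[v] == 1) log(p) else log(1 - p)
  }
  w <- exp(ll - max(ll)) * stats::dnorm(th)
  w <- w / sum(w)
  m <- sum(w * th)
  list(mean = m, sd = sqrt(sum(w * th^2) - m^2))
}

# locate information maxima by scanning a grid `factor` times finer
brute_peak_scan <- function(info_fun, lo = -4, hi = 4, step = 0.001) {
  th <- seq(lo, hi, by = step)
  y <- info_fun(th)
  i <- which(y == max(y))[1L]
  list(theta = th[i], height = y[i])
}

# quadrature value of the marginal proportion correct E[pi(Theta)]
marginal_pbar <- function(item, n_grid = 2001L) {
  th <- seq(-6, 6, length.out = n_grid)
  w <- stats::dnorm(th)
  sum(w * irf(item, th)) / sum(w)
}

make_2pl_set <- function(eta, xi, labels = NULL) {
  item_set(mapply(item_2pl, eta, xi, SIMPLIFY = FALSE), labels = labels)
}
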