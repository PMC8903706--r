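# Independent oracles used across the suite. Each is a different route to
# the quantity than the implementation under test.

# Hardy-Weinberg 1-df chi-square via the closed-form disequilibrium
# identity chi2 = n (4 n_AA n_aa - n_Aa^2)^2 / ((2 n_AA + n_Aa)^2 (2 n_aa + n_Aa)^2)
hwe_chi2_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  d1 <- 2 * n_AA + n_Aa
  d2 <- 2 * n_aa + n_Aa
  if (d1 == 0 || d2 == 0) return(0)
  n * (4 * n_AA * n_aa - n_Aa^2)^2 / (d1^2 * d2^2)
}

# Fieller limits by dense grid search + root refinement of the inverted
# test statistic (beta_zy - t beta_zx)^2 <= z^2 (se_zy^2 - 2 t cov + t^2 se_zx^2)
fieller_grid_oracle <- function(beta_zy, se_zy, beta_zx, se_zx,
                                covariance = 0, alpha = 0.05,
                                lim = 500, step = 0.01) {
  z2 <- stats::qnorm(1 - alpha / 2)^2
  f <- function(t) (beta_zy - t * beta_zx)^2 -
    z2 * (se_zy^2 - 2 * t * covariance + t^2 * se_zx^2)
  th <- seq(-lim, lim, by = step)
  s <- sign(f(th))
  w <- which(diff(s) != 0)
  roots <- vapply(w, function(i)
    stats::uniroot(f, c(th[i], th[i + 1L]), tol = 1e-12)$root, numeric(1))
  sort(roots)
}

# Two-group exponential survival data with a known hazard ratio
make_two_group_surv <- function(n_per_arm, hr, base_rate = 0.02,
                                admin = 60) {
  grp <- rep(0:1, each = n_per_arm)
  rate <- base_rate * ifelse(grp == 1, hr, 1)
  tt <- stats::rexp(2 * n_per_arm, rate)
  list(time = pmin(tt, admin), event = as.integer(tt <= admin), group = grp)
}

# Restricted-mean survival recomputed from scratch (sorted data, product
# limit, rectangle integral) without using the package's KM code paths
rmst_oracle <- function(time, event, horizon) {
  ut <- sort(unique(time[event == 1]))
  surv <- 1; s_prev <- 1; t_prev <- 0; area <- 0
  for (u in ut) {
    if (u > horizon) break
    area <- area + s_prev * (u - t_prev)
    n_risk <- sum(time >= u)
    d <- sum(time == u & event == 1)
    s_prev <- s_prev * (1 - d / n_risk)
    t_prev <- u
  }
  area + s_prev * (horizon - t_prev)
}
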