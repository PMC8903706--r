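# Endpoint association models: Cox partial likelihood, logistic
# regression, Kaplan-Meier/log-rank, blood-pressure control rule.

test_that("Cox fit agrees with the established survival fitter on tied data", {
  skip_if_not_installed("survival")
  set.seed(101)
  worst <- 0
  for (r in 1:50) {
    n <- sample(50:200, 1)
    x <- rnorm(n); z1 <- rnorm(n); z2 <- rbinom(n, 1, 0.4)
    tt <- round(rexp(n, exp(0.5 * x - 0.3 * z1)) * 10) + 1  # rounded: ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 3) next
    f1 <- fit_cox(tt, ev, x, covariates = data.frame(z1 = z1, z2 = z2))
    f2 <- survival::coxph(survival::Surv(tt, ev) ~ x + z1 + z2, ties = "efron")
    worst <- max(worst, max(abs(f1$coefficients - coef(f2))))
  }
  expect_lt(worst, 1e-6)
})

test_that("Cox recovers a known hazard ratio of 2 on exponential data", {
  set.seed(202)
  d <- make_two_group_surv(1000, hr = 2)
  f <- fit_cox(d$time, d$event, d$group, term = "group")
  expect_equal(f$status, "converged")
  expect_lt(abs(f$estimate$beta - log(2)), 2 * f$estimate$se)
})

test_that("Cox estimate is centred at zero for a permuted exposure", {
  set.seed(303)
  d <- make_two_group_surv(400, hr = 2)
  betas <- replicate(50, {
    f <- fit_cox(d$time, d$event, sample(d$group), term = "group")
    f$estimate$beta
  })
  expect_gt(t.test(betas)$p.value, 0.01)
})

test_that("Cox degenerate inputs produce explicit failure statuses", {
  f <- fit_cox(1:10, rep(0L, 10), rnorm(10))
  expect_equal(f$status, "no_events")
  expect_null(f$estimate)
  # covariate perfectly ordering the events: monotone partial likelihood
  f2 <- fit_cox(1:30, rep(1L, 30), -(1:30))
  expect_false(f2$status == "converged")
  expect_error(fit_cox(c(-1, 2, 3), c(1, 1, 0), rnorm(3)), "negative")
})

test_that("logistic fit matches the 2x2 closed form and the glm oracle", {
  # 2x2 table (a, b; c, d): log OR = log(ad/bc), Woolf se
  a <- 40; b <- 25; cc <- 15; d <- 60
  y <- rep(c(1, 1, 0, 0), c(a, b, cc, d))
  x <- rep(c(1, 0, 1, 0), c(a, b, cc, d))
  f <- fit_logistic(y, x)
  expect_equal(f$estimate$beta, log(a * d / (b * cc)), tolerance = 1e-8)
  expect_equal(f$estimate$se, sqrt(1 / a + 1 / b + 1 / cc + 1 / d),
               tolerance = 1e-8)

  skip_if_not_installed("survival")  # oracle block shares the seed setup
  set.seed(404)
  worst <- 0
  for (r in 1:50) {
    n <- sample(50:200, 1)
    xx <- rnorm(n); z <- rnorm(n)
    yy <- rbinom(n, 1, plogis(-0.5 + 0.8 * xx - 0.4 * z))
    if (length(unique(yy)) < 2) next
    f1 <- fit_logistic(yy, xx, covariates = data.frame(z = z))
    if (f1$status != "converged") next
    f2 <- glm(yy ~ xx + z, family = binomial)
    worst <- max(worst, max(abs(f1$coefficients - coef(f2))))
  }
  expect_lt(worst, 1e-6)
})

test_that("logistic odds ratio is centred at 1 for an unrelated predictor", {
  set.seed(505)
  betas <- replicate(60, {
    y <- rbinom(300, 1, 0.5)
    fit_logistic(y, rnorm(300))$estimate$beta
  })
  expect_gt(t.test(betas)$p.value, 0.01)
})

test_that("separation is reported explicitly and the Firth mode resolves it", {
  x <- c(rnorm(30, -2), rnorm(30, 2))
  y <- as.integer(x > 0)
  f <- fit_logistic(y, x)
  expect_equal(f$status, "separation")
  expect_match(f$advice, "penalized")
  fp <- fit_logistic(y, x, penalized = TRUE)
  expect_equal(fp$status, "converged")
  expect_true(is.finite(fp$estimate$beta))
  expect_error(fit_logistic(rep(1, 10), rnorm(10)), "both classes")
})

test_that("log-rank is zero for identical groups and matches survival", {
  tt <- c(5, 8, 12, 20, 33); ev <- c(1, 0, 1, 1, 0)
  k <- km_logrank(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_lt(k$logrank_stat, 1e-12)
  expect_equal(unname(k$restricted_mean[1]), unname(k$restricted_mean[2]))

  skip_if_not_installed("survival")
  set.seed(606)
  d <- make_two_group_surv(150, hr = 1.8)
  k2 <- km_logrank(round(d$time) + 1, d$event, d$group)
  sd_ <- survival::survdiff(
    survival::Surv(round(d$time) + 1, d$event) ~ d$group)
  expect_equal(k2$logrank_stat, sd_$chisq, tolerance = 1e-8)
})

test_that("log-rank is invariant to time rescaling and label swap", {
  set.seed(707)
  d <- make_two_group_surv(200, hr = 2)
  k1 <- km_logrank(d$time, d$event, d$group)
  k2 <- km_logrank(d$time * 3.7, d$event, d$group)
  k3 <- km_logrank(d$time, d$event, 1 - d$group)
  expect_equal(k1$logrank_stat, k2$logrank_stat, tolerance = 1e-12)
  expect_equal(k1$logrank_stat, k3$logrank_stat, tolerance = 1e-12)
  expect_error(km_logrank(d$time, d$event, rep(1, length(d$time))),
               "two levels")
})

test_that("log-rank detects a doubled hazard with the expected power", {
  set.seed(808)
  hits <- replicate(200, {
    d <- make_two_group_surv(500, hr = 2)
    km_logrank(d$time, d$event, d$group)$p < 0.001
  })
  # Schoenfeld approximation: ~800 events, sqrt(d/4)*ln2 ~ 9.8 sd, so the
  # 0.001-level test should essentially always reject
  expect_gte(mean(hits), 0.95)
})

test_that("restricted mean survival equals the step-curve integral", {
  set.seed(909)
  d <- make_two_group_surv(120, hr = 1.5)
  k <- km_logrank(d$time, d$event, d$group)
  for (g in c(0, 1)) {
    expect_equal(unname(k$restricted_mean[as.character(g)]),
                 rmst_oracle(d$time[d$group == g], d$event[d$group == g],
                             k$horizon),
                 tolerance = 1e-10)
  }
  expect_true(all(k$restricted_mean <= k$horizon))
})

test_that("GRS median split orders event-free survival as the causal model implies", {
  st <- simulate_two_sample_study(sim_config(seed = 2718))
  oc <- st$outcome$cohort
  split <- factor(ifelse(oc$grs >= median(oc$grs), "ge_median", "lt_median"))
  k <- km_logrank(oc$time_combined, oc$event_combined, split)
  # higher genetically predicted exposure is protective: >= median survives longer
  expect_gt(k$restricted_mean[["ge_median"]], k$restricted_mean[["lt_median"]])
})

test_that("blood-pressure control classification is a strict monotone threshold rule", {
  expect_equal(classify_bp_control(150, 80, "JNC8"), 1L)   # boundary fails
  expect_equal(classify_bp_control(149, 89, "JNC8"), 0L)   # strict inequality
  expect_equal(classify_bp_control(145, 85, "ADA"), 1L)
  expect_equal(classify_bp_control(139, 89, "ADA"), 0L)
  expect_equal(classify_bp_control(145, 95, "JNC8"), 1L)   # diastolic failure
  expect_equal(classify_bp_control(145, 95, "JNC8", systolic_only = TRUE), 0L)
  expect_true(is.na(classify_bp_control(NA, 80, "JNC8")))
  expect_error(classify_bp_control(-10, 80), "positive")
  # monotone non-decreasing in both pressures
  grid <- expand.grid(sbp = seq(90, 200, by = 5), dbp = seq(50, 120, by = 5))
  fl <- classify_bp_control(grid$sbp, grid$dbp, "JNC8")
  for (dd in unique(grid$dbp))
    expect_true(all(diff(fl[grid$dbp == dd][order(grid$sbp[grid$dbp == dd])]) >= 0))
  for (ss in unique(grid$sbp))
    expect_true(all(diff(fl[grid$sbp == ss][order(grid$dbp[grid$sbp == ss])]) >= 0))
})
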