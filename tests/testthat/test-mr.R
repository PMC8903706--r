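# Wald ratio and Fieller confidence interval: closed form, degeneracies,
# equivariances, per-SNP and subgroup sensitivity machinery.

test_that("Wald ratio reproduces the printed worked-example quotients", {
  # combined CVD: per-allele HR 0.90 over B = 0.66 ng/mL per allele
  expect_true(exp(wald_ratio(log(0.90), 0.66)) > 0.85 &&
                exp(wald_ratio(log(0.90), 0.66)) < 0.86)
  # myocardial infarction: per-allele HR 0.83 over the same denominator
  expect_true(exp(wald_ratio(log(0.83), 0.66)) > 0.75 &&
                exp(wald_ratio(log(0.83), 0.66)) < 0.76)
  expect_equal(exp(wald_ratio(0, 0.66)), 1)
  expect_error(wald_ratio(0.1, 0), "zero")
})

test_that("Wald ratio sign and unit-scaling equivariances hold", {
  set.seed(1)
  for (r in 1:20) {
    bzy <- rnorm(1); bzx <- rnorm(1, 1, 0.3)
    th <- wald_ratio(bzy, bzx)
    expect_equal(sign(th), sign(bzy) * sign(bzx))
    expect_equal(wald_ratio(bzy, 2 * bzx), th / 2)  # doubling exposure units
  }
})

test_that("Fieller interval matches the printed combined-CVD estimate", {
  fc <- fieller_ci(log(0.90), se_from_ci(log(0.84), log(0.96)),
                   0.66, se_from_ci(0.51, 0.82))
  expect_equal(fc$status, "bounded")
  expect_lt(abs(fc$or_low - 0.75), 0.01)
  expect_lt(abs(fc$or_high - 0.95), 0.01)
  expect_lt(fc$g, 1)
})

test_that("Fieller limits converge to the delta-method interval as se_zx -> 0", {
  bzy <- log(0.9); sezy <- 0.034; bzx <- 0.66
  prev_dev <- Inf
  for (sezx in c(0.05, 0.01, 0.001, 1e-5)) {
    fi <- fieller_ci(bzy, sezy, bzx, sezx)
    de <- fieller_ci(bzy, sezy, bzx, sezx, method = "delta")
    dev <- max(abs(c(fi$ci_low - de$ci_low, fi$ci_high - de$ci_high)))
    expect_lte(dev, prev_dev + 1e-15)
    prev_dev <- dev
  }
  expect_lt(prev_dev, 1e-8)
  # exact limit: zero denominator uncertainty reduces to theta +/- z se_zy/|bzx|
  d0 <- fieller_ci(bzy, sezy, bzx, 0)
  th <- bzy / bzx
  expect_equal(d0$ci_low, th - qnorm(0.975) * sezy / abs(bzx), tolerance = 1e-8)
  expect_equal(d0$ci_high, th + qnorm(0.975) * sezy / abs(bzx), tolerance = 1e-8)
})

test_that("weak denominators yield explicit unbounded or exclusive sets", {
  # g > 1 with a clearly nonzero numerator: exclusive set
  fc <- fieller_ci(0.8, 0.1, 0.1, 0.2)
  expect_gt(fc$g, 1)
  expect_equal(fc$status, "exclusive")
  expect_true(is.na(fc$ci_low))
  # both numerator and denominator null: the whole line
  fc2 <- fieller_ci(0.05, 0.2, 0.05, 0.2)
  expect_equal(fc2$status, "unbounded")
  expect_identical(fc2$ci_low, -Inf)
  # oracle confirmation for the exclusive case: the excluded region is
  # where the inverted test rejects
  z2 <- qnorm(0.975)^2
  tstat <- function(t) (0.8 - t * 0.1)^2 / (0.1^2 + t^2 * 0.2^2)
  inside <- mean(sapply(seq(fc$excluded_region[1] + 1e-3,
                            fc$excluded_region[2] - 1e-3,
                            length.out = 50), tstat) > z2)
  expect_equal(inside, 1)
  expect_error(fieller_ci(0.5, -0.1, 0.6, 0.1), "positive")
})

test_that("Fieller limits equal the grid-search inversion oracle", {
  set.seed(314)
  for (r in 1:20) {
    bzx <- runif(1, 0.2, 1.5); sezx <- runif(1, 0.02, 0.3)
    bzy <- rnorm(1, 0, 0.3); sezy <- runif(1, 0.02, 0.3)
    fc <- fieller_ci(bzy, sezy, bzx, sezx)
    roots <- fieller_grid_oracle(bzy, sezy, bzx, sezx)
    if (fc$status == "bounded" && length(roots) == 2) {
      expect_equal(c(fc$ci_low, fc$ci_high), roots, tolerance = 1e-4)
    }
  }
})

test_that("grs_mr composes the ratio, guards scales and flags weak instruments", {
  fs <- assoc_estimate("grs", 0.66, se_from_ci(0.51, 0.82), scale = "linear")
  num <- assoc_estimate("grs", log(0.90), se_from_ci(log(0.84), log(0.96)),
                        scale = "log-hazard")
  w <- grs_mr(fs, num)
  expect_s3_class(w, "wald_result")
  expect_equal(w$or_estimate, exp(log(0.90) / 0.66))
  expect_false(w$weak_instrument)
  expect_identical(w$covariance_zy_zx, 0)
  expect_true(w$ci_low <= w$or_estimate && w$or_estimate <= w$ci_high)

  # scale guards: a denominator on a ratio scale is a different quantity
  expect_error(grs_mr(num, num), "linear exposure scale")
  expect_error(grs_mr(fs, fs), "log-hazard or log-odds")
  # weak first stage is flagged but still reported
  weak_fs <- assoc_estimate("grs", 0.2, 0.15, scale = "linear")
  w2 <- grs_mr(weak_fs, num)
  expect_true(w2$weak_instrument)
})

test_that("per-SNP ratios are mutually consistent under a shared causal model", {
  set.seed(42)
  # larger derivation sample so every single-SNP first stage is strong
  # (bounded Fieller sets); the check is about mutual consistency
  overlap <- replicate(40, {
    g_d <- simulate_genotypes(c(0.45, 0.40, 0.50), 8000,
                              snp_ids = c("a", "b", "c"))
    x_d <- simulate_exposure(g_d, 0.66, 5.47)
    g_o <- simulate_genotypes(c(0.45, 0.40, 0.50), 2500,
                              snp_ids = c("a", "b", "c"))
    x_o <- simulate_exposure(g_o, 0.66, 5.47)
    oc <- simulate_outcomes(x_o, baseline_hazard = 0.0019)
    ex <- per_snp_exposure_fits(g_d, x_d)
    ep <- do.call(rbind, lapply(c("a", "b", "c"), function(s) {
      f <- fit_cox(oc$time_combined, oc$event_combined,
                   unclass(g_o)[, s], term = s)
      data.frame(snp_id = s, beta = f$estimate$beta, se = f$estimate$se)
    }))
    res <- per_snp_mr(ex, ep, weak_p_threshold = 1)
    lo <- log(res$ci_low); hi <- log(res$ci_high)
    all(!is.na(lo)) &&
      all(combn(3, 2, function(ij) lo[ij[1]] <= hi[ij[2]] &&
                  lo[ij[2]] <= hi[ij[1]]))
  })
  expect_gte(mean(overlap), 0.95)
})

test_that("per-SNP machinery flags null first stages and mismatched panels", {
  ex <- data.frame(snp_id = c("a", "b"), beta = c(0.6, 0), se = c(0.1, 0.1),
                   p = c(1e-5, 0.9))
  ep <- data.frame(snp_id = c("a", "b"), beta = c(-0.1, -0.1),
                   se = c(0.03, 0.03))
  res <- per_snp_mr(ex, ep)
  expect_equal(res$status[res$snp_id == "b"], "undefined")
  expect_true(res$weak_instrument[res$snp_id == "b"])
  expect_false(res$weak_instrument[res$snp_id == "a"])
  expect_error(per_snp_mr(ex, ep[1, ]), "different SNP sets")
})

test_that("vitamin D status categories split at 20 and 30 ng/mL", {
  s <- vitd_status(c(10, 19.99, 20, 29.99, 30, 45))
  expect_equal(as.character(s),
               c("deficient", "deficient", "insufficient", "insufficient",
                 "sufficient", "sufficient"))
})

test_that("subgroup MR populates strata, tolerates empty ones, finds heterogeneity", {
  set.seed(77)
  st <- simulate_two_sample_study(sim_config(seed = 8))
  oc <- st$outcome$cohort
  fs <- first_stage_fit(st$derivation$cohort$grs,
                        st$derivation$cohort$exposure_25ohd)
  # threshold below every exposure: a single populated stratum
  res0 <- subgroup_mr(oc, fs, threshold = 0.5)
  expect_equal(res0$deficient$status, "no_events_in_stratum")
  expect_s3_class(res0$non_deficient, "wald_result")
  # three-level classification at 20 and 30 ng/mL
  res3 <- subgroup_mr(oc, fs, threshold = c(20, 30))
  expect_setequal(names(res3), c("deficient", "insufficient", "sufficient"))

  # designed heterogeneity: the causal slope acts only below 20 ng/mL.
  # Stratification on the exposure strongly attenuates the within-stratum
  # genotype-exposure gradient, so the designed contrast is deliberately
  # large and event-rich to make the recovery check well powered.
  hits <- replicate(25, {
    g_o <- simulate_genotypes(c(0.45, 0.40, 0.50), 8000,
                              snp_ids = c("a", "b", "c"))
    x <- simulate_exposure(g_o, 0.66, 5.47)
    slope <- ifelse(x < 20, -1.0, 0)
    h <- 0.01 * exp(slope * (x - 20))
    tt <- rexp(8000, h); cfu <- pmin(rexp(8000, 0.0123), 120)
    coh <- data.frame(grs = score_grs(g_o, c("a", "b", "c")),
                      exposure_25ohd = x, time_combined = pmin(tt, cfu),
                      event_combined = as.integer(tt <= cfu))
    r <- subgroup_mr(coh, fs, threshold = 20)
    abs(log(r$deficient$or_estimate)) > abs(log(r$non_deficient$or_estimate))
  })
  expect_gte(mean(hits), 0.9)
})
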