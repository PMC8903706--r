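# Instrument construction: Hardy-Weinberg QC, LD, allele scoring,
# SNP selection, first-stage strength, confounder independence.

test_that("HWE chi-square matches hand computations and degenerate cases", {
  expect_equal(hwe_chi_square(25, 50, 25)$chi2, 0)
  h <- hwe_chi_square(30, 40, 30)  # p-hat 0.5, expected (25, 50, 25)
  expect_equal(h$chi2, 4.0, tolerance = 1e-12)
  expect_equal(h$p, pchisq(4, 1, lower.tail = FALSE))
  mono <- hwe_chi_square(0, 0, 100)
  expect_equal(mono$chi2, 0)
  expect_true(mono$monomorphic)
  expect_error(hwe_chi_square(-1, 0, 5), "non-negative")
  expect_error(hwe_chi_square(0, 0, 0), "no genotyped")
})

test_that("HWE statistic equals the closed-form oracle on all triples n <= 30", {
  for (n in 1:30) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        cc <- n - a - b
        expect_equal(hwe_chi_square(a, b, cc)$chi2, hwe_chi2_oracle(a, b, cc),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("pairwise LD r2 behaves at the self, independence and degenerate limits", {
  set.seed(42)
  a <- rbinom(1e5, 2, 0.4)
  expect_equal(pairwise_ld_r2(a, a), 1)
  b <- rbinom(1e5, 2, 0.5)
  expect_lt(pairwise_ld_r2(a, b), 0.001)
  expect_warning(r2 <- pairwise_ld_r2(rep(1L, 10), rbinom(10, 2, .5)),
                 "zero dosage variance")
  expect_true(is.na(r2))
  expect_error(pairwise_ld_r2(1:3, 1:4), "equal length")
})

test_that("latent LD generation lands near the requested dosage correlation", {
  set.seed(7)
  g <- simulate_genotypes(c(0.4, 0.5), 1e5, snp_ids = c("s1", "s2"),
                          ld_pairs = data.frame(a = "s1", b = "s2", rho = 0.6))
  expect_equal(pairwise_ld_r2(g[, 1], g[, 2]), 0.16, tolerance = 0.2)
  expect_error(
    simulate_genotypes(c(0.4, 0.4), 10, snp_ids = c("s1", "s2"),
                       ld_pairs = data.frame(a = "s1", b = "s2", rho = 1)),
    "positive-definite")
})

test_that("allele score sums dosages, ranges 0-6 and excludes missing listwise", {
  g <- matrix(c(2L, 0L, 1L, NA,
                2L, 0L, 0L, 1L,
                2L, 0L, 2L, 1L), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  class(g) <- c("genotype_matrix", class(g))
  s <- score_grs(g, c("a", "b", "c"))
  expect_equal(unname(s[1:3]), c(6L, 0L, 3L))
  expect_true(is.na(s[4]))
  expect_equal(attr(s, "n_excluded"), 1L)
  expect_error(score_grs(g, c("a", "zz")), "zz")
})

test_that("GRS mean converges to twice the summed allele frequencies under HWE", {
  set.seed(11)
  freqs <- c(0.45, 0.40, 0.50)
  g <- simulate_genotypes(freqs, 1e5, snp_ids = c("a", "b", "c"))
  s <- score_grs(g, c("a", "b", "c"))
  expect_equal(mean(s), 2 * sum(freqs), tolerance = 0.01)
  expect_equal(sd(s), sqrt(2 * sum(freqs * (1 - freqs))), tolerance = 0.02)
})

test_that("selection recovers the causal SNPs, prunes LD and handles null panels", {
  set.seed(303)
  n <- 1460
  freqs <- c(0.45, 0.40, 0.50, 0.3, 0.35, 0.25)
  ids <- paste0("s", 1:6)
  effects <- c(1.2, 1.2, 1.2, 0, 0, 0)  # strong causal trio for the recovery check
  hits <- logical(200)
  for (r in 1:200) {
    g <- simulate_genotypes(freqs, n, snp_ids = ids)
    x <- pmax(20.7 + drop(unclass(g) %*% effects) + rnorm(n, 0, 5.47), 1)
    fits <- per_snp_exposure_fits(g, x)
    sel <- select_instrument_snps(fits, ld_matrix(g))
    hits[r] <- setequal(sel$selected, ids[1:3])
  }
  expect_gte(mean(hits), 0.95)

  # no SNP past the screening threshold: empty selection, explicit status
  null_fits <- data.frame(snp_id = ids, beta = rnorm(6, 0, 0.05),
                          se = 0.2, t = rnorm(6, 0, 0.3),
                          p = runif(6, 0.2, 0.9), n = 400)
  ld0 <- diag(1, 6); dimnames(ld0) <- list(ids, ids)
  sel0 <- select_instrument_snps(null_fits, ld0)
  expect_identical(sel0$selected, character(0))
  expect_identical(sel0$status, "no_snp_passes_alpha")

  # perfectly duplicated SNP: only one of the pair retained
  g2 <- unclass(simulate_genotypes(c(0.4, 0.5), 800, snp_ids = c("p", "q")))
  g3 <- cbind(g2, r = g2[, "p"])
  class(g3) <- c("genotype_matrix", class(g3))
  x <- pmax(20 + 1.5 * g3[, "p"] + 0.8 * g3[, "q"] + rnorm(800, 0, 3), 1)
  sel2 <- select_instrument_snps(per_snp_exposure_fits(g3, x), ld_matrix(g3))
  expect_length(intersect(c("p", "r"), sel2$selected), 1L)
  expect_true(any(grepl("LD with", sel2$dropped$reason)))
})

test_that("first stage recovers a noiseless slope and satisfies the F closed form", {
  grs <- rep(0:6, length.out = 210)
  # lm warns that the fit is essentially perfect - that is the point here
  fit <- suppressWarnings(first_stage_fit(grs, 0.5 * grs + 10))
  expect_equal(fit$estimate$beta, 0.5, tolerance = 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-12)

  set.seed(5)
  g <- simulate_genotypes(c(0.45, 0.40, 0.50), 1460, snp_ids = c("a", "b", "c"))
  s <- score_grs(g, c("a", "b", "c"))
  x <- simulate_exposure(g, 0.66, 5.47)
  f <- first_stage_fit(s, x)
  # univariable closed form F = R^2 (n - 2) / (1 - R^2)
  expect_equal(f$f_statistic,
               f$r_squared * (f$n - 2) / (1 - f$r_squared), tolerance = 1e-10)
  expect_equal(f$estimate$beta, 0.66, tolerance = 0.4)

  expect_error(first_stage_fit(s, x, covariates = data.frame(dup = s)),
               "collinear")
})

test_that("first-stage slope test holds its 5% size under the null", {
  set.seed(99)
  n <- 1460
  rej <- logical(1000)
  for (r in seq_along(rej)) {
    g <- simulate_genotypes(c(0.45, 0.40, 0.50), n, snp_ids = c("a", "b", "c"))
    s <- score_grs(g, c("a", "b", "c"))
    x <- simulate_exposure(g, 0, 5.47)    # null instrument
    rej[r] <- first_stage_fit(s, x)$estimate$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("a null instrument yields near-zero R^2 and F near 1 in expectation", {
  set.seed(13)
  g <- simulate_genotypes(c(0.45, 0.40, 0.50), 5000, snp_ids = c("a", "b", "c"))
  s <- score_grs(g, c("a", "b", "c"))
  x <- simulate_exposure(g, 0.66, residual_sd = 500)  # noise swamps the signal
  f <- first_stage_fit(s, x)
  expect_lt(f$r_squared, 0.002)
  expect_lt(f$f_statistic, 8)
})

test_that("confounder screen: null p-values uniform, deterministic leak flagged", {
  set.seed(21)
  ps <- replicate(200, {
    g <- rbinom(500, 6, 0.45)
    confounder_independence(g, data.frame(cv = rnorm(500)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  g <- rbinom(500, 6, 0.45)
  # the leak covariate IS the score, so lm warns about a perfect fit
  res <- suppressWarnings(confounder_independence(
    g, data.frame(leak = g, ok = rnorm(500)), threshold = 0.20))
  expect_true(res$flagged[res$covariate == "leak"])
  expect_lt(res$p[res$covariate == "leak"], 1e-10)
  expect_warning(
    res2 <- confounder_independence(g, data.frame(const = rep(1, 500))),
    "constant")
  expect_null(res2)
})

test_that("build_instrument assembles QC, selection and first stage on a panel", {
  set.seed(31)
  panel <- candidate_panel_specs()
  g <- simulate_genotypes(panel$specs$effect_allele_freq, 1460,
                          snp_ids = panel$specs$snp_id,
                          ld_pairs = panel$ld_pairs)
  x <- simulate_exposure(g, panel$specs$per_allele_effect, 5.2)
  rep_ <- build_instrument(g, x, covariates = data.frame(bmi = rnorm(1460, 25, 4)))
  expect_equal(nrow(rep_$qc), 12L)
  expect_true(all(rep_$qc$hwe_chi2 >= 0))
  expect_length(rep_$selection$selected, 3L)
  expect_s3_class(rep_$first_stage, "first_stage")
  expect_true(all(diag(rep_$ld_matrix) == 1))
  expect_true(isSymmetric(rep_$ld_matrix))
})
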