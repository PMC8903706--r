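#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg proportions implied by the estimated allele
#' frequency `p = (2 n_AA + n_Aa) / (2 n)`: expected counts `n p^2`,
#' `2 n p (1 - p)`, `n (1 - p)^2`, statistic `sum((O - E)^2 / E)` without
#' continuity correction. A monomorphic locus (all subjects carry the same
#' allele) is a defined degenerate case: the statistic is 0 and the result
#' carries a `monomorphic` flag rather than failing.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = two effect alleles).
#' @return list with `chi2`, `p` (upper-tail, 1 df), `effect_allele_freq`,
#'   `expected` counts, and logical `monomorphic`.
#' @export
hwe_chi_square <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("no genotyped subjects")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p = 1, effect_allele_freq = p,
                expected = c(AA = n * p^2, Aa = 2 * n * p * (1 - p),
                             aa = n * (1 - p)^2),
                monomorphic = TRUE))
  }
  expected <- c(AA = n * p^2, Aa = 2 * n * p * (1 - p), aa = n * (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       effect_allele_freq = p, expected = expected, monomorphic = FALSE)
}

#' Per-SNP genotype quality-control report
#'
#' Genotype counts, effect-allele frequency and the Hardy-Weinberg test
#' for every SNP in a dosage matrix.
#'
#' @param genotypes dosage matrix (0/1/2, `NA` missing).
#' @return data.frame with one row per SNP: counts `n_AA`/`n_Aa`/`n_aa`
#'   (AA = dosage 2), `n_missing`, `effect_allele_freq`, `hwe_chi2`,
#'   `hwe_p`, `monomorphic`.
#' @export
snp_qc_report <- function(genotypes) {
  g <- unclass(genotypes)
  rows <- lapply(colnames(g), function(s) {
    d <- g[, s]
    n2 <- sum(d == 2L, na.rm = TRUE)
    n1 <- sum(d == 1L, na.rm = TRUE)
    n0 <- sum(d == 0L, na.rm = TRUE)
    h <- hwe_chi_square(n2, n1, n0)
    data.frame(snp_id = s, n_AA = n2, n_Aa = n1, n_aa = n0,
               n_missing = sum(is.na(d)),
               effect_allele_freq = h$effect_allele_freq,
               hwe_chi2 = h$chi2, hwe_p = h$p, monomorphic = h$monomorphic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Squared Pearson correlation of two dosage vectors over
#' pairwise-complete observations.
#'
#' @param dosage_a,dosage_b equal-length dosage vectors.
#' @return r^2 in `[0, 1]`; `NA` with a warning when a vector has zero
#'   variance over the complete pairs.
#' @export
pairwise_ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop("dosage vectors must have equal length")
  ok <- stats::complete.cases(dosage_a, dosage_b)
  if (sum(ok) < 2L) stop("need at least 2 complete genotype pairs")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero dosage variance; LD r^2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Pairwise LD matrix over all SNPs
#'
#' @param genotypes dosage matrix.
#' @return Symmetric matrix of r^2 with unit diagonal; `NA` entries mark
#'   pairs involving a zero-variance SNP.
#' @export
ld_matrix <- function(genotypes) {
  g <- unclass(genotypes)
  k <- ncol(g)
  m <- diag(1, k)
  dimnames(m) <- list(colnames(g), colnames(g))
  if (k < 2L) return(m)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      r2 <- tryCatch(suppressWarnings(pairwise_ld_r2(g[, i], g[, j])),
                     error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- r2
    }
  }
  m
}

#' Unweighted allele-count genetic risk score
#'
#' Sums the effect-allele dosages of the selected SNPs into a simple
#' point-scale score; with the default three-SNP instrument the score is
#' the integer range 0-6, 0 and 6 marking the lowest and highest
#' genetically predicted exposure. Subjects missing a dosage at any
#' selected SNP receive `NA` (listwise exclusion downstream); the number
#' excluded is attached as attribute `n_excluded`.
#'
#' @param genotypes dosage matrix with named columns.
#' @param snp_ids ordered SNP identifiers to score.
#' @return Named integer vector of scores with `NA` for excluded subjects.
#' @export
score_grs <- function(genotypes, snp_ids) {
  g <- unclass(genotypes)
  missing_snps <- setdiff(snp_ids, colnames(g))
  if (length(missing_snps))
    stop("genotype matrix lacks SNP(s): ", paste(missing_snps, collapse = ", "))
  sub <- g[, snp_ids, drop = FALSE]
  if (!all(sub %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or missing")
  score <- as.integer(rowSums(sub))
  names(score) <- rownames(g)
  attr(score, "n_excluded") <- sum(is.na(score))
  score
}

#' Per-SNP exposure association screen
#'
#' Regresses the exposure on each candidate SNP's dosage separately
#' (optionally adjusted), yielding the per-allele effect, its t statistic
#' and p-value used by [select_instrument_snps()].
#'
#' @param genotypes dosage matrix.
#' @param exposure numeric exposure vector, ng/mL.
#' @param covariates optional data.frame of adjustment covariates.
#' @return data.frame: `snp_id`, `beta`, `se`, `t`, `p`, `n`.
#' @export
per_snp_exposure_fits <- function(genotypes, exposure, covariates = NULL) {
  g <- unclass(genotypes)
  rows <- lapply(colnames(g), function(s) {
    df <- data.frame(exposure = exposure, dosage = g[, s])
    if (!is.null(covariates)) df <- cbind(df, covariates)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    fit <- stats::lm(exposure ~ ., data = df)
    cf <- summary(fit)$coefficients["dosage", ]
    data.frame(snp_id = s, beta = cf[["Estimate"]], se = cf[["Std. Error"]],
               t = cf[["t value"]], p = cf[["Pr(>|t|)"]], n = nrow(df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select instrument SNPs by association strength with LD pruning
#'
#' Keeps candidates whose exposure association passes `alpha`, ranks them
#' by absolute first-stage t statistic, and greedily retains the strongest
#' while dropping any later SNP whose dosage r^2 with an already-retained
#' SNP exceeds `ld_threshold`, up to `max_snps` SNPs. A pair correlated
#' below the threshold is deliberately retained together (weak LD is
#' tolerated, mirroring the instrument-construction convention here of
#' keeping a pair at r^2 = 0.16 under a 0.2 threshold).
#'
#' @param fits data.frame from [per_snp_exposure_fits()].
#' @param ld r^2 matrix over the same SNPs, see [ld_matrix()].
#' @param alpha screening significance level for the exposure association.
#' @param ld_threshold maximum tolerated pairwise r^2.
#' @param max_snps instrument size cap.
#' @return list with `selected` (character vector, possibly empty),
#'   `status` (`"ok"` or `"no_snp_passes_alpha"`), and `dropped`
#'   (data.frame of excluded SNPs with reasons).
#' @export
select_instrument_snps <- function(fits, ld, alpha = 0.05,
                                   ld_threshold = 0.2, max_snps = 3L) {
  stopifnot(all(fits$snp_id %in% rownames(ld)))
  cand <- fits[fits$p < alpha, , drop = FALSE]
  dropped <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  ns <- setdiff(fits$snp_id, cand$snp_id)
  if (length(ns))
    dropped <- rbind(dropped, data.frame(snp_id = ns, reason = "p >= alpha"))
  if (nrow(cand) == 0L)
    return(list(selected = character(), status = "no_snp_passes_alpha",
                dropped = dropped))
  cand <- cand[order(-abs(cand$t)), , drop = FALSE]
  selected <- character()
  for (s in cand$snp_id) {
    if (length(selected) >= max_snps) {
      dropped <- rbind(dropped, data.frame(snp_id = s, reason = "cap reached"))
      next
    }
    r2 <- ld[s, selected]
    if (length(selected) && any(!is.na(r2) & r2 > ld_threshold)) {
      hit <- selected[which(!is.na(r2) & r2 > ld_threshold)[1L]]
      dropped <- rbind(dropped, data.frame(
        snp_id = s, reason = sprintf("LD with %s (r2 = %.3f)", hit,
                                     max(r2, na.rm = TRUE))))
      next
    }
    selected <- c(selected, s)
  }
  list(selected = selected, status = "ok", dropped = dropped)
}

#' First-stage fit of exposure on the genetic risk score
#'
#' Least-squares regression of serum 25(OH)D on the allele score
#' (optionally with covariates). Reports the per-allele slope B with its
#' standard error and 95% confidence interval, the (partial) R^2 for the
#' score term, and the F statistic of the score term, `F = t^2`; in the
#' univariable case this satisfies the closed form
#' `F = R^2 (n - 2) / (1 - R^2)` exactly. F below about 10 conventionally
#' flags a weak instrument.
#'
#' @param grs numeric allele scores.
#' @param exposure ng/mL.
#' @param covariates optional data.frame of adjustment covariates.
#' @return Object of class `first_stage`: list with `estimate` (an
#'   [assoc_estimate()] on the linear scale), `r_squared`, `f_statistic`,
#'   `n`, `univariable`, `adjustment_set`.
#' @export
first_stage_fit <- function(grs, exposure, covariates = NULL) {
  df <- data.frame(exposure = exposure, grs = grs)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= ncol(df) + 1L) stop("too few complete observations for the fit")
  fit <- stats::lm(exposure ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         " not estimable")
  sm <- summary(fit)
  cf <- sm$coefficients["grs", ]
  tval <- cf[["t value"]]
  univariable <- is.null(covariates)
  r2 <- if (univariable) sm$r.squared else {
    # partial R^2 for the score term from its t statistic
    tval^2 / (tval^2 + fit$df.residual)
  }
  ci <- stats::confint(fit, "grs", level = 0.95)
  est <- assoc_estimate("grs", beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                        ci_low = ci[1L], ci_high = ci[2L],
                        p = cf[["Pr(>|t|)"]], n = n, scale = "linear",
                        adjustment_set = setdiff(names(df), c("exposure", "grs")))
  structure(list(estimate = est, r_squared = r2, f_statistic = tval^2,
                 n = n, univariable = univariable,
                 adjustment_set = est$adjustment_set),
            class = "first_stage")
}

#' @export
print.first_stage <- function(x, ...) {
  cat(sprintf("First stage: B = %.3f ng/mL per allele [%.3f, %.3f], R^2 = %.4f, F = %.1f, n = %d\n",
              x$estimate$beta, x$estimate$ci_low, x$estimate$ci_high,
              x$r_squared, x$f_statistic, x$n))
  if (x$f_statistic < 10) cat("  warning: F < 10, weak instrument\n")
  invisible(x)
}

#' Test independence of the score from measured confounders
#'
#' Instrument-validity screen: associates the allele score with each
#' covariate using a test matched to the covariate type (linear
#' regression for numeric, logistic regression for binary, chi-square
#' contingency test for categorical). Covariates with p below `threshold`
#' are flagged; under valid Mendelian randomization all p-values should be
#' unremarkable (the reporting convention here flags p <= 0.20).
#'
#' @param grs numeric allele scores.
#' @param covariates data.frame of covariates to screen.
#' @param threshold flagging threshold on the p-value.
#' @return data.frame: `covariate`, `test`, `p`, `flagged`; constant
#'   covariates are skipped with a warning.
#' @export
confounder_independence <- function(grs, covariates, threshold = 0.20) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(grs))
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    ok <- stats::complete.cases(grs, v)
    g <- grs[ok]; v <- if (is.factor(v)) droplevels(v[ok]) else v[ok]
    if (length(unique(v)) < 2L) {
      warning("covariate '", nm, "' is constant; skipped")
      return(NULL)
    }
    if (is.factor(v) || is.character(v)) {
      p <- suppressWarnings(stats::chisq.test(table(g, v))$p.value)
      test <- "chi-square"
    } else if (all(v %in% c(0, 1))) {
      fit <- fit_logistic(v, g)
      p <- fit$estimate$p
      test <- "logistic"
    } else {
      p <- summary(stats::lm(v ~ g))$coefficients["g", "Pr(>|t|)"]
      test <- "linear"
    }
    data.frame(covariate = nm, test = test, p = p, flagged = p <= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the full instrument report
#'
#' Runs the quality-control and construction pipeline on a derivation
#' cohort: per-SNP Hardy-Weinberg tests, pairwise LD, per-SNP exposure
#' screen, LD-pruned selection, allele-score construction and first-stage
#' strength, plus the confounder-independence screen.
#'
#' @param genotypes candidate-panel dosage matrix.
#' @param exposure ng/mL.
#' @param covariates data.frame used for the confounder screen (and,
#'   optionally, first-stage adjustment when `adjust_first_stage = TRUE`).
#' @param alpha,ld_threshold,max_snps selection settings, see
#'   [select_instrument_snps()].
#' @param confounder_set names of covariates to screen (default: all).
#' @param adjust_first_stage adjust the first-stage fit for `covariates`.
#' @return Object of class `instrument_report`: list with `qc`,
#'   `ld_matrix`, `per_snp_fits`, `selection`, `grs`, `first_stage`,
#'   `confounders`.
#' @export
build_instrument <- function(genotypes, exposure, covariates = NULL,
                             alpha = 0.05, ld_threshold = 0.2, max_snps = 3L,
                             confounder_set = NULL,
                             adjust_first_stage = FALSE) {
  qc <- snp_qc_report(genotypes)
  ld <- ld_matrix(genotypes)
  fits <- per_snp_exposure_fits(genotypes, exposure)
  sel <- select_instrument_snps(fits, ld, alpha = alpha,
                                ld_threshold = ld_threshold,
                                max_snps = max_snps)
  grs <- first_stage <- confounders <- NULL
  if (length(sel$selected)) {
    grs <- score_grs(genotypes, sel$selected)
    first_stage <- first_stage_fit(
      grs, exposure, covariates = if (adjust_first_stage) covariates)
    if (!is.null(covariates)) {
      cset <- if (is.null(confounder_set)) names(covariates) else confounder_set
      confounders <- confounder_independence(grs, covariates[cset])
    }
  }
  structure(list(qc = qc, ld_matrix = ld, per_snp_fits = fits,
                 selection = sel, grs = grs, first_stage = first_stage,
                 confounders = confounders),
            class = "instrument_report")
}

#' @export
print.instrument_report <- function(x, ...) {
  cat("Instrument report\n")
  cat("  selected SNPs:", if (length(x$selection$selected))
    paste(x$selection$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  HWE chi-square range: %.3g - %.3g\n",
              min(x$qc$hwe_chi2), max(x$qc$hwe_chi2)))
  if (!is.null(x$first_stage)) print(x$first_stage)
  if (!is.null(x$confounders) && any(x$confounders$flagged))
    cat("  flagged confounder associations:",
        paste(x$confounders$covariate[x$confounders$flagged], collapse = ", "), "\n")
  invisible(x)
}
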