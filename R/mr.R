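#' Wald ratio causal estimate
#'
#' The instrumental-variable ratio estimator: the genetic association with
#' the outcome divided by the genetic association with the exposure, both
#' per effect allele. The quotient is the causal effect per unit (ng/mL)
#' of exposure on the numerator's scale (log hazard or log odds).
#'
#' @param beta_zy per-allele instrument-outcome association (log ratio).
#' @param beta_zx per-allele instrument-exposure association (exposure
#'   units per allele); must be nonzero.
#' @return The ratio estimate `theta = beta_zy / beta_zx`.
#' @export
wald_ratio <- function(beta_zy, beta_zx) {
  if (!is.finite(beta_zx) || beta_zx == 0)
    stop("Wald ratio undefined: instrument-exposure association is zero")
  beta_zy / beta_zx
}

#' Fieller's-theorem confidence interval for a ratio of normal estimates
#'
#' Inverts the test of `H0: beta_zy = theta0 * beta_zx`, whose statistic
#' `(beta_zy - theta0 beta_zx)^2 / (se_zy^2 - 2 theta0 cov + theta0^2
#' se_zx^2)` is chi-square(1) under normality, giving the exact confidence
#' set for the ratio. The set is the interval between the roots of
#' `A theta^2 + B theta + C <= 0` with `A = beta_zx^2 - z^2 se_zx^2`,
#' `B = -2 (beta_zy beta_zx - z^2 cov)`, `C = beta_zy^2 - z^2 se_zy^2`.
#' When the denominator is not significant at `alpha` (the degeneracy
#' statistic `g = z^2 se_zx^2 / beta_zx^2` reaches 1) the set is the
#' whole line or the complement of an interval; these are reported as
#' explicit `"unbounded"` / `"exclusive"` statuses, never silently
#' truncated. In the strong-instrument limit `se_zx -> 0` the interval
#' converges to the delta-method (plug-in) interval, which is also
#' available directly via `method = "delta"`.
#'
#' @param beta_zy,se_zy numerator estimate and standard error (log-ratio
#'   scale).
#' @param beta_zx,se_zx denominator estimate and standard error (exposure
#'   units per allele).
#' @param covariance covariance of the two estimates; 0 in a two-sample
#'   design where they come from disjoint cohorts.
#' @param alpha two-sided error rate (0.05 for a 95% interval).
#' @param method `"fieller"` (default) or `"delta"`.
#' @return list with `theta` (ratio point estimate), log-scale limits
#'   `ci_low`/`ci_high` (`NA` when not bounded), exponentiated limits
#'   `or_low`/`or_high`, degeneracy statistic `g`, `method`, and `status`
#'   (`"bounded"`, `"unbounded"`, or `"exclusive"` with an
#'   `excluded_region`).
#' @export
fieller_ci <- function(beta_zy, se_zy, beta_zx, se_zx, covariance = 0,
                       alpha = 0.05, method = c("fieller", "delta")) {
  method <- match.arg(method)
  if (!is.finite(se_zy) || !is.finite(se_zx) || se_zy <= 0 || se_zx < 0)
    stop("standard errors must be positive (se_zx may be zero only in the limit)")
  theta <- wald_ratio(beta_zy, beta_zx)
  z <- stats::qnorm(1 - alpha / 2)
  g <- z^2 * se_zx^2 / beta_zx^2

  if (method == "delta" || se_zx == 0) {
    se_theta <- sqrt(se_zy^2 + theta^2 * se_zx^2 - 2 * theta * covariance) /
      abs(beta_zx)
    lo <- theta - z * se_theta; hi <- theta + z * se_theta
    return(list(theta = theta, ci_low = lo, ci_high = hi,
                or_low = exp(lo), or_high = exp(hi), g = g,
                method = "delta", status = "bounded"))
  }

  A <- beta_zx^2 - z^2 * se_zx^2
  B <- -2 * (beta_zy * beta_zx - z^2 * covariance)
  C <- beta_zy^2 - z^2 * se_zy^2
  disc <- B^2 - 4 * A * C

  if (A > 0) {
    # g < 1: a bounded interval containing theta
    lo <- (-B - sqrt(disc)) / (2 * A)
    hi <- (-B + sqrt(disc)) / (2 * A)
    list(theta = theta, ci_low = lo, ci_high = hi,
         or_low = exp(lo), or_high = exp(hi), g = g,
         method = "fieller", status = "bounded")
  } else if (disc > 0 && A < 0) {
    # denominator indistinguishable from zero but numerator is not:
    # confidence set is the complement of a finite interval
    r <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
    list(theta = theta, ci_low = NA_real_, ci_high = NA_real_,
         or_low = NA_real_, or_high = NA_real_, g = g,
         method = "fieller", status = "exclusive", excluded_region = r)
  } else {
    # neither estimate distinguishable from zero: the whole line
    list(theta = theta, ci_low = -Inf, ci_high = Inf,
         or_low = 0, or_high = Inf, g = g,
         method = "fieller", status = "unbounded")
  }
}

#' Compose a Wald-ratio causal estimate with its Fieller interval
#'
#' Divides a per-allele instrument-outcome association by the per-allele
#' first-stage association and attaches Fieller confidence limits,
#' recording both inputs and the covariance assumption for the audit
#' trail. The numerator must be on a log-ratio scale and the denominator
#' on the linear exposure scale; the exponentiated estimate is reported
#' per 1 ng/mL of exposure and labelled an odds ratio under the rare-event
#' equivalence of hazard and odds ratios (no scale conversion is applied).
#'
#' @param first_stage an [assoc_estimate()] (or `first_stage` object) on
#'   the linear scale: exposure units per allele.
#' @param endpoint_fit an [assoc_estimate()] (or `cox_fit`/`logistic_fit`)
#'   on the log-hazard or log-odds scale: per-allele outcome association.
#' @param covariance numerator-denominator covariance (0 for disjoint
#'   subcohorts).
#' @param alpha two-sided error rate.
#' @return Object of class `wald_result`: `theta`, `or_estimate`,
#'   `ci_low`/`ci_high` (ratio scale), `g`, `method`, `status`,
#'   `weak_instrument` flag (first-stage F < 10), `numerator`,
#'   `denominator`, `covariance_zy_zx`.
#' @export
grs_mr <- function(first_stage, endpoint_fit, covariance = 0, alpha = 0.05) {
  den <- if (inherits(first_stage, "first_stage")) first_stage$estimate
         else first_stage
  num <- if (inherits(endpoint_fit, c("cox_fit", "logistic_fit")))
           endpoint_fit$estimate else endpoint_fit
  if (is.null(num))
    stop("endpoint fit did not converge; no numerator available")
  stopifnot(inherits(den, "assoc_estimate"), inherits(num, "assoc_estimate"))
  if (den$scale != "linear")
    stop("denominator must be on the linear exposure scale, got ", den$scale)
  if (!num$scale %in% c("log-hazard", "log-odds"))
    stop("numerator must be a log-hazard or log-odds estimate, got ", num$scale)
  fc <- fieller_ci(num$beta, num$se, den$beta, den$se,
                   covariance = covariance, alpha = alpha)
  f_stat <- (den$beta / den$se)^2
  structure(
    list(theta = fc$theta, or_estimate = exp(fc$theta),
         ci_low = fc$or_low, ci_high = fc$or_high,
         ci_low_log = fc$ci_low, ci_high_log = fc$ci_high,
         g = fc$g, method = fc$method, status = fc$status,
         excluded_region = fc$excluded_region,
         weak_instrument = f_stat < 10,
         numerator = num, denominator = den,
         covariance_zy_zx = covariance, alpha = alpha),
    class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald ratio per 1 ng/mL: OR = %.4f", x$or_estimate))
  if (x$status == "bounded") {
    cat(sprintf(" [%.4f, %.4f] (Fieller, g = %.3f)\n",
                x$ci_low, x$ci_high, x$g))
  } else {
    cat(sprintf(" -- %s confidence set (g = %.3f)\n", x$status, x$g))
  }
  if (x$weak_instrument) cat("  flag: weak instrument (first-stage F < 10)\n")
  invisible(x)
}

#' Per-SNP Wald ratio sensitivity estimates
#'
#' SNP-specific causal estimates from matched per-allele exposure and
#' endpoint associations. No meta-combination is applied: multi-SNP
#' summaries come from re-scored allele-count instruments, not from
#' inverse-variance pooling. SNPs with a null first stage are flagged weak
#' (or undefined for an exactly zero denominator) but still reported.
#'
#' @param exposure_fits data.frame from [per_snp_exposure_fits()] (columns
#'   `snp_id`, `beta`, `se`, `p`).
#' @param endpoint_fits data.frame with columns `snp_id`, `beta`, `se` on
#'   a log-ratio scale (e.g. per-allele Cox coefficients).
#' @param alpha two-sided error rate.
#' @param weak_p_threshold first-stage p-value above which a SNP is
#'   flagged as a weak instrument.
#' @return data.frame: one row per SNP with `theta`, `or_estimate`,
#'   `ci_low`, `ci_high`, `g`, `status`, `weak_instrument`.
#' @export
per_snp_mr <- function(exposure_fits, endpoint_fits, alpha = 0.05,
                       weak_p_threshold = 0.05) {
  if (!setequal(exposure_fits$snp_id, endpoint_fits$snp_id))
    stop("exposure and endpoint fits cover different SNP sets")
  rows <- lapply(exposure_fits$snp_id, function(s) {
    ex <- exposure_fits[exposure_fits$snp_id == s, ]
    ep <- endpoint_fits[endpoint_fits$snp_id == s, ]
    if (ex$beta == 0) {
      return(data.frame(snp_id = s, theta = NA_real_, or_estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, g = Inf,
                        status = "undefined", weak_instrument = TRUE,
                        stringsAsFactors = FALSE))
    }
    fc <- fieller_ci(ep$beta, ep$se, ex$beta, ex$se, alpha = alpha)
    data.frame(snp_id = s, theta = fc$theta, or_estimate = exp(fc$theta),
               ci_low = fc$or_low, ci_high = fc$or_high, g = fc$g,
               status = fc$status,
               weak_instrument = ex$p > weak_p_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Vitamin D status categories
#'
#' @param exposure serum 25(OH)D, ng/mL.
#' @param thresholds `c(deficient_below, sufficient_at_or_above)`,
#'   defaults 20 and 30 ng/mL.
#' @return Factor with levels `deficient`, `insufficient`, `sufficient`.
#' @export
vitd_status <- function(exposure, thresholds = c(20, 30)) {
  stopifnot(length(thresholds) == 2L, thresholds[1L] < thresholds[2L])
  cut(exposure, breaks = c(-Inf, thresholds, Inf),
      labels = c("deficient", "insufficient", "sufficient"), right = FALSE)
}

#' Subgroup Mendelian randomization by exposure stratum
#'
#' Runs the MR numerator fit and ratio within outcome-cohort strata
#' defined by the measured exposure (default: deficient, 25(OH)D below
#' 20 ng/mL, versus not), keeping the derivation-cohort first stage as the
#' shared denominator (two-sample design). A stratum without events gets
#' a per-stratum failure status rather than halting the others.
#'
#' @param cohort outcome cohort table with `grs`, `exposure_25ohd`, the
#'   endpoint's `time_*`/`event_*` columns.
#' @param first_stage denominator [assoc_estimate()] or `first_stage`.
#' @param endpoint endpoint name, e.g. `"combined"` or `"mi"`.
#' @param threshold ng/mL cut defining the deficient stratum; or both
#'   cuts `c(20, 30)` for the three-level status classification.
#' @param covariates optional data.frame of Cox adjustment covariates
#'   (subset to each stratum automatically).
#' @param alpha two-sided error rate.
#' @return Named list of `wald_result` objects (or failure records with a
#'   `status` element), one per stratum.
#' @export
subgroup_mr <- function(cohort, first_stage, endpoint = "combined",
                        threshold = 20, covariates = NULL, alpha = 0.05) {
  tcol <- paste0("time_", endpoint); ecol <- paste0("event_", endpoint)
  stopifnot(all(c(tcol, ecol, "grs", "exposure_25ohd") %in% names(cohort)))
  strata <- if (length(threshold) == 2L) {
    vitd_status(cohort$exposure_25ohd, threshold)
  } else {
    factor(ifelse(cohort$exposure_25ohd < threshold, "deficient",
                  "non_deficient"),
           levels = c("deficient", "non_deficient"))
  }
  out <- list()
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    if (!length(idx) || sum(cohort[[ecol]][idx], na.rm = TRUE) == 0L) {
      out[[lev]] <- list(status = "no_events_in_stratum", n = length(idx))
      next
    }
    fit <- fit_cox(cohort[[tcol]][idx], cohort[[ecol]][idx],
                   cohort$grs[idx], term = "grs",
                   covariates = if (!is.null(covariates))
                     covariates[idx, , drop = FALSE])
    out[[lev]] <- if (fit$status == "converged")
      grs_mr(first_stage, fit, alpha = alpha)
    else list(status = fit$status, n = length(idx))
  }
  out
}
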