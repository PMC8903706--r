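#' Construct an association estimate
#'
#' Light container for one fitted effect: a slope, log-hazard ratio or
#' log-odds ratio together with its standard error, Wald confidence
#' interval, p-value and sample accounting. Used for both the
#' instrument-exposure association (the Wald-ratio denominator, linear
#' scale) and the instrument-outcome associations (the numerators, on the
#' log-hazard or log-odds scale).
#'
#' @param term name of the term the estimate belongs to.
#' @param beta point estimate on the estimation scale.
#' @param se standard error (must be positive when not `NA`).
#' @param ci_low,ci_high 95% bounds on the estimation scale; derived from
#'   `beta` and `se` when omitted.
#' @param p two-sided p-value.
#' @param n number of subjects used in the fit.
#' @param n_events number of events (survival/binary fits), `NA` otherwise.
#' @param scale one of `"linear"`, `"log-hazard"`, `"log-odds"`.
#' @param adjustment_set character vector of covariates adjusted for.
#' @return An object of class `assoc_estimate`.
#' @export
assoc_estimate <- function(term, beta, se, ci_low = NULL, ci_high = NULL,
                           p = NA_real_, n = NA_integer_, n_events = NA_integer_,
                           scale = c("linear", "log-hazard", "log-odds"),
                           adjustment_set = character()) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!is.na(se) && se <= 0) stop("standard error must be positive")
  z <- stats::qnorm(0.975)
  if (is.null(ci_low)) ci_low <- beta - z * se
  if (is.null(ci_high)) ci_high <- beta + z * se
  if (!is.na(ci_low) && !is.na(ci_high) && !(ci_low <= beta && beta <= ci_high))
    stop("confidence bounds must bracket the point estimate")
  structure(
    list(term = term, beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
         p = p, n = n, n_events = n_events, scale = scale,
         adjustment_set = adjustment_set),
    class = "assoc_estimate")
}

#' @export
print.assoc_estimate <- function(x, ...) {
  lab <- switch(x$scale,
                "linear" = "B", "log-hazard" = "log-HR", "log-odds" = "log-OR")
  cat(sprintf("%s [%s]: %s = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n = %s\n",
              x$term, x$scale, lab, x$beta, x$se, x$ci_low, x$ci_high, x$p,
              format(x$n)), ...)
  if (length(x$adjustment_set))
    cat("  adjusted for:", paste(x$adjustment_set, collapse = ", "), "\n")
  invisible(x)
}

#' Back-derive a standard error from a printed 95% confidence interval
#'
#' Utility for working-example recomputations from published summary
#' statistics: `se = (upper - lower) / (2 * 1.96)` on the estimation scale.
#'
#' @param lower,upper confidence bounds on the estimation scale.
#' @param level confidence level of the printed interval.
#' @return Standard error implied by the interval under normality.
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (any(upper <= lower)) stop("upper bound must exceed lower bound")
  (upper - lower) / (2 * stats::qnorm(1 - (1 - level) / 2))
}

# shared internal checks ------------------------------------------------

.check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]")
  invisible(x)
}

.check_count <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != round(x))
    stop(what, " must be a positive integer")
  invisible(as.integer(x))
}
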