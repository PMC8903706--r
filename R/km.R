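#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (non-negative).
#' @param event event indicator (0/1).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv` (survival just after `time`). The curve
#'   starts implicitly at `S(0) = 1`.
#' @export
km_curve <- function(time, event) {
  ok <- stats::complete.cases(time, event)
  time <- time[ok]; event <- as.integer(event[ok])
  if (any(time < 0)) stop("negative follow-up times")
  n <- length(time)
  ut <- sort(unique(time[event == 1L]))
  if (!length(ut))
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), surv = numeric()))
  n_risk <- vapply(ut, function(u) sum(time >= u), integer(1L))
  n_event <- vapply(ut, function(u) sum(time == u & event == 1L), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Restricted mean survival from a Kaplan-Meier curve
#'
#' Area under the step survival curve from 0 to `horizon`; equals the sum
#' of interval widths weighted by the survival level entering each
#' interval.
#'
#' @param curve data.frame from [km_curve()].
#' @param horizon restriction time, months.
#' @return Restricted mean survival time, months.
#' @export
km_restricted_mean <- function(curve, horizon) {
  tt <- c(0, curve$time[curve$time <= horizon], horizon)
  ss <- c(1, curve$surv[curve$time <= horizon])
  sum(ss * diff(tt))
}

#' Kaplan-Meier comparison with the log-rank test
#'
#' Product-limit survival per group, the one-degree-of-freedom log-rank
#' statistic, and restricted mean survival to the largest observed time
#' (the conventional horizon when a mean survival is quoted with a
#' Kaplan-Meier analysis).
#'
#' @param time follow-up times, months.
#' @param event event indicator (0/1).
#' @param group two-level grouping (factor, character or binary).
#' @return Object of class `km_comparison`: per-group `n`, `n_events`,
#'   `restricted_mean` (with `horizon`), `logrank_stat`, `p`, and the two
#'   `curves`.
#' @export
km_logrank <- function(time, event, group) {
  ok <- stats::complete.cases(time, event, group)
  time <- time[ok]; event <- as.integer(event[ok]); group <- group[ok]
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (min(table(g)) == 0L) stop("both groups must be non-empty")
  lev <- levels(g)
  in1 <- g == lev[1L]

  ut <- sort(unique(time[event == 1L]))
  o1 <- e1 <- v <- numeric(length(ut))
  for (k in seq_along(ut)) {
    u <- ut[k]
    at_risk <- time >= u
    n_tot <- sum(at_risk); n1 <- sum(at_risk & in1)
    d_tot <- sum(time == u & event == 1L)
    d1 <- sum(time == u & event == 1L & in1)
    o1[k] <- d1
    e1[k] <- d_tot * n1 / n_tot
    v[k] <- if (n_tot > 1L)
      d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1L)
    else 0
  }
  stat <- if (sum(v) > 0) (sum(o1) - sum(e1))^2 / sum(v) else 0
  horizon <- max(time)
  curves <- lapply(lev, function(l) km_curve(time[g == l], event[g == l]))
  names(curves) <- lev
  rmst <- vapply(curves, km_restricted_mean, numeric(1L), horizon = horizon)
  structure(
    list(groups = lev,
         n = as.vector(table(g)),
         n_events = vapply(lev, function(l) sum(event[g == l]), integer(1L)),
         restricted_mean = rmst, horizon = horizon,
         logrank_stat = stat,
         p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         curves = curves),
    class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("Kaplan-Meier comparison\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: n = %d, events = %d, restricted mean %.1f months (to %.1f)\n",
                x$groups[i], x$n[i], x$n_events[i], x$restricted_mean[i],
                x$horizon))
  cat(sprintf("  log-rank = %.2f, p = %.3g\n", x$logrank_stat, x$p))
  invisible(x)
}
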