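# Cox proportional hazards by Newton-Raphson on the partial likelihood.
# Ties handled by the Efron approximation (Breslow available). Columns are
# centred internally; the partial likelihood is invariant to covariate
# location so estimates are unchanged while exp(eta) stays well scaled.

.flat_pairs <- function(p) {
  # index pairs (i <= j) for packed symmetric storage
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

.unflatten_sym <- function(v, p, pairs) {
  m <- matrix(0, p, p)
  m[pairs] <- v
  m[pairs[, c(2L, 1L), drop = FALSE]] <- v
  m
}

.revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x[nrow(x):1L, , drop = FALSE], 2L, cumsum)[nrow(x):1L, , drop = FALSE]
  } else rev(cumsum(rev(x)))
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood by Newton iteration with
#' step-halving, using the Efron approximation for tied event times.
#' Returns the per-unit log hazard ratio for the main exposure term with
#' Wald standard error, confidence interval and p-value, plus convergence
#' diagnostics. Degenerate inputs yield an explicit failure `status`
#' (`"no_events"`, `"monotone_likelihood"`, `"not_converged"`) instead of
#' a misleading estimate.
#'
#' @param time follow-up times, months (non-negative).
#' @param event event indicator (0/1).
#' @param x main exposure term (numeric vector), reported first.
#' @param covariates optional data.frame of adjustment covariates
#'   (factors expanded to dummies).
#' @param term name for the exposure term in the report.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `cox_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik` (null and fitted), `iter`, `status`, `n`, `n_events`, and
#'   `estimate` (an [assoc_estimate()] for `term` on the log-hazard
#'   scale; `NULL` unless `status == "converged"`).
#' @export
fit_cox <- function(time, event, x, covariates = NULL, term = "exposure",
                    ties = c("efron", "breslow"), max_iter = 30L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- cbind(term = x)
  colnames(X) <- term
  if (!is.null(covariates)) {
    covariates <- droplevels(as.data.frame(covariates))
    mm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    X <- cbind(X, mm)
  }
  ok <- stats::complete.cases(time, event, X)
  time <- time[ok]; event <- as.integer(event[ok]); X <- X[ok, , drop = FALSE]
  if (any(time < 0)) stop("negative follow-up times")
  n <- length(time)
  result <- function(status, beta = NULL, V = NULL, ll = NULL, ll0 = NULL,
                     iter = 0L) {
    est <- NULL
    if (status == "converged") {
      se <- sqrt(diag(V))
      est <- assoc_estimate(term, beta = beta[[1L]], se = se[[1L]],
                            p = 2 * stats::pnorm(-abs(beta[[1L]] / se[[1L]])),
                            n = n, n_events = sum(event), scale = "log-hazard",
                            adjustment_set = colnames(X)[-1L])
    }
    structure(list(coefficients = beta,
                   se = if (!is.null(V)) sqrt(diag(V)),
                   vcov = V, loglik = c(null = ll0, fitted = ll),
                   iter = iter, status = status, n = n,
                   n_events = sum(event), ties = ties, estimate = est),
              class = "cox_fit")
  }
  if (sum(event) < 1L) return(result("no_events"))

  xsd <- apply(X, 2L, stats::sd)
  if (xsd[1L] == 0) stop("constant covariate in the Cox design: ", term)
  if (any(xsd[-1L] == 0)) {
    drop_cols <- which(xsd == 0)
    warning("dropping constant adjustment column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    xsd <- xsd[-drop_cols]
  }
  p <- ncol(X)
  X <- sweep(X, 2L, colMeans(X))

  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  evt <- which(d_s == 1L)
  ut <- unique(t_s[evt])
  ri <- match(ut, t_s)                     # first risk-set index per event time
  gid <- match(t_s[evt], ut)               # tie group of each event
  dg <- tabulate(gid)
  idx_g <- rep(seq_along(ut), dg)
  f <- if (ties == "efron") (sequence(dg) - 1) / rep(dg, dg) else
    rep(0, sum(dg))
  pairs <- .flat_pairs(p)
  Xe_sum <- colSums(X_s[evt, , drop = FALSE])

  eval_pl <- function(beta) {
    eta <- drop(X_s %*% beta)
    w <- exp(eta)
    wX <- X_s * w
    wXX <- wX[, pairs[, 1L], drop = FALSE] * X_s[, pairs[, 2L], drop = FALSE]
    S0 <- .revcumsum(w)[ri]
    S1 <- .revcumsum(wX)[ri, , drop = FALSE]
    S2 <- .revcumsum(wXX)[ri, , drop = FALSE]
    D0 <- drop(rowsum(w[evt], gid))
    D1 <- rowsum(wX[evt, , drop = FALSE], gid)
    D2 <- rowsum(wXX[evt, , drop = FALSE], gid)
    den <- S0[idx_g] - f * D0[idx_g]
    E1 <- (S1[idx_g, , drop = FALSE] - f * D1[idx_g, , drop = FALSE]) / den
    E2 <- (S2[idx_g, , drop = FALSE] - f * D2[idx_g, , drop = FALSE]) / den
    ll <- sum(eta[evt]) - sum(log(den))
    grad <- Xe_sum - colSums(E1)
    info <- .unflatten_sym(colSums(E2), p, pairs) - crossprod(E1)
    list(ll = ll, grad = grad, info = info)
  }

  beta <- rep(0, p)
  cur <- eval_pl(beta)
  ll0 <- cur$ll
  status <- "not_converged"; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) { status <- "singular_information"; break }
    new_beta <- beta + step
    nxt <- eval_pl(new_beta)
    halvings <- 0L
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- eval_pl(new_beta)
      halvings <- halvings + 1L
    }
    if (any(abs(new_beta * xsd) > 30)) { status <- "monotone_likelihood"; break }
    done <- abs(nxt$ll - cur$ll) < tol * (abs(cur$ll) + 0.1)
    beta <- new_beta; cur <- nxt
    if (done) { status <- "converged"; break }
  }
  if (status != "converged")
    return(result(status, beta = stats::setNames(beta, colnames(X)),
                  ll = cur$ll, ll0 = ll0, iter = iter))
  V <- solve(cur$info)
  dimnames(V) <- list(colnames(X), colnames(X))
  result("converged", beta = stats::setNames(beta, colnames(X)), V = V,
         ll = cur$ll, ll0 = ll0, iter = iter)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d subjects, %d events, status %s\n",
              x$ties, x$n, x$n_events, x$status))
  if (x$status == "converged") {
    hr <- exp(x$coefficients)
    for (i in seq_along(hr))
      cat(sprintf("  %s: HR = %.4f [%.4f, %.4f]\n",
                  names(hr)[i], hr[i],
                  exp(x$coefficients[i] - 1.96 * x$se[i]),
                  exp(x$coefficients[i] + 1.96 * x$se[i])))
  }
  invisible(x)
}
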