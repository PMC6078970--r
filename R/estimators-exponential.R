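# Exponential relaxation fits for observable traces.
#
# Rises are A (1 - exp(-t/tau)) (+ second phase) (+ offset); decays are
# A exp(-t/tau) (+ offset).  Double exponentials are notoriously
# degenerate, so the time constants are found by variable projection
# (amplitudes and offset are linear and profiled out by weighted least
# squares) with a log-spaced multi-start grid over the trace span.

.exp_basis <- function(t, taus, direction, through_origin) {
  B <- vapply(taus, function(tau) {
    e <- exp(-t / tau)
    if (direction == "rise") 1 - e else e
  }, numeric(length(t)))
  if (!through_origin) B <- cbind(B, offset = 1)
  B
}

.exp_profile_sse <- function(ltaus, t, y, w, direction, through_origin) {
  if (length(ltaus) > 1L && min(diff(sort(ltaus))) < 0.05)
    return(Inf)                        # collinear phases
  B <- .exp_basis(t, exp(ltaus), direction, through_origin)
  fit <- tryCatch(lm.wfit(B, y, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(Inf)
  sum(w * fit$residuals^2)
}

#' Fit exponential relaxation phases to a trace
#'
#' Weighted nonlinear least squares of one or two exponential phases.
#' For `direction = "rise"` the model is
#' `sum_i A_i (1 - exp(-t/tau_i)) + c`; for `"decay"` it is
#' `sum_i A_i exp(-t/tau_i) + c`.  `through_origin = TRUE` removes the
#' constant term `c` (for rises this pins the trace to 0 at t = 0, the
#' convention for a mixing experiment where nothing is bound yet).
#' Weights are 1/sigma^2; points with zero or missing sigma receive the
#' median weight.  Time constants are returned sorted ascending; by the
#' usual convention the reported relaxation ("binding") time of a
#' two-phase fit is the longest one, `tau_slow`.
#'
#' @param trace an [observable_trace()] (or data.frame with t, value,
#'   sigma).
#' @param n_phases 1 or 2.
#' @param direction `"rise"` or `"decay"`.
#' @param through_origin drop the constant term (default FALSE).
#' @param n_starts number of log-spaced grid points per time constant in
#'   the multi-start search (default 12).
#' @return An object of class `exponential_fit`: `tau` (ascending) with
#'   `se_tau`, `amplitudes`, `offset`, `tau_slow`, `covariance` (full
#'   parameter covariance from the Jacobian), `fitted`, `sse`, `aic`.
#' @export
fit_exponential <- function(trace, n_phases = 1L,
                            direction = c("rise", "decay"),
                            through_origin = FALSE, n_starts = 12L) {
  direction <- match.arg(direction)
  stopifnot(n_phases %in% c(1L, 2L))
  t <- trace$t; y <- trace$value
  s <- if (!is.null(trace$sigma)) trace$sigma else rep(0, length(t))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]; s <- s[ok]
  p_free <- n_phases * 2L + (!through_origin)
  if (length(t) < 3L * p_free)
    stop("too few points: need at least 3 per free parameter")
  w <- ifelse(is.finite(s) & s > 0, 1 / s^2, NA_real_)
  w[is.na(w)] <- if (all(is.na(w))) 1 else median(w, na.rm = TRUE)

  dt <- diff(sort(unique(t[t >= 0])))
  lt_lo <- log(max(min(dt[dt > 0]) / 4, 1e-12))
  lt_hi <- log(max(t) * 4)
  grid <- seq(lt_lo, lt_hi, length.out = n_starts)
  sse_fun <- function(lt) .exp_profile_sse(lt, t, y, w, direction,
                                           through_origin)

  if (n_phases == 1L) {
    sses <- vapply(grid, sse_fun, numeric(1))
    lt0 <- grid[which.min(sses)]
    opt <- optim(lt0, sse_fun, method = "Brent",
                 lower = lt_lo - 2, upper = lt_hi + 2,
                 control = list(reltol = 1e-14))
    ltaus <- opt$par
  } else {
    pairs <- t(combn(grid, 2L))
    sses <- apply(pairs, 1L, sse_fun)
    best <- pairs[which.min(sses), ]
    opt <- optim(best, sse_fun, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    opt <- optim(opt$par, sse_fun, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    ltaus <- sort(opt$par)
  }
  if (!is.finite(opt$value))
    stop("exponential fit failed to converge from any start")
  if (any(ltaus < lt_lo - 1.9) || any(ltaus > lt_hi + 1.9))
    stop("fitted time constant hit the search bounds; trace does not ",
         "constrain it")

  taus <- exp(ltaus)
  B <- .exp_basis(t, taus, direction, through_origin)
  lfit <- lm.wfit(B, y, w)
  A <- lfit$coefficients[seq_len(n_phases)]
  offset <- if (through_origin) 0 else lfit$coefficients[[n_phases + 1L]]
  fitted <- drop(B %*% lfit$coefficients)
  sse <- sum(w * (y - fitted)^2)

  # covariance of (A_1..A_k, tau_1..tau_k[, c]) from the Jacobian
  pars <- c(A, taus, if (!through_origin) offset)
  nmA <- paste0("A", seq_len(n_phases))
  nmT <- paste0("tau", seq_len(n_phases))
  names(pars) <- c(nmA, nmT, if (!through_origin) "offset")
  model_at <- function(p) {
    Bi <- .exp_basis(t, p[n_phases + seq_len(n_phases)], direction, TRUE)
    drop(Bi %*% p[seq_len(n_phases)]) +
      (if (through_origin) 0 else p[[2L * n_phases + 1L]])
  }
  J <- vapply(seq_along(pars), function(j) {
    h <- max(abs(pars[j]), 1e-8) * 1e-6
    pp <- pars; pp[j] <- pp[j] + h
    pm <- pars; pm[j] <- pm[j] - h
    (model_at(pp) - model_at(pm)) / (2 * h)
  }, numeric(length(t)))
  dof <- length(t) - length(pars)
  s2 <- if (dof > 0) sse / dof else 0
  JtWJ <- crossprod(J * sqrt(w))
  covm <- tryCatch(s2 * solve(JtWJ), error = function(e) {
    matrix(NA_real_, length(pars), length(pars))
  })
  dimnames(covm) <- list(names(pars), names(pars))
  se <- sqrt(pmax(diag(covm), 0))

  ord <- order(taus)
  structure(list(n_phases = n_phases, direction = direction,
                 through_origin = through_origin,
                 amplitudes = unname(A[ord]), tau = unname(taus[ord]),
                 se_tau = unname(se[nmT][ord]),
                 se_amplitudes = unname(se[nmA][ord]),
                 offset = offset,
                 se_offset = if (through_origin) 0 else unname(se[["offset"]]),
                 tau_slow = max(taus), tau_fast = min(taus),
                 covariance = covm, fitted = fitted, sse = sse,
                 aic = length(t) * log(sse / length(t)) + 2 * length(pars),
                 n = length(t)),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("%d-phase exponential %s%s\n", x$n_phases, x$direction,
              if (x$through_origin) " (through origin)" else ""))
  for (i in seq_len(x$n_phases))
    cat(sprintf("  tau%d = %.4g +/- %.2g s (A = %.4g)\n", i, x$tau[i],
                x$se_tau[i], x$amplitudes[i]))
  if (!x$through_origin)
    cat(sprintf("  offset = %.4g +/- %.2g\n", x$offset, x$se_offset))
  invisible(x)
}
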