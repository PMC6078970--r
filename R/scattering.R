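#' Excess scattering lengths of genome and subunit
#'
#' The contrast description of a two-component mixture: excess scattering
#' lengths of the genome (`db_G`) and of one subunit (`db_S`) in any
#' consistent absolute-intensity units.  The derived quantity
#' \eqn{\Gamma = \Delta b_G / \Delta b_S - 1/2} enters the
#' distribution-free occupancy bound.  In SANS at the RNA match point
#' (68% D2O) `db_G = 0` and Gamma = -1/2.
#'
#' @param db_G excess scattering length of the genome.
#' @param db_S excess scattering length of a subunit (non-zero).
#' @return An object of class `contrast_set` with derived field `gamma`.
#' @export
contrast_set <- function(db_G, db_S) {
  stopifnot(is.numeric(db_G), is.numeric(db_S), length(db_G) == 1L,
            length(db_S) == 1L, is.finite(db_G), is.finite(db_S))
  if (db_S == 0) stop("db_S must be non-zero")
  structure(list(db_G = db_G, db_S = db_S, gamma = db_G / db_S - 0.5),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Contrast: db_G = %.4g, db_S = %.4g, Gamma = %.4g\n",
              x$db_G, x$db_S, x$gamma))
  invisible(x)
}

#' A 1-D small-angle scattering curve
#'
#' Three parallel vectors: wavenumber q (1/Angstrom, strictly
#' increasing), absolute intensity, and per-point uncertainty.
#'
#' @param q wavenumbers, strictly increasing (1/Angstrom).
#' @param I intensities, absolute units.
#' @param sigma per-point standard deviations (> 0).
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I, sigma) {
  stopifnot(length(q) == length(I), length(I) == length(sigma))
  if (any(!is.finite(q)) || any(diff(q) <= 0))
    stop("q must be finite and strictly increasing")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive")
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 sigma = as.numeric(sigma)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("Scattering curve: %d points, q in [%.3g, %.3g] A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' A time-stamped scalar observable trace
#'
#' @param t times, seconds, non-decreasing.
#' @param value scalar observable (I0, R_g, mean-occupancy bound, or a
#'   form-factor value).
#' @param sigma standard error of each value (>= 0).
#' @param label optional observable name.
#' @return An object of class `observable_trace` (also a data.frame).
#' @export
observable_trace <- function(t, value, sigma = rep(0, length(t)),
                             label = NULL) {
  stopifnot(length(t) == length(value), length(value) == length(sigma))
  if (any(diff(t) < 0)) stop("t must be non-decreasing")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  structure(data.frame(t = t, value = value, sigma = sigma),
            label = label, class = c("observable_trace", "data.frame"))
}

#' Forward scattering intensity of a complex mixture
#'
#' The q -> 0 intensity of a solution of free subunits and N-th order
#' complexes:
#' \deqn{I_0 = \Delta b_S^2 X_S + \sum_N X_N (\Delta b_G + \Delta b_S N)^2.}
#'
#' @param dist a [complex_distribution()].
#' @param contrast a [contrast_set()].
#' @return forward intensity (numeric scalar, exact, no uncertainty).
#' @export
forward_intensity <- function(dist, contrast) {
  stopifnot(inherits(dist, "complex_distribution"),
            inherits(contrast, "contrast_set"))
  N <- seq_along(dist$X) - 1
  contrast$db_S^2 * dist$X_S +
    sum(dist$X * (contrast$db_G + contrast$db_S * N)^2)
}

#' Pre-complexation baseline intensity
#'
#' Forward intensity of the mixture before any complexation:
#' \eqn{I_0^* = \Delta b_G^2 c_G + \Delta b_S^2 c_S}.
#'
#' @param comp a [mixture_composition()].
#' @param contrast a [contrast_set()].
#' @return baseline forward intensity.
#' @export
baseline_intensity <- function(comp, contrast) {
  contrast$db_G^2 * comp$c_G + contrast$db_S^2 * comp$c_S
}

#' Distribution-free upper bound on the mean occupancy
#'
#' Inverts a forward intensity into the bound
#' \deqn{\langle N\rangle_{up} = \sqrt{\Gamma^2 +
#'   (I_0 - I_0^*)/(\Delta b_S^2 c_G)} - \Gamma,}
#' which satisfies \eqn{\langle N\rangle_{up} \ge \langle N\rangle} for
#' any occupancy distribution (equality iff the distribution has zero
#' variance).  The uncertainty is propagated linearly from `sigma_I0`.
#'
#' A small negative intensity excess (early frames where I0 ~ I0* plus
#' noise) is clipped to zero with a warning; an excess more than
#' `max_sigma_deficit` standard errors below zero is rejected as
#' inconsistent input.  For Gamma < 0 (e.g. genome-matched SANS,
#' Gamma = -1/2) the inversion is monotone only for means >= -Gamma;
#' results below that floor are reported as 0.
#'
#' @param I0 measured forward intensity (scalar).
#' @param comp a [mixture_composition()] with `c_G > 0`.
#' @param contrast a [contrast_set()].
#' @param sigma_I0 standard error of `I0` (default 0).
#' @param max_sigma_deficit tolerance, in units of `sigma_I0`, for a
#'   negative excess before signalling an error (default 3).
#' @return named numeric vector `c(value = , sigma = )`.
#' @export
n_up_from_intensity <- function(I0, comp, contrast, sigma_I0 = 0,
                                max_sigma_deficit = 3) {
  stopifnot(inherits(comp, "mixture_composition"),
            inherits(contrast, "contrast_set"),
            is.numeric(I0), length(I0) == 1L, sigma_I0 >= 0)
  if (comp$c_G <= 0) stop("occupancy bound undefined for c_G = 0")
  denom <- contrast$db_S^2 * comp$c_G
  excess <- (I0 - baseline_intensity(comp, contrast)) / denom
  if (excess < 0) {
    if (sigma_I0 > 0 && -excess * denom > max_sigma_deficit * sigma_I0)
      stop("I0 is more than ", max_sigma_deficit,
           " sigma below the pre-complexation baseline: inconsistent inputs")
    if (excess * denom < -1e-12 * max(abs(I0), 1e-300))
      warning("negative intensity excess clipped to zero")
    excess <- 0
  }
  g <- contrast$gamma
  root <- sqrt(g^2 + excess)
  value <- root - g
  if (g < 0 && value < -g) value <- 0    # bound quoted for <N> >= -Gamma
  sigma <- if (root > 0) sigma_I0 / (2 * denom * root) else Inf
  c(value = value, sigma = sigma)
}

#' Guinier fit of a scattering curve
#'
#' Weighted linear fit of ln I against q^2 over the largest low-q window
#' satisfying q R_g <= `q_rg_max`, iterated to self-consistency (the
#' window is recomputed from the fitted R_g until it stabilises).
#' Returns I0 = exp(intercept) and R_g = sqrt(-3 slope) with standard
#' errors propagated from the weighted regression.
#'
#' @param curve a [scattering_curve()].
#' @param q_rg_max Guinier validity limit on q R_g (default 1.3).
#' @param min_points minimum number of points in the window (default 5).
#' @return An object of class `guinier_fit`: list with `I0`, `sigma_I0`,
#'   `Rg`, `sigma_Rg`, `n_points`, `q_window`.
#' @export
guinier_fit <- function(curve, q_rg_max = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "scattering_curve"))
  keep <- curve$I > 0
  q <- curve$q[keep]; I <- curve$I[keep]; s <- curve$sigma[keep]
  if (length(q) < min_points) stop("too few positive-intensity points")
  fit_window <- function(n_pts) {
    idx <- seq_len(n_pts)
    w <- (I[idx] / s[idx])^2           # var(ln I) = (sigma/I)^2
    lm(log(I[idx]) ~ I(q[idx]^2), weights = w)
  }
  n_pts <- length(q)                   # start from the full curve
  for (iter in 1:25) {
    fit <- fit_window(n_pts)
    slope <- coef(fit)[[2L]]
    if (!is.finite(slope) || slope >= 0) {
      # shrink towards low q: noise or structure dominates the window
      if (n_pts > min_points) { n_pts <- max(min_points, n_pts %/% 2); next }
      stop("non-negative Guinier slope: curve is not in a Guinier regime")
    }
    Rg <- sqrt(-3 * slope)
    n_new <- max(min_points, sum(q * Rg <= q_rg_max))
    if (n_new == n_pts) break
    n_pts <- n_new
  }
  fit <- fit_window(n_pts)
  slope <- coef(fit)[[2L]]
  if (!is.finite(slope) || slope >= 0)
    stop("non-negative Guinier slope: curve is not in a Guinier regime")
  Rg <- sqrt(-3 * slope)
  V <- suppressWarnings(vcov(fit))
  I0 <- exp(coef(fit)[[1L]])
  structure(list(I0 = I0,
                 sigma_I0 = I0 * sqrt(V[1L, 1L]),
                 Rg = Rg,
                 sigma_Rg = 3 / (2 * Rg) * sqrt(V[2L, 2L]),
                 n_points = n_pts,
                 q_window = c(q[1L], q[n_pts])),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: I0 = %.4g +/- %.2g, Rg = %.4g +/- %.2g A (%d pts, q <= %.3g)\n",
              x$I0, x$sigma_I0, x$Rg, x$sigma_Rg, x$n_points, x$q_window[2L]))
  invisible(x)
}

#' Form-factor value at a probe wavenumber, frame by frame
#'
#' For each frame the intensity is normalised to a form factor with
#' P(0) = 1 using the frame's Guinier forward intensity, then linearly
#' interpolated at `q_probe`.  Uncertainties combine the point noise and
#' the I0 error in quadrature.  Optionally a flat free-subunit background
#' (intensity `background`) is subtracted before normalisation.
#'
#' @param curves list of [scattering_curve()] frames.
#' @param times frame times, seconds.
#' @param q_probe probe wavenumber (1/Angstrom), default 0.033, which
#'   sits at the first minimum of the capsid form factor.
#' @param q_width width of the q window averaged around the probe
#'   (inverse-variance weighted), emulating a detector radial bin;
#'   default 0 reads the linearly interpolated value at `q_probe`
#'   alone.
#' @param background optional per-q background curve (numeric vector on
#'   each frame's q grid, or a single [scattering_curve()]) subtracted
#'   prior to normalisation; default none.
#' @param q_rg_max passed to [guinier_fit()].
#' @return an [observable_trace()] of P(q_probe).
#' @export
form_factor_trace <- function(curves, times, q_probe = 0.033,
                              q_width = 0, background = NULL,
                              q_rg_max = 1.3) {
  stopifnot(length(curves) == length(times), q_width >= 0)
  vals <- sig <- numeric(length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (q_probe < min(cv$q) || q_probe > max(cv$q))
      stop("q_probe outside the curve's q range")
    I <- cv$I
    if (!is.null(background)) {
      bg <- if (inherits(background, "scattering_curve"))
        approx(background$q, background$I, xout = cv$q, rule = 2)$y
      else background
      I <- I - bg
    }
    gf <- guinier_fit(scattering_curve(cv$q, pmax(I, .Machine$double.xmin),
                                       cv$sigma), q_rg_max = q_rg_max)
    in_win <- abs(cv$q - q_probe) <= q_width / 2
    if (q_width > 0 && sum(in_win) >= 2L) {
      wq <- 1 / cv$sigma[in_win]^2
      Ip <- sum(wq * I[in_win]) / sum(wq)
      sp <- sqrt(1 / sum(wq))
    } else {
      Ip <- approx(cv$q, I, xout = q_probe)$y
      sp <- approx(cv$q, cv$sigma, xout = q_probe)$y
    }
    vals[i] <- Ip / gf$I0
    sig[i] <- abs(vals[i]) * sqrt((sp / Ip)^2 + (gf$sigma_I0 / gf$I0)^2)
  }
  observable_trace(times, vals, sig, label = sprintf("P(q=%g)", q_probe))
}
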