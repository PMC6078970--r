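# Closed-form single-particle form factors, normalised to P(0) = 1.

.sphere_amplitude <- function(x) {
  # 3 (sin x - x cos x) / x^3, with series for small x
  out <- numeric(length(x))
  small <- x < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Homogeneous-sphere form factor
#'
#' `P(q) = [3 (sin x - x cos x) / x^3]^2` with `x = q R`; P(0) = 1.  The
#' first zero sits at x ~= 4.493 (the first root of tan x = x).
#'
#' @param q wavenumbers (1/Angstrom, >= 0).
#' @param R sphere radius (Angstrom, > 0).
#' @return numeric vector of P(q).
#' @export
sphere_form_factor <- function(q, R) {
  if (any(q < 0)) stop("q must be >= 0")
  if (R <= 0) stop("non-physical radius")
  .sphere_amplitude(q * R)^2
}

#' Core-shell (hollow sphere) form factor
#'
#' Normalised two-radius difference form: the amplitude is the
#' volume-weighted difference of two sphere amplitudes,
#' `A = [rho_c V_i A(qR_i) + (V_o A(qR_o) - V_i A(qR_i))] /
#'      [rho_c V_i + (V_o - V_i)]`,
#' where `rho_c = contrast_ratio` is the core scattering contrast
#' relative to the shell (0 = hollow).  P(0) = 1.
#'
#' @param q wavenumbers (1/Angstrom, >= 0).
#' @param R_in,R_out inner/outer radii (Angstrom, 0 <= R_in < R_out).
#' @param contrast_ratio core-to-shell contrast ratio (default 0,
#'   a hollow shell).
#' @return numeric vector of P(q).
#' @export
core_shell_form_factor <- function(q, R_in, R_out, contrast_ratio = 0) {
  if (any(q < 0)) stop("q must be >= 0")
  if (R_in < 0 || R_out <= R_in) stop("non-physical radii: need 0 <= R_in < R_out")
  V_i <- R_in^3
  V_o <- R_out^3
  num <- contrast_ratio * V_i * .sphere_amplitude(q * R_in) +
    (V_o * .sphere_amplitude(q * R_out) - V_i * .sphere_amplitude(q * R_in))
  den <- contrast_ratio * V_i + (V_o - V_i)
  (num / den)^2
}

#' Gaussian-chain (Debye) form factor
#'
#' `P(q) = 2 (exp(-u) - 1 + u) / u^2` with `u = (q R_g)^2`; P(0) = 1.
#'
#' @param q wavenumbers (1/Angstrom, >= 0).
#' @param R_g radius of gyration of the chain (Angstrom, > 0).
#' @return numeric vector of P(q).
#' @export
gaussian_chain_form_factor <- function(q, R_g) {
  if (any(q < 0)) stop("q must be >= 0")
  if (R_g <= 0) stop("non-physical radius of gyration")
  u <- (q * R_g)^2
  out <- numeric(length(u))
  small <- u < 1e-5
  out[small] <- 1 - u[small] / 3
  ul <- u[!small]
  out[!small] <- 2 * (exp(-ul) - 1 + ul) / ul^2
  out
}

#' Polydispersity-averaged form factor
#'
#' Averages a form factor over a Gaussian distribution of particle sizes
#' (all length scales scaled together, so `P_f(q) = P(q f)`), weighting
#' each size class by its squared volume (`f^6`).  P(0) = 1 is
#' preserved.  A few percent of size dispersity is what fills the sharp
#' minima of monodisperse shells in measured capsid form factors.
#'
#' @param ff base form factor, a function of q.
#' @param sd_frac relative standard deviation of the size distribution
#'   (default 0.05).
#' @param n_points quadrature points across +/- 2.5 sd (default 9).
#' @return a function of q.
#' @export
polydisperse_form_factor <- function(ff, sd_frac = 0.05, n_points = 9L) {
  stopifnot(sd_frac > 0, sd_frac < 0.3, n_points >= 3L)
  f <- seq(1 - 2.5 * sd_frac, 1 + 2.5 * sd_frac, length.out = n_points)
  w <- exp(-(f - 1)^2 / (2 * sd_frac^2)) * f^6
  w <- w / sum(w)
  function(q) {
    out <- 0
    for (i in seq_along(f)) out <- out + w[i] * ff(q * f[i])
    out
  }
}
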