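#' Critical concentration from a titration of the equilibrium occupancy
#'
#' At fixed total subunit concentration the equilibrium mean occupancy is
#' proportional to the mass ratio: `<N>(Inf) = (1 - K_inv/c_S) * m_ratio
#' * rho`.  A weighted through-origin regression of `<N>(Inf)` on rho
#' therefore yields the critical concentration from the slope `s`:
#' `K_inv = c_S (1 - s / m_ratio)`.
#'
#' @param rho mass ratios.
#' @param N_inf equilibrium mean occupancies (same length).
#' @param sigma standard errors of `N_inf` (default equal weights).
#' @param c_S total subunit concentration (M), common to all points.
#' @param m_ratio molar ratio per unit mass ratio (default 25).
#' @return An object of class `critical_concentration_fit`: `slope`,
#'   `se_slope`, `K_inv` (M), `se_K_inv`, plus the inputs.
#' @export
fit_critical_concentration <- function(rho, N_inf, sigma = NULL, c_S,
                                       m_ratio = 25) {
  stopifnot(length(rho) == length(N_inf), length(rho) >= 2L,
            c_S > 0, m_ratio > 0)
  w <- if (is.null(sigma)) rep(1, length(rho)) else {
    stopifnot(length(sigma) == length(rho))
    ifelse(is.finite(sigma) & sigma > 0, 1 / sigma^2, NA_real_)
  }
  w[is.na(w)] <- if (all(is.na(w))) 1 else median(w, na.rm = TRUE)
  fit <- lm(N_inf ~ 0 + rho, weights = w)
  s <- coef(fit)[[1L]]
  se_s <- sqrt(suppressWarnings(vcov(fit))[1L, 1L])
  if (s > m_ratio)
    stop("slope exceeds m_ratio: implies negative K_inv ",
         "(saturated or invalid regime)")
  if (s < 0) stop("negative slope: occupancies decrease with rho")
  structure(list(slope = s, se_slope = se_s,
                 K_inv = c_S * (1 - s / m_ratio),
                 se_K_inv = c_S * se_s / m_ratio,
                 c_S = c_S, m_ratio = m_ratio,
                 rho = rho, N_inf = N_inf),
            class = "critical_concentration_fit")
}

#' @export
print.critical_concentration_fit <- function(x, ...) {
  cat(sprintf("Critical concentration fit: slope = %.4g +/- %.2g per rho\n",
              x$slope, x$se_slope))
  cat(sprintf("  K^-1 = %.4g +/- %.2g M\n", x$K_inv, x$se_K_inv))
  invisible(x)
}

#' Binding free energy from the critical concentration
#'
#' `G_bind = R T ln(K_inv / c_ref)`.  The reference (standard-state)
#' concentration is an explicit parameter because the value of G_bind is
#' only defined up to this convention; the default is 1 M.
#'
#' @param K_inv critical concentration (M, > 0).
#' @param temperature absolute temperature (K), default 298.
#' @param reference_conc standard-state concentration (M), default 1.
#' @param se_K_inv optional standard error of `K_inv` for propagation.
#' @return An object of class `free_energy_result` with the energy in
#'   J/mol, kJ/mol and units of k_B T0 (T0 = 298 K).
#' @export
binding_free_energy <- function(K_inv, temperature = .T_ROOM,
                                reference_conc = 1, se_K_inv = 0) {
  stopifnot(K_inv > 0, reference_conc > 0, temperature > 0)
  G_J <- .R_GAS * temperature * log(K_inv / reference_conc)
  se_J <- .R_GAS * temperature * se_K_inv / K_inv
  structure(list(G_J_per_mol = G_J, G_kJ_per_mol = G_J / 1000,
                 G_kT0 = G_J / (.R_GAS * .T_ROOM),
                 se_kT0 = se_J / (.R_GAS * .T_ROOM),
                 temperature = temperature,
                 reference_conc = reference_conc),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("G_bind = %.3g kJ/mol = %.3g kB T0 (reference %.3g M, T = %g K)\n",
              x$G_kJ_per_mol, x$G_kT0, x$reference_conc, x$temperature))
  invisible(x)
}

#' Diffusion-limited (Smoluchowski) forward rate constant
#'
#' For diffusion-limited binding of subunits onto a complex of capture
#' radius `R_C`, `k+ = 4 pi N_A R_C D_S` (converted to per-molar
#' per-second).
#'
#' @param R_C capture radius, meters.
#' @param D_S subunit diffusion coefficient, m^2/s.
#' @return forward rate constant, M^-1 s^-1.
#' @seealso [apparent_diffusion()] for the exact inverse.
#' @export
diffusion_limited_rate <- function(R_C, D_S) {
  stopifnot(R_C > 0, D_S > 0)
  4 * pi * .N_AVOGADRO * R_C * D_S * 1000   # m^3/mol/s -> L/mol/s
}

#' Apparent diffusion coefficient from a forward rate constant
#'
#' Inverts [diffusion_limited_rate()]: `D_S = k+ / (4 pi N_A R_C)`.
#'
#' @param k_plus forward rate constant, M^-1 s^-1.
#' @param R_C capture radius, meters.
#' @return apparent diffusion coefficient, m^2/s.
#' @export
apparent_diffusion <- function(k_plus, R_C) {
  stopifnot(k_plus > 0, R_C > 0)
  k_plus / (4 * pi * .N_AVOGADRO * R_C * 1000)
}

#' Arrhenius fit of relaxation times against temperature
#'
#' For an activated process `tau ~ exp(E_a / (k_B T))`, so ln(tau) is
#' linear in 1/T with slope `E_a / k_B`.  The activation energy is
#' reported in J/mol and in units of k_B T0 (T0 = 298 K).
#'
#' @param temperature absolute temperatures (K), length >= 3.
#' @param tau relaxation times (s, > 0).
#' @param sigma_tau optional standard errors of `tau` (propagated to
#'   ln tau weights).
#' @return An object of class `arrhenius_fit`: `E_a_J_per_mol`,
#'   `E_a_kT0`, standard errors, and the `prefactor` (s).
#' @export
fit_arrhenius <- function(temperature, tau, sigma_tau = NULL) {
  stopifnot(length(temperature) == length(tau), length(tau) >= 3L)
  if (any(tau <= 0)) stop("non-positive relaxation time")
  if (any(temperature <= 0)) stop("temperatures must be in kelvin (> 0)")
  w <- if (is.null(sigma_tau)) rep(1, length(tau)) else {
    v <- (sigma_tau / tau)^2           # var(ln tau)
    ifelse(is.finite(v) & v > 0, 1 / v, NA_real_)
  }
  w[is.na(w)] <- if (all(is.na(w))) 1 else median(w, na.rm = TRUE)
  invT <- 1 / temperature
  fit <- lm(log(tau) ~ invT, weights = w)
  slope <- coef(fit)[[2L]]             # E_a / k_B, in kelvin
  se_slope <- sqrt(suppressWarnings(vcov(fit))[2L, 2L])
  structure(list(E_a_J_per_mol = .R_GAS * slope,
                 E_a_kT0 = slope / .T_ROOM,
                 se_E_a_J_per_mol = .R_GAS * se_slope,
                 se_E_a_kT0 = se_slope / .T_ROOM,
                 prefactor = exp(coef(fit)[[1L]]),
                 se_log_prefactor = sqrt(suppressWarnings(vcov(fit))[1L, 1L]),
                 temperature = temperature, tau = tau),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures: E_a = %.3g kJ/mol = %.3g kB T0 (+/- %.2g)\n",
              length(x$temperature), x$E_a_J_per_mol / 1000, x$E_a_kT0,
              x$se_E_a_kT0))
  invisible(x)
}

#' Fit templated-assembly rate constants to a forward-intensity trace
#'
#' Weighted least-squares fit of a measured I0(t) trace with the model
#' curve obtained by propagating the binding ladder from `init` and
#' mapping each state through [forward_intensity()].  By default only
#' k+ floats and k- is slaved to a known critical concentration
#' (`k- = k+ K_inv`); with `float_k_minus = TRUE` both rate constants
#' float.  The apparent subunit diffusion coefficient implied by the
#' fitted k+ is derived via [apparent_diffusion()].
#'
#' @param trace an [observable_trace()] of forward intensities.
#' @param comp a [mixture_composition()].
#' @param contrast a [contrast_set()].
#' @param params0 a [kinetic_parameters()] initial guess (also sets
#'   `n_max` and, unless `K_inv` is given, the fixed critical
#'   concentration).
#' @param K_inv fixed critical concentration (M); default
#'   `params0$K_inv`.  Ignored when `float_k_minus = TRUE`.
#' @param float_k_minus float k- as a second free parameter.
#' @param R_C capture radius (m) for the derived diffusion coefficient;
#'   default 120 Angstrom.
#' @param init initial [complex_distribution()]; default all genome bare.
#' @param fit_scale float a global intensity scale factor (default
#'   TRUE).  Absolute intensity calibration and the Guinier
#'   extrapolation both carry percent-level multiplicative error, which
#'   would otherwise leak into the rate constant; the optimal scale is
#'   profiled analytically at each step.
#' @param rtol ODE tolerance used inside the fit (default 1e-6; the
#'   final reported curve is recomputed at 1e-8).
#' @return An object of class `kinetic_fit`: `k_plus`, `se_k_plus`,
#'   `k_minus`, `D_S`, `tau_bind` (= 1/(k+ c_G)), `scale`, `chi2`,
#'   `dof`, `fitted` trace.
#' @export
fit_kinetic_params <- function(trace, comp, contrast, params0,
                               K_inv = NULL, float_k_minus = FALSE,
                               R_C = 120e-10,
                               init = NULL, fit_scale = TRUE,
                               rtol = 1e-6) {
  stopifnot(inherits(params0, "kinetic_parameters"),
            inherits(comp, "mixture_composition"),
            inherits(contrast, "contrast_set"))
  t <- trace$t; y <- trace$value
  s <- if (!is.null(trace$sigma)) trace$sigma else rep(0, length(t))
  stopifnot(length(t) >= 3L)
  w <- ifelse(is.finite(s) & s > 0, 1 / s^2, NA_real_)
  w[is.na(w)] <- if (all(is.na(w))) 1 else median(w, na.rm = TRUE)
  if (is.null(K_inv)) K_inv <- params0$K_inv
  if (is.null(init)) init <- bare_genome_distribution(comp, params0$n_max)

  times <- sort(unique(c(0, t)))
  model_I0 <- function(kp, km, tol = rtol) {
    par <- kinetic_parameters(kp, km, params0$n_max)
    tr <- propagate_ode(par, comp, init, times, rtol = tol)
    I <- vapply(tr$states, forward_intensity, numeric(1),
                contrast = contrast)
    I[match(t, times)]
  }
  prof_scale <- function(m) {
    if (!fit_scale) return(1)
    sum(w * y * m) / sum(w * m^2)
  }
  obj <- function(th) {
    kp <- exp(th[1L])
    km <- if (float_k_minus) exp(th[2L]) else kp * K_inv
    m <- tryCatch(model_I0(kp, km), error = function(e) NULL)
    if (is.null(m)) return(1e30)
    sum(w * (y - prof_scale(m) * m)^2)
  }

  th0 <- log(params0$k_plus)
  if (float_k_minus) {
    opt <- optim(c(th0, log(max(params0$k_minus, 1e-12))), obj,
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    th <- opt$par
  } else {
    opt <- optim(th0, obj, method = "Brent", lower = th0 - 8,
                 upper = th0 + 8, control = list(reltol = 1e-12))
    th <- opt$par
  }
  sse <- opt$value
  # identifiability: curvature of the objective in log k+, judged
  # against the weighted data scale (a flat objective means the trace
  # carries no kinetic information)
  h <- 0.05
  curv <- (obj(th + c(h, numeric(length(th) - 1L))) - 2 * sse +
             obj(th - c(h, numeric(length(th) - 1L)))) / h^2
  if (!is.finite(curv) || curv <= 1e-12 * sum(w * y^2))
    stop("kinetic fit is not identifiable: objective is flat in k+")

  k_plus <- exp(th[1L])
  k_minus <- if (float_k_minus) exp(th[2L]) else k_plus * K_inv
  dof <- length(t) - length(th)
  s2 <- if (dof > 0) sse / dof else 0
  se_log_kp <- sqrt(2 * s2 / curv)
  m_best <- model_I0(k_plus, k_minus, tol = 1e-8)
  scale <- prof_scale(m_best)
  fitted <- scale * m_best
  structure(list(k_plus = k_plus, se_k_plus = k_plus * se_log_kp,
                 k_minus = k_minus, K_inv = k_minus / k_plus,
                 float_k_minus = float_k_minus, scale = scale,
                 D_S = apparent_diffusion(k_plus, R_C), R_C = R_C,
                 tau_bind = 1 / (k_plus * comp$c_G),
                 chi2 = sse, dof = dof,
                 fitted = observable_trace(t, fitted,
                                           label = "I0 (model)")),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: k+ = %.4g +/- %.2g M^-1 s^-1 (k- %s = %.4g s^-1)\n",
              x$k_plus, x$se_k_plus,
              if (x$float_k_minus) "floated" else "slaved", x$k_minus))
  cat(sprintf("  apparent D_S = %.4g m^2/s at R_C = %.3g A; tau_bind = %.4g s\n",
              x$D_S, x$R_C * 1e10, x$tau_bind))
  invisible(x)
}
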