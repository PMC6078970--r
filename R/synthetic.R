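# Synthetic TR-SAXS/SANS data with known ground truth.
#
# Frame intensities are built species by species:
#   I(q) = dbS^2 X_S P_sub(q) + dbG^2 X_0 P_gen(q)
#        + [I0(Eq) - dbS^2 X_S - dbG^2 X_0] P_npc(q, t)
# so that I(q -> 0) equals the forward intensity of the ground-truth
# complex distribution exactly (all form factors obey P(0) = 1).  The
# complex form factor relaxes from an initial (amorphous) to a final
# (ordered shell) model with configurable exponential phases, emulating
# the structural self-organisation that sharpens the capsid arches.
# Noise is Gaussian with variance proportional to intensity (the photon
# counting limit); the flux scale is calibrated so the relative error on
# I0 matches `rel_sigma_I0`.

#' Contrast as a function of the D2O fraction (SANS)
#'
#' Linear contrast-variation model: each component's excess scattering
#' length interpolates through zero at its match point,
#' `db(f) = db_h2o (1 - f / f_match)`.  RNA matches at 68% D2O; protein
#' near 42%.
#'
#' @param f_d2o D2O volume fraction in `[0, 1]`.
#' @param db_G_h2o,db_S_h2o excess scattering lengths in pure H2O.
#' @param match_G,match_S match-point D2O fractions (defaults 0.68 and
#'   0.42).
#' @return a [contrast_set()] at that solvent composition.
#' @export
contrast_at_d2o <- function(f_d2o, db_G_h2o, db_S_h2o,
                            match_G = 0.68, match_S = 0.42) {
  stopifnot(f_d2o >= 0, f_d2o <= 1)
  db_G <- db_G_h2o * (1 - f_d2o / match_G)
  if (abs(db_G) < 1e-12 * abs(db_G_h2o)) db_G <- 0
  contrast_set(db_G = db_G, db_S = db_S_h2o * (1 - f_d2o / match_S))
}

#' Configuration of the synthetic frame-series generator
#'
#' @param params a [kinetic_parameters()].
#' @param comp a [mixture_composition()].
#' @param contrast a [contrast_set()].
#' @param times frame times (s), strictly increasing; default 60 frames
#'   log-spaced from the 5 ms exposure floor to `t_end`.
#' @param t_end experiment end (s), used only for the default `times`.
#' @param q wavenumber grid (1/Angstrom); default 120 points log-spaced
#'   over the instrument window 3.3e-3..0.26.
#' @param ff_subunit,ff_genome form factors of free subunit and bare
#'   genome, functions of q.  Defaults: sphere with the 33 Angstrom
#'   subunit radius of gyration; Gaussian chain with the 140 Angstrom
#'   genome radius of gyration.
#' @param ff_npc_initial,ff_npc_final complex form factors at the start
#'   and end of structural relaxation.  Defaults: Gaussian-chain blob
#'   (amorphous complex) and a hollow core-shell (ordered capsid) with
#'   3.5% size polydispersity, the dispersity cryo-TEM reports for
#'   reconstituted virions (29 +/- 1 nm).
#' @param tau_struc structural relaxation time constant(s), seconds; two
#'   values give a double-exponential relaxation.
#' @param struc_weights phase weights for `tau_struc` (same length,
#'   summing to 1).
#' @param init initial [complex_distribution()]; default all genome bare.
#' @param rel_sigma_I0 relative photon-noise level at the forward
#'   intensity (default 0.03, the 2-5% regime of synchrotron error bars);
#'   0 disables noise.
#' @param seed RNG seed; fixed seed gives bitwise-identical series.
#' @return A `generator_config` list.
#' @export
generator_config <- function(params, comp, contrast, times = NULL,
                             t_end = 600,
                             q = NULL,
                             ff_subunit = function(q)
                               sphere_form_factor(q, 33 * sqrt(5 / 3)),
                             ff_genome = function(q)
                               gaussian_chain_form_factor(q, 140),
                             ff_npc_initial = function(q)
                               gaussian_chain_form_factor(q, 105),
                             ff_npc_final = polydisperse_form_factor(
                               function(q) core_shell_form_factor(q, 95, 145),
                               sd_frac = 0.035),
                             tau_struc = 48,
                             struc_weights = rep(1 / length(tau_struc),
                                                 length(tau_struc)),
                             init = NULL,
                             rel_sigma_I0 = 0.03, seed = 1L) {
  if (is.null(times))
    times <- exp(seq(log(5e-3), log(t_end), length.out = 60L))
  if (is.null(q))
    q <- exp(seq(log(3.3e-3), log(0.26), length.out = 120L))
  stopifnot(all(diff(times) > 0), times[1L] > 0,
            length(tau_struc) == length(struc_weights),
            abs(sum(struc_weights) - 1) < 1e-9, rel_sigma_I0 >= 0)
  structure(list(params = params, comp = comp, contrast = contrast,
                 times = times, q = q, ff_subunit = ff_subunit,
                 ff_genome = ff_genome, ff_npc_initial = ff_npc_initial,
                 ff_npc_final = ff_npc_final, tau_struc = tau_struc,
                 struc_weights = struc_weights, init = init,
                 rel_sigma_I0 = rel_sigma_I0, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic TR-SAXS frame series with ground truth
#'
#' Propagates the templated assembly model across the frame times,
#' renders each frame's 1-D curve from the configured per-species form
#' factors, and adds seeded photon-counting noise.  The forward limit of
#' every noiseless frame equals the forward intensity of its ground-truth
#' distribution exactly.
#'
#' @param config a [generator_config()].
#' @return An object of class `frame_series`: `times`, `curves` (list of
#'   [scattering_curve()]), and `truth` (per-frame
#'   [complex_distribution()]s, noiseless `I0`, mean occupancies, the
#'   structural relaxation coordinate `alpha`, and the config).
#' @export
generate_frame_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  params <- config$params; comp <- config$comp; ctr <- config$contrast
  times <- config$times; q <- config$q
  init <- config$init
  if (is.null(init)) init <- bare_genome_distribution(comp, params$n_max)

  traj <- propagate_ode(params, comp, init, c(0, times))
  states <- traj$states[-1L]

  alpha <- 1 - drop(vapply(seq_along(config$tau_struc), function(i)
    config$struc_weights[i] * exp(-times / config$tau_struc[i]),
    numeric(length(times))) %*% rep(1, length(config$tau_struc)))
  P_sub <- config$ff_subunit(q)
  P_gen <- config$ff_genome(q)
  P_npc0 <- config$ff_npc_initial(q)
  P_npc1 <- config$ff_npc_final(q)

  I0_truth <- vapply(states, forward_intensity, numeric(1), contrast = ctr)
  flux <- if (config$rel_sigma_I0 > 0)
    1 / (config$rel_sigma_I0^2 * I0_truth[length(I0_truth)]) else NA_real_

  set.seed(config$seed)
  curves <- vector("list", length(times))
  for (i in seq_along(times)) {
    st <- states[[i]]
    I_sub <- ctr$db_S^2 * st$X_S
    I_gen <- ctr$db_G^2 * st$X[1L]
    I_npc <- I0_truth[i] - I_sub - I_gen
    P_npc <- (1 - alpha[i]) * P_npc0 + alpha[i] * P_npc1
    I <- I_sub * P_sub + I_gen * P_gen + I_npc * P_npc
    if (config$rel_sigma_I0 > 0) {
      sigma <- sqrt(pmax(I, 0) / flux)
      sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-12)
      I <- I + rnorm(length(q), 0, sigma)
    } else {
      sigma <- pmax(abs(I), max(abs(I)) * 1e-12) * 1e-10 + 1e-300
    }
    curves[[i]] <- scattering_curve(q, I, sigma)
  }
  structure(list(times = times, curves = curves,
                 truth = list(states = states, I0 = I0_truth,
                              mean_N = traj$mean_N[-1L], alpha = alpha,
                              config = config)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("Synthetic frame series: %d frames, t in [%g, %g] s, %d q points\n",
              length(x$times), min(x$times), max(x$times),
              length(x$curves[[1L]]$q)))
  invisible(x)
}

#' Generate noisy exponential observable traces with known truth
#'
#' Builds `sum_i A_i (1 - exp(-t/tau_i)) + offset` (rise) or
#' `sum_i A_i exp(-t/tau_i) + offset` (decay) traces plus seeded Gaussian
#' noise, for estimator recovery studies.
#'
#' @param times sample times (s).
#' @param tau time constant(s), seconds.
#' @param amplitudes amplitude(s), same length as `tau`.
#' @param direction `"rise"` or `"decay"`.
#' @param offset constant term (default 0).
#' @param noise_rel relative noise level (fraction of the trace's
#'   dynamic range).
#' @param noise_abs absolute noise level added in quadrature.
#' @param seed RNG seed; same seed, same trace.
#' @return an [observable_trace()] with attribute `truth` echoing the
#'   generating parameters.
#' @export
generate_observable_trace <- function(times, tau, amplitudes,
                                      direction = c("rise", "decay"),
                                      offset = 0, noise_rel = 0,
                                      noise_abs = 0, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(tau) == length(amplitudes), all(tau > 0))
  B <- .exp_basis(times, tau, direction, through_origin = TRUE)
  value <- drop(B %*% amplitudes) + offset
  span <- max(abs(diff(range(value))), max(abs(value)) * 1e-12)
  sigma <- rep(sqrt((noise_rel * span)^2 + noise_abs^2), length(times))
  set.seed(as.integer(seed))
  noisy <- value + if (any(sigma > 0)) rnorm(length(times), 0, sigma) else 0
  tr <- observable_trace(times, noisy, sigma)
  attr(tr, "truth") <- list(tau = tau, amplitudes = amplitudes,
                            offset = offset, direction = direction,
                            noiseless = value)
  tr
}

#' Generate a named set of observable traces
#'
#' @param specs named list; each element is a list of arguments for
#'   [generate_observable_trace()] (minus `times` and `seed`).
#' @param times common sample times.
#' @param seed base seed; trace i uses `seed + i - 1`.
#' @return named list of [observable_trace()]s.
#' @export
generate_observable_traces <- function(specs, times, seed = 1L) {
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    out[[i]] <- do.call(generate_observable_trace,
                        c(list(times = times, seed = seed + i - 1L),
                          specs[[i]]))
  }
  out
}
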