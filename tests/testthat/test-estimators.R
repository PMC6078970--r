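# Relaxation-time, titration, free-energy, rate-constant and Arrhenius
# estimators.

test_that("noiseless exponential fits are exact", {
  t <- exp(seq(log(5e-3), log(0.5), length.out = 40))
  tr <- generate_observable_trace(t, tau = 0.028, amplitudes = 77,
                                  direction = "rise")
  f <- fit_exponential(tr, 1, "rise", through_origin = TRUE)
  expect_equal(f$tau, 0.028, tolerance = 1e-7)
  expect_equal(f$amplitudes, 77, tolerance = 1e-7)
  expect_identical(f$offset, 0)

  # two-phase rise, amplitude ratio 1:3, reported binding time = slowest
  t2 <- exp(seq(log(1), log(20000), length.out = 60))
  tr2 <- generate_observable_trace(t2, tau = c(10, 3000),
                                   amplitudes = c(1, 3),
                                   direction = "rise")
  f2 <- fit_exponential(tr2, 2, "rise", through_origin = TRUE)
  expect_equal(f2$tau, c(10, 3000), tolerance = 1e-5)
  expect_equal(f2$tau_slow, 3000, tolerance = 1e-5)
  expect_equal(f2$amplitudes, c(1, 3), tolerance = 1e-5)

  # decay with offset
  t3 <- seq(1, 1200, length.out = 50)
  tr3 <- generate_observable_trace(t3, tau = 204, amplitudes = 17,
                                   direction = "decay", offset = 58)
  f3 <- fit_exponential(tr3, 1, "decay")
  expect_equal(f3$tau, 204, tolerance = 1e-6)
  expect_equal(f3$offset, 58, tolerance = 1e-6)

  expect_error(fit_exponential(tr3[1:4, ], 2, "decay"), "too few")
})

test_that("noisy decay time constant has small median bias (204 s case)", {
  t <- seq(2, 1200, length.out = 100)
  est <- vapply(1:50, function(s) {
    tr <- generate_observable_trace(t, tau = 204, amplitudes = 17,
                                    direction = "decay", offset = 58,
                                    noise_rel = 0.05, seed = 1000 + s)
    fit_exponential(tr, 1, "decay")$tau
  }, numeric(1))
  expect_lt(abs(median(est) / 204 - 1), 0.02)
})

test_that("1-sigma intervals of the exponential fit cover at a Gaussian rate", {
  t <- seq(2, 1200, length.out = 40)
  hits <- vapply(1:200, function(s) {
    tr <- generate_observable_trace(t, tau = 204, amplitudes = 17,
                                    direction = "decay", offset = 58,
                                    noise_rel = 0.04, seed = 3000 + s)
    f <- fit_exponential(tr, 1, "decay")
    abs(f$tau - 204) <= f$se_tau
  }, logical(1))
  expect_gt(mean(hits), 0.55)
  expect_lt(mean(hits), 0.85)
})

test_that("critical concentration fit inverts noiseless titrations exactly", {
  rho <- c(2, 4, 6, 8)
  N_inf <- (1 - 13.6 / 24.6) * 25 * rho
  fit <- fit_critical_concentration(rho, N_inf, c_S = 24.6e-6)
  expect_equal(fit$K_inv, 13.6e-6, tolerance = 1e-9)
  # ideal binding limit: slope = m_ratio -> K_inv = 0
  fit0 <- fit_critical_concentration(rho, 25 * rho, c_S = 24.6e-6)
  expect_equal(fit0$K_inv, 0, tolerance = 1e-12)
  expect_error(fit_critical_concentration(rho, 30 * rho, c_S = 24.6e-6),
               "m_ratio")
})

test_that("full equilibrium solver titration stays within 10% of K_inv", {
  # linearisation quality: generate <N>inf from the full solver
  rho <- c(2, 4, 6, 8)
  N_inf <- vapply(rho, function(r) {
    comp <- ref_comp(rho = r)
    moments(equilibrium_distribution(ref_params(n_max = 450L), comp))[["mean"]]
  }, numeric(1))
  fit <- fit_critical_concentration(rho, N_inf, c_S = 24.6e-6)
  expect_equal(fit$K_inv, 13.6e-6, tolerance = 0.1)
})

test_that("binding free energy units and ratios are consistent", {
  expect_equal(binding_free_energy(1e-3, reference_conc = 1e-3)$G_kT0, 0)
  # printed spread: G(13.6 uM) - G(10.9 uM) ~ 0.22 kT0
  dG <- binding_free_energy(13.6e-6)$G_kT0 -
    binding_free_energy(10.9e-6)$G_kT0
  expect_equal(dG, log(13.6 / 10.9), tolerance = 1e-9)
  expect_equal(dG, 0.221, tolerance = 0.005)
  # 1 M standard state gives -11.2 kT0, not the printed -6.7
  expect_equal(binding_free_energy(13.6e-6)$G_kT0, -11.2, tolerance = 0.005)
  # kJ/mol and kT0 representations agree through R*T0
  G <- binding_free_energy(13.6e-6)
  expect_equal(G$G_J_per_mol / (8.314462618 * 298), G$G_kT0,
               tolerance = 1e-9)
})

test_that("diffusion-limited rate constant and its inverse", {
  k <- diffusion_limited_rate(120e-10, 4.9e-12)
  expect_equal(k, 4.45e8, tolerance = 0.005)
  expect_equal(apparent_diffusion(k, 120e-10), 4.9e-12, tolerance = 1e-12)
  # a free-subunit diffusion coefficient of 3.0e-10 is ~61x larger
  k2 <- diffusion_limited_rate(120e-10, 3.0e-10)
  expect_equal(k2 / k, 3.0e-10 / 4.9e-12, tolerance = 1e-9)
  expect_gt(k2 / k, 50)
})

test_that("arrhenius fit recovers activation energies", {
  T0 <- 298
  Tk <- c(283, 293, 303, 313)
  tau <- 3100 * exp(20 * T0 * (1 / Tk - 1 / 293))
  fit <- fit_arrhenius(Tk, tau)
  expect_equal(fit$E_a_kT0, 20, tolerance = 1e-9)
  # E_a = 0: flat
  expect_equal(fit_arrhenius(Tk, rep(100, 4))$E_a_kT0, 0, tolerance = 1e-12)
  expect_error(fit_arrhenius(Tk, c(-1, 1, 1, 1)), "non-positive")
  expect_error(fit_arrhenius(Tk[1:2], tau[1:2]), "length")
})

test_that("arrhenius estimator is unbiased under lognormal noise", {
  Tk <- c(283, 293, 303, 313)
  tau0 <- 3100 * exp(20 * 298 * (1 / Tk - 1 / 293))
  set.seed(55)
  est <- se <- numeric(100)
  for (i in 1:100) {
    tau <- tau0 * exp(rnorm(4, 0, 0.1))
    f <- fit_arrhenius(Tk, tau)
    est[i] <- f$E_a_kT0
    se[i] <- f$se_E_a_kT0
  }
  # mean estimate within its (ensemble-averaged) propagated s.e.
  expect_lt(abs(mean(est) - 20), mean(se))
})

test_that("kinetic fit recovers rate constants from forward intensities", {
  comp <- ref_comp(rho = 8)
  ct <- contrast_set(db_G = 20, db_S = 1)
  kp_true <- diffusion_limited_rate(120e-10, 4.9e-12)
  p_true <- kinetic_parameters(kp_true, kp_true * 13.6e-6, n_max = 300L)
  times <- exp(seq(log(1e-3), log(0.5), length.out = 35))
  tr <- propagate_ode(p_true, comp, bare_genome_distribution(comp, 300L),
                      c(0, times))
  I0 <- vapply(tr$states[-1], forward_intensity, numeric(1), contrast = ct)

  # noiseless self-consistency from a distorted initial guess
  p0 <- kinetic_parameters(kp_true * 5, kp_true * 5 * 13.6e-6, 300L)
  kf <- fit_kinetic_params(observable_trace(times, I0), comp, ct, p0,
                           K_inv = 13.6e-6)
  expect_equal(kf$k_plus, kp_true, tolerance = 1e-3)
  expect_equal(kf$D_S, 4.9e-12, tolerance = 2e-3)

  # photon-like noise: tau = 1/(k+ c_G) recovered within noise
  set.seed(77)
  sig <- 0.03 * I0
  trn <- observable_trace(times, I0 + rnorm(35, 0, sig), sig)
  kfn <- fit_kinetic_params(trn, comp, ct, p0, K_inv = 13.6e-6)
  expect_equal(kfn$tau_bind, 1 / (kp_true * comp$c_G), tolerance = 0.1)
  # the apparent diffusion coefficient sits ~2 orders below the
  # free-subunit one
  expect_lt(kfn$D_S, 3.0e-10 / 30)
})

test_that("kinetic fit signals non-identifiable traces", {
  comp <- ref_comp()
  ct <- contrast_set(db_G = 20, db_S = 1)
  p0 <- ref_params(n_max = 100L)
  # times far beyond saturation for every admissible k+: with k- slaved
  # to K_inv the equilibrium is k+-independent, so the objective is flat
  flat <- observable_trace(c(1000, 2000, 3000),
                           rep(baseline_intensity(comp, ct), 3))
  expect_error(fit_kinetic_params(flat, comp, ct, p0, K_inv = 13.6e-6),
               "identifiable")
})
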