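# Form factors, the frame-series generator, observable traces and
# file round trips.

test_that("form factors are normalised and match closed-form anchors", {
  q <- c(0, 1e-4, 0.01, 0.1)
  expect_equal(sphere_form_factor(0, 50), 1)
  expect_equal(core_shell_form_factor(0, 95, 145), 1)
  expect_equal(gaussian_chain_form_factor(0, 140), 1)
  expect_equal(polydisperse_form_factor(
    function(q) core_shell_form_factor(q, 95, 145))(0), 1)
  # Debye function at q Rg = 1 (u = 1): 2 (e^-1 - 1 + 1) / 1 = 2/e
  expect_equal(gaussian_chain_form_factor(1, 1), 2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(gaussian_chain_form_factor(1, 1), 0.7358, tolerance = 1e-4)
  # sphere first zero at x = qR ~ 4.4934 (first positive root of
  # tan x = x, located independently by brute-force root finding)
  x_zero <- uniroot(function(x) tan(x) - x, c(pi + 0.1, 1.5 * pi - 0.1),
                    tol = 1e-12)$root
  expect_equal(x_zero, 4.4934, tolerance = 1e-4)
  f <- function(x) sphere_form_factor(x, 1)
  expect_lt(f(x_zero), 1e-12)
  # non-physical inputs
  expect_error(sphere_form_factor(-0.1, 50), "q")
  expect_error(sphere_form_factor(0.1, -5), "radius")
  expect_error(core_shell_form_factor(0.1, 145, 95), "radii")
  expect_error(gaussian_chain_form_factor(0.1, 0), "radius")
})

test_that("generated frames hit the forward-intensity identity exactly", {
  comp <- ref_comp()
  p <- ref_params(n_max = 200L)
  # put a near-zero q point on the grid so I(q -> 0) is directly visible
  q <- c(1e-8, exp(seq(log(3.3e-3), log(0.26), length.out = 80)))
  cfg <- generator_config(p, comp, contrast_set(20, 1),
                          times = c(0.01, 0.1, 1), q = q,
                          rel_sigma_I0 = 0)
  ser <- generate_frame_series(cfg)
  for (i in 1:3) {
    I0_truth <- forward_intensity(ser$truth$states[[i]], cfg$contrast)
    expect_equal(ser$curves[[i]]$I[1], I0_truth, tolerance = 1e-9)
    expect_equal(ser$truth$I0[i], I0_truth, tolerance = 1e-12)
  }
})

test_that("a bare-genome series shows the genome radius of gyration", {
  # negligible subunits and frozen kinetics: frames are all genome
  comp <- mixture_composition(c_S = 1e-15, c_G = 0.164e-6)
  p <- kinetic_parameters(1e-6, 1e-6, n_max = 2)
  cfg <- generator_config(p, comp, contrast_set(20, 1e-6),
                          times = c(1, 2), rel_sigma_I0 = 0,
                          init = bare_genome_distribution(comp, 2))
  ser <- generate_frame_series(cfg)
  expect_equal(ser$curves[[1]]$I, ser$curves[[2]]$I, tolerance = 1e-12)
  gf <- guinier_fit(ser$curves[[1]])
  # Guinier on a Debye chain is biased low by ~8% at q Rg <= 1.3 (the
  # chain's ln I is not quadratic that far out); a tighter window
  # converges towards the true 140 A
  expect_equal(gf$Rg, 140, tolerance = 0.10)
  gf_tight <- guinier_fit(ser$curves[[1]], q_rg_max = 0.7)
  expect_equal(gf_tight$Rg, 140, tolerance = 0.04)
  expect_gt(gf_tight$Rg, gf$Rg)
})

test_that("contrast matching at 68% D2O removes the genome", {
  ct <- contrast_at_d2o(0.68, db_G_h2o = 30, db_S_h2o = 2)
  expect_identical(ct$db_G, 0)
  expect_equal(ct$gamma, -0.5)
  # frames become independent of the genome form factor
  comp <- ref_comp()
  p <- ref_params(n_max = 150L)
  mk <- function(ffg) generate_frame_series(generator_config(
    p, comp, ct, times = c(0.005, 0.02), rel_sigma_I0 = 0,
    ff_genome = ffg))
  s1 <- mk(function(q) gaussian_chain_form_factor(q, 140))
  s2 <- mk(function(q) sphere_form_factor(q, 60))
  expect_equal(s1$curves[[1]]$I, s2$curves[[1]]$I, tolerance = 1e-12)
})

test_that("the generator is bitwise deterministic under a fixed seed", {
  comp <- ref_comp()
  p <- ref_params(n_max = 150L)
  cfg <- generator_config(p, comp, contrast_set(20, 1),
                          times = c(0.005, 0.05, 0.5), seed = 33)
  s1 <- generate_frame_series(cfg)
  s2 <- generate_frame_series(cfg)
  expect_identical(s1$curves, s2$curves)
  cfg2 <- generator_config(p, comp, contrast_set(20, 1),
                           times = c(0.005, 0.05, 0.5), seed = 34)
  expect_false(identical(generate_frame_series(cfg2)$curves, s1$curves))
})

test_that("observable traces: zero noise is exact, seeds reproduce", {
  t <- seq(0.001, 0.2, length.out = 30)
  tr0 <- generate_observable_trace(t, 0.028, 77, "rise")
  expect_equal(tr0$value, 77 * (1 - exp(-t / 0.028)), tolerance = 1e-12)
  trA <- generate_observable_trace(t, 0.028, 77, "rise", noise_rel = 0.05,
                                   seed = 5)
  trB <- generate_observable_trace(t, 0.028, 77, "rise", noise_rel = 0.05,
                                   seed = 5)
  expect_identical(trA$value, trB$value)
  specs <- list(a = list(tau = 1, amplitudes = 2, direction = "decay"),
                b = list(tau = 2, amplitudes = 1, direction = "rise"))
  ts <- generate_observable_traces(specs, times = t, seed = 9)
  expect_named(ts, c("a", "b"))
})

test_that("tau is recovered from paper-like noisy occupancy traces", {
  # plateau ~77, tau = 28 ms, 5% noise
  t <- exp(seq(log(5e-3), log(0.3), length.out = 40))
  rel_err <- vapply(1:40, function(s) {
    tr <- generate_observable_trace(t, 0.028, 77, "rise",
                                    noise_rel = 0.05, seed = 500 + s)
    f <- fit_exponential(tr, 1, "rise", through_origin = TRUE)
    abs(f$tau - 0.028) / 0.028
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
  expect_lt(unname(quantile(rel_err, 0.9)), 0.10)
})

test_that("curve and series files round-trip", {
  q <- exp(seq(log(3.3e-3), log(0.26), length.out = 40))
  cv <- scattering_curve(q, 5 * exp(-q^2 * 900), rep(0.01, 40))
  f <- tempfile(fileext = ".dat")
  write_curve_dat(cv, f, comments = c("synthetic fixture"))
  cv2 <- read_curve_dat(f)
  expect_equal(cv2$q, cv$q, tolerance = 1e-7)
  expect_equal(cv2$I, cv$I, tolerance = 1e-7)
  expect_equal(cv2$sigma, cv$sigma, tolerance = 1e-7)

  comp <- ref_comp()
  p <- ref_params(n_max = 120L)
  ser <- generate_frame_series(generator_config(
    p, comp, contrast_set(20, 1), times = c(0.01, 0.1), seed = 2))
  d <- tempfile("series")
  manifest <- write_frame_series(ser, d)
  expect_true(file.exists(file.path(d, "truth.json")))
  back <- read_frame_series(manifest)
  expect_equal(back$times, ser$times)
  expect_equal(back$curves[[2]]$I, ser$curves[[2]]$I, tolerance = 1e-7)
})
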