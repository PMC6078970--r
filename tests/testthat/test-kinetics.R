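# Templated assembly ladder: types, deterministic and stochastic
# propagation, equilibrium solutions.

test_that("parameter and composition constructors validate their inputs", {
  p <- kinetic_parameters(2.2e8, 2.2e8 * 13.6e-6, n_max = 200)
  expect_equal(p$K_inv, 13.6e-6)
  expect_error(kinetic_parameters(-1, 0, 10), "k_plus")
  expect_error(kinetic_parameters(1, -1, 10), "k_minus")
  expect_error(kinetic_parameters(1, 0, 0), "n_max")

  comp <- mixture_composition(c_S = 24.6e-6, rho = 6)
  expect_equal(comp$c_G, 24.6e-6 / 150)
  expect_equal(comp$rho, 6)
  expect_error(mixture_composition(c_S = 1e-6, c_G = 1e-6, rho = 6),
               "inconsistent")
  expect_equal(default_n_max(comp), 450L)
  expect_equal(default_n_max(mixture_composition(1e-3, 1e-9)), 500L)
})

test_that("complex distributions enforce non-negativity and conservation", {
  comp <- mixture_composition(c_S = 12e-6, c_G = 1e-6)
  X <- c(0.5e-6, 0.5e-6, rep(0, 9))
  d <- complex_distribution(X, X_S = 12e-6 - 0.5e-6, comp = comp)
  expect_equal(bound_subunits(d), 0.5e-6)
  expect_error(complex_distribution(-X, 1e-6), "negative")
  expect_error(complex_distribution(X, X_S = 5e-6, comp = comp),
               "conservation")
})

test_that("moments match point-mass, uniform and geometric oracles", {
  # all mass at N = 10
  X <- numeric(21); X[11] <- 3
  expect_equal(unname(moments(X)), c(10, 100))
  # uniform on {0, 1, 2}
  expect_equal(unname(moments(rep(1, 3))), c(1, 5 / 3))
  # geometric r = 0.9, closed form <N> = r/(1-r), <N^2> = r(1+r)/(1-r)^2
  g <- geometric_distribution(0.9, n_max = 2000)
  m <- moments(g)
  expect_equal(m[["mean"]], 0.9 / 0.1, tolerance = 1e-9)
  expect_equal(m[["second"]], 0.9 * 1.9 / 0.01, tolerance = 1e-9)
  expect_error(moments(numeric(5)), "zero")
})

test_that("ODE propagation conserves genome and subunits across regimes", {
  sets <- list(ref_params(), ref_params(k_plus = 1e6, K_inv = 1e-6),
               ref_params(k_plus = 5e4, K_inv = 40e-6))
  comp <- ref_comp()
  for (p in sets) {
    tr <- propagate_ode(p, comp, bare_genome_distribution(comp, p$n_max),
                        times = c(0, 1e-3, 0.1, 2))
    for (st in tr$states) {
      expect_lt(abs(sum(st$X) - comp$c_G), 1e-6 * comp$c_G)
      expect_lt(abs(st$X_S + bound_subunits(st) - comp$c_S),
                1e-6 * comp$c_S)
      expect_true(all(st$X >= 0))
    }
  }
})

test_that("irreversible and no-binding limits behave as mass balance dictates", {
  # k- = 0, n_max small: everything piles to n_max, X_S -> c_S - n_max c_G
  comp <- mixture_composition(c_S = 20e-6, c_G = 1e-6)
  p <- kinetic_parameters(2e8, 0, n_max = 5)
  tr <- propagate_ode(p, comp, bare_genome_distribution(comp, 5),
                      times = c(0, 10))
  st <- tr$states[[2]]
  expect_equal(st$X[6], comp$c_G, tolerance = 1e-6)
  expect_equal(st$X_S, 20e-6 - 5 * 1e-6, tolerance = 1e-6)

  # k+ c_S << k-: stays essentially bare
  p2 <- kinetic_parameters(1e3, 1e4, n_max = 50)   # K_inv = 10 M >> c_S
  tr2 <- propagate_ode(p2, ref_comp(), bare_genome_distribution(ref_comp(), 50),
                       times = c(0, 5))
  expect_lt(tr2$mean_N[2], 1e-3)
})

test_that("non-conserving initial states are rejected", {
  comp <- ref_comp()
  bad <- complex_distribution(c(comp$c_G / 2, rep(0, 200)), comp$c_S)
  expect_error(propagate_ode(ref_params(), comp, bad, c(0, 1)),
               "conservation")
  expect_error(propagate_ode(ref_params(), comp,
                             bare_genome_distribution(comp, 200),
                             times = c(1, 0.5)), "increasing")
})

test_that("long-time ODE state matches the equilibrium solver", {
  # c_S = 24.6 uM, c_G = 0.164 uM, K_inv = 13.6 uM: <N> -> ~67
  comp <- ref_comp()
  p <- ref_params(n_max = 450L)
  eq <- equilibrium_distribution(p, comp)
  tr <- propagate_ode(p, comp, bare_genome_distribution(comp, 450L),
                      times = c(0, 20))
  st <- tr$states[[2]]
  expect_lt(max(abs(st$X - eq$X)) / max(eq$X), 1e-3)
  expect_equal(tr$mean_N[2], moments(eq)[["mean"]], tolerance = 1e-3)
  expect_equal(moments(eq)[["mean"]],
               equilibrium_mean_approx(comp$c_S, comp$c_G, 13.6e-6),
               tolerance = 0.02)
})

test_that("equilibrium distribution satisfies detailed balance", {
  comp <- ref_comp()
  p <- ref_params(n_max = 300L)
  eq <- equilibrium_distribution(p, comp)
  r <- eq$X_S / p$K_inv
  ratios <- eq$X[-1] / eq$X[-length(eq$X)]
  expect_equal(ratios, rep(r, 300), tolerance = 1e-9)
  expect_lt(abs(sum(eq$X) - comp$c_G), 1e-9 * comp$c_G)
  # sub-critical regime: mean small
  eq2 <- equilibrium_distribution(ref_params(K_inv = 100e-6), comp)
  expect_lt(moments(eq2)[["mean"]], 0.5)
  expect_error(equilibrium_distribution(
    kinetic_parameters(1e8, 0, 100), comp), "K_inv")
})

test_that("equilibrium mean approximation and its edge cases", {
  expect_equal(equilibrium_mean_approx(24.6e-6, 0.164e-6, 13.6e-6),
               (24.6 - 13.6) / 0.164, tolerance = 1e-12)
  expect_equal(as.numeric(equilibrium_mean_approx(10e-6, 1e-6, 10e-6)), 0)
  # homogeneity: doubling c_G halves the mean
  expect_equal(equilibrium_mean_approx(24.6e-6, 2 * 0.164e-6, 13.6e-6),
               equilibrium_mean_approx(24.6e-6, 0.164e-6, 13.6e-6) / 2)
  expect_warning(v <- equilibrium_mean_approx(5e-6, 1e-6, 13.6e-6),
                 "sub-critical")
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "subcritical"))
})

test_that("gillespie is deterministic under a fixed seed", {
  comp <- ref_comp()
  p <- ref_params(n_max = 150L)
  g1 <- simulate_gillespie(p, comp, 100, seed = 11, t_end = 0.05,
                           max_events = 500)
  g2 <- simulate_gillespie(p, comp, 100, seed = 11, t_end = 0.05,
                           max_events = 500)
  expect_identical(g1$occupancy, g2$occupancy)
  expect_identical(g1$events, g2$events)
  g3 <- simulate_gillespie(p, comp, 100, seed = 12, t_end = 0.05)
  expect_false(identical(g1$occupancy, g3$occupancy))
})

test_that("irreversible gillespie trajectories are non-decreasing", {
  comp <- ref_comp()
  p <- kinetic_parameters(2.2e8, 0, n_max = 150)
  g <- simulate_gillespie(p, comp, 80, seed = 3, t_end = 0.1,
                          record_times = seq(0.005, 0.1, by = 0.005))
  expect_true(all(apply(g$occupancy, 2L, function(x) all(diff(x) >= 0))))
})

test_that("gillespie ensemble mean matches the ODE within 3 sem", {
  comp <- ref_comp()
  p <- ref_params(n_max = 150L)
  rec <- c(0.01, 0.05, 0.15)
  g <- simulate_gillespie(p, comp, 400, seed = 21, t_end = 0.15,
                          record_times = rec)
  tr <- propagate_ode(p, comp, bare_genome_distribution(comp, 150L),
                      times = c(0, rec))
  z <- abs(g$mean_N - tr$mean_N[-1]) / g$sem_N
  expect_true(all(z < 3))
  expect_error(simulate_gillespie(p, mixture_composition(1e-12, 1e-6),
                                  10, 1, 1), "copy number")
})

test_that("ODE mean relaxes with the mean-field time 1/(k+ c_G)", {
  comp <- ref_comp()
  p <- ref_params(n_max = 450L)
  tau_mf <- 1 / (p$k_plus * comp$c_G)        # ~27.7 ms
  times <- seq(1e-3, 4 * tau_mf, length.out = 40)
  tr <- propagate_ode(p, comp, bare_genome_distribution(comp, 450L),
                      times = c(0, times))
  fit <- fit_exponential(observable_trace(times, tr$mean_N[-1]),
                         n_phases = 1, direction = "rise",
                         through_origin = TRUE)
  expect_equal(fit$tau, tau_mf, tolerance = 0.05)
})

test_that("trajectory CSV export has the documented deterministic layout", {
  comp <- mixture_composition(c_S = 10e-6, c_G = 1e-6)
  p <- kinetic_parameters(1e7, 10, n_max = 4)
  tr <- propagate_ode(p, comp, bare_genome_distribution(comp, 4),
                      times = c(0, 0.5, 1))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- read.csv(f, check.names = FALSE)
  expect_identical(names(df),
                   c("time_s", paste0("X_", 0:4), "X_S", "mean_N"))
  expect_equal(df$time_s, c(0, 0.5, 1))
  expect_equal(df$X_S[1], 10e-6)
})
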