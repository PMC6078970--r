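# Deterministic propagation of the templated assembly ladder
#
#   dX_N/dt = k+ X_S X_{N-1} + k- X_{N+1} - k+ X_S X_N - k- X_N
#
# with the N = 0 and N = n_max boundary terms dropped and X_S eliminated
# through subunit conservation, X_S = c_S - sum(N X_N).  The system is
# moderately stiff (k+ X_S and k+ c_G can differ by the molar ratio, and
# rate constants span ms..hour scales), so we use a linearly implicit
# Rosenbrock(2,3) stepper (the ode23s scheme) with an analytic Jacobian.
# The Jacobian is tridiagonal plus a rank-one term from the X_S coupling;
# each stage solve is O(n) via the Thomas algorithm and the
# Sherman-Morrison identity.

.ladder_rhs <- function(X, b, km, n1) {
  up <- b * X
  up[n1] <- 0                      # no binding beyond n_max
  down <- km * X
  down[1L] <- 0                    # bare genome cannot unbind
  c(0, up[-n1]) - up + c(down[-1L], 0) - down
}

# One ode23s step.  Returns list(y, err_norm) or NULL if the linear
# solver failed (caller retries with a smaller step via dense fallback).
.ros23_step <- function(y, h, kp, km, c_S, n1, sk_fun) {
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  N <- 0:(n1 - 1L)
  X_S <- c_S - sum(N * y)
  b <- kp * X_S

  # Jacobian J = T + w v', T tridiagonal
  ind_bind <- c(rep(1, n1 - 1L), 0)    # N < n_max
  ind_unb <- c(0, rep(1, n1 - 1L))     # N >= 1
  Tdiag <- -b * ind_bind - km * ind_unb
  Tsub <- rep(b, n1 - 1L)              # effect of X_{N-1}
  Tsup <- rep(km, n1 - 1L)             # effect of X_{N+1}
  w <- c(0, y[-n1]) - y * ind_bind     # d(rhs)/d(b)
  v <- -kp * N                         # d(b)/d(X)

  hd <- h * d
  A_d <- 1 - hd * Tdiag
  A_dl <- -hd * Tsub
  A_du <- -hd * Tsup
  p <- -hd * w                          # W = A + p v'

  Ap <- .tridiag_solve(A_dl, A_d, A_du, matrix(p, ncol = 1L))
  if (is.null(Ap)) return(NULL)
  Ap <- Ap[, 1L]
  denom <- 1 + sum(v * Ap)
  if (!is.finite(denom) || abs(denom) < 1e-300) return(NULL)
  wsolve <- function(rhs) {
    Ab <- .tridiag_solve(A_dl, A_d, A_du, matrix(rhs, ncol = 1L))
    if (is.null(Ab)) return(NULL)
    Ab <- Ab[, 1L]
    Ab - Ap * (sum(v * Ab) / denom)
  }

  F0 <- .ladder_rhs(y, b, km, n1)
  k1 <- wsolve(F0)
  if (is.null(k1)) return(NULL)
  y_half <- y + 0.5 * h * k1
  F1 <- .ladder_rhs(y_half, kp * (c_S - sum(N * y_half)), km, n1)
  k2 <- wsolve(F1 - k1)
  if (is.null(k2)) return(NULL)
  k2 <- k2 + k1
  y1 <- y + h * k2
  F2 <- .ladder_rhs(y1, kp * (c_S - sum(N * y1)), km, n1)
  k3 <- wsolve(F2 - e32 * (k2 - F1) - 2 * (k1 - F0))
  if (is.null(k3)) return(NULL)

  err <- (h / 6) * (k1 - 2 * k2 + k3)
  list(y = y1, err_norm = max(abs(err) / sk_fun(y, y1)))
}

.integrate_ladder <- function(y0, t0, t1, kp, km, c_S, rtol, atol,
                              max_steps = 2e6L) {
  n1 <- length(y0)
  sk_fun <- function(a, b) atol + rtol * pmax(abs(a), abs(b))
  y <- y0
  t <- t0
  rate0 <- kp * c_S + km + 1e-300
  h <- min(0.01 / rate0, (t1 - t0))
  steps <- 0L
  while (t < t1) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("ODE solver failed to converge: step budget exceeded at t = ",
           signif(t, 6), " s")
    h <- min(h, t1 - t)
    st <- .ros23_step(y, h, kp, km, c_S, n1, sk_fun)
    if (is.null(st) || !all(is.finite(st$y))) {
      h <- h / 4
      if (h < 1e-15 * max(t1, 1)) stop("ODE solver stalled: step size underflow")
      next
    }
    if (st$err_norm <= 1 && all(st$y > -100 * atol)) {
      t <- t + h
      y <- st$y
      y[y < 0] <- 0
      h <- h * min(5, max(0.2, 0.9 * st$err_norm^(-1 / 3)))
    } else {
      h <- h * min(0.9, max(0.1, 0.9 * max(st$err_norm, 1e-10)^(-1 / 3)))
    }
  }
  y
}

#' Propagate the templated assembly model deterministically
#'
#' Integrates the master-equation ladder for the complex concentrations
#' X_0..X_nmax with the free subunit concentration eliminated through
#' conservation.  `init` is the state at `times[1]`; one state per
#' requested time is returned (the first being `init` itself).
#'
#' @param params a [kinetic_parameters()].
#' @param comp a [mixture_composition()].
#' @param init a [complex_distribution()] satisfying both conservation
#'   laws for `comp` (checked; non-conserving input is rejected).
#' @param times strictly increasing numeric vector of seconds,
#'   `times[1] >= 0`.
#' @param rtol,atol relative/absolute integration tolerances.  `atol`
#'   defaults to `10 * rtol * c_G`, i.e. absolute error is controlled
#'   relative to the genome concentration scale.
#' @return An object of class `kinetic_trajectory`: list with `times`,
#'   `states` (list of [complex_distribution()]), `mean_N`, `X_S`,
#'   `params`, `comp`.
#' @examples
#' comp <- mixture_composition(c_S = 24.6e-6, rho = 6)
#' par <- kinetic_parameters(2.2e8, 2.2e8 * 13.6e-6, n_max = 200)
#' tr <- propagate_ode(par, comp, bare_genome_distribution(comp, 200),
#'                     times = c(0, 0.01, 0.1, 1))
#' tr$mean_N
#' @export
propagate_ode <- function(params, comp, init, times, rtol = 1e-8,
                          atol = NULL) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(comp, "mixture_composition"),
            inherits(init, "complex_distribution"))
  if (length(times) < 1L || any(diff(times) <= 0) || times[1L] < 0)
    stop("times must be strictly increasing with times[1] >= 0")
  if (init$n_max != params$n_max)
    stop("init truncation order does not match params$n_max")
  assert_conserved(init, comp, tol = 1e-6)
  if (is.null(atol)) atol <- 10 * rtol * max(comp$c_G, comp$c_S * 1e-6)

  n1 <- params$n_max + 1L
  N <- 0:params$n_max
  states <- vector("list", length(times))
  y <- init$X
  states[[1L]] <- init
  if (comp$c_G > 0) {
    for (i in seq_along(times)[-1L]) {
      y <- .integrate_ladder(y, times[i - 1L], times[i], params$k_plus,
                             params$k_minus, comp$c_S, rtol, atol)
      # genome conservation is analytic in the ladder; renormalise the
      # accumulated round-off so downstream checks see exact totals
      drift <- sum(y) - comp$c_G
      if (abs(drift) > 1e-3 * comp$c_G)
        stop("ODE solver lost genome conservation (relative drift ",
             signif(drift / comp$c_G, 3), ")")
      y <- y * (comp$c_G / sum(y))
      states[[i]] <- complex_distribution(y, max(0, comp$c_S - sum(N * y)))
    }
  } else {
    for (i in seq_along(times)[-1L])
      states[[i]] <- complex_distribution(numeric(n1), comp$c_S)
  }
  mean_N <- vapply(states, function(s)
    if (comp$c_G > 0) sum(N * s$X) / sum(s$X) else NA_real_, numeric(1))
  structure(list(times = times, states = states, mean_N = mean_N,
                 X_S = vapply(states, function(s) s$X_S, numeric(1)),
                 params = params, comp = comp),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf("Kinetic trajectory: %d states, t in [%g, %g] s, final <N> = %.4g\n",
              length(x$times), min(x$times), max(x$times),
              x$mean_N[length(x$mean_N)]))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trajectory <- function(x, ...) {
  Xmat <- t(vapply(x$states, function(s) s$X, numeric(x$params$n_max + 1L)))
  colnames(Xmat) <- paste0("X_", 0:x$params$n_max)
  data.frame(time_s = x$times, Xmat, X_S = x$X_S, mean_N = x$mean_N,
             check.names = FALSE)
}

#' Write a kinetic trajectory as CSV
#'
#' Columns: time_s, X_0..X_nmax, X_S, mean_N, in that (deterministic)
#' order.
#'
#' @param traj a `kinetic_trajectory` from [propagate_ode()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Equilibrium distribution of the templated assembly model
#'
#' At equilibrium, detailed balance makes the occupancy distribution a
#' (truncated) geometric: X_{N+1}/X_N = X_S / K^{-1}.  The free subunit
#' concentration is solved self-consistently: the bound-subunit total is
#' strictly increasing in X_S, so X_S is the unique root of
#' X_S + c_G <N>(X_S) = c_S in (0, c_S], located by root bracketing to
#' 1e-12 relative tolerance.
#'
#' @param params a [kinetic_parameters()] with `K_inv > 0`.
#' @param comp a [mixture_composition()].
#' @param tol relative tolerance on X_S.
#' @return a [complex_distribution()].
#' @export
equilibrium_distribution <- function(params, comp, tol = 1e-12) {
  if (params$K_inv <= 0)
    stop("equilibrium_distribution requires K_inv > 0 (k_minus > 0)")
  n_max <- params$n_max
  N <- 0:n_max
  if (comp$c_G <= 0)
    return(complex_distribution(numeric(n_max + 1L), comp$c_S))
  geom_X <- function(X_S) {
    lr <- N * (log(X_S) - log(params$K_inv))
    w <- exp(lr - max(lr))
    comp$c_G * w / sum(w)
  }
  g <- function(X_S) X_S + sum(N * geom_X(X_S)) - comp$c_S
  lo <- comp$c_S * 1e-14
  if (g(lo) >= 0) stop("no self-consistent X_S in (0, c_S): infeasible")
  root <- uniroot(g, c(lo, comp$c_S), tol = tol * comp$c_S)$root
  X <- geom_X(root)
  complex_distribution(X, X_S = comp$c_S - sum(N * X), comp = comp)
}

#' Linearised equilibrium mean occupancy
#'
#' In the pre-saturation regime the equilibrium mean number of subunits
#' per complex is `<N>(t -> Inf) ~= (c_S - K_inv) / c_G`.  Below the
#' critical concentration (`c_S <= K_inv`) the mean is effectively zero;
#' the returned value is then 0 with attribute `subcritical = TRUE` and a
#' warning.
#'
#' @param c_S total subunit concentration (M).
#' @param c_G total genome concentration (M, > 0).
#' @param K_inv critical concentration k-/k+ (M).
#' @return the approximate mean occupancy (numeric scalar).
#' @export
equilibrium_mean_approx <- function(c_S, c_G, K_inv) {
  stopifnot(c_S > 0, c_G > 0, K_inv >= 0)
  if (c_S < K_inv) {
    warning("sub-critical regime: c_S <= K_inv, no complexes accumulate")
    return(structure(0, subcritical = TRUE))
  }
  (c_S - K_inv) / c_G
}
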