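#' Kinetic parameters of the templated assembly model
#'
#' Bundles the uniform forward and backward rate constants of the binding
#' ladder \eqn{C_N + S \rightleftharpoons C_{N+1}} together with the
#' truncation order `n_max` (the largest complex order retained).  The
#' derived critical concentration \eqn{K^{-1} = k^-/k^+} is the free
#' subunit concentration above which complexes accumulate.
#'
#' @param k_plus forward rate constant, M^-1 s^-1 (> 0).
#' @param k_minus backward rate constant, s^-1 (>= 0).
#' @param n_max maximal complex order (positive integer).  The default,
#'   used by [default_n_max()], is three times the subunit-to-genome molar
#'   ratio, capped at 500, which keeps truncation error negligible for
#'   occupancies in the tens.
#' @return An object of class `kinetic_parameters` with fields `k_plus`,
#'   `k_minus`, `n_max` and the derived `K_inv` (molar).
#' @examples
#' kinetic_parameters(k_plus = 2.2e8, k_minus = 2.2e8 * 13.6e-6, n_max = 200)
#' @export
kinetic_parameters <- function(k_plus, k_minus, n_max) {
  stopifnot(is.numeric(k_plus), length(k_plus) == 1L, is.finite(k_plus),
            is.numeric(k_minus), length(k_minus) == 1L, is.finite(k_minus),
            is.numeric(n_max), length(n_max) == 1L)
  if (k_plus <= 0) stop("k_plus must be > 0")
  if (k_minus < 0) stop("k_minus must be >= 0")
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("n_max must be a positive integer")
  structure(list(k_plus = k_plus, k_minus = k_minus, n_max = n_max,
                 K_inv = k_minus / k_plus),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Templated-assembly kinetic parameters\n")
  cat(sprintf("  k+    = %.4g M^-1 s^-1\n", x$k_plus))
  cat(sprintf("  k-    = %.4g s^-1\n", x$k_minus))
  cat(sprintf("  K^-1  = %.4g M (critical concentration)\n", x$K_inv))
  cat(sprintf("  n_max = %d\n", x$n_max))
  invisible(x)
}

#' Default truncation order for the binding ladder
#'
#' @param comp a [mixture_composition()].
#' @param factor multiple of the molar ratio c_S/c_G retained (default 3).
#' @param cap hard upper limit on the order (default 500).
#' @return integer truncation order.
#' @export
default_n_max <- function(comp, factor = 3, cap = 500L) {
  as.integer(min(cap, max(1, ceiling(factor * comp$c_S / comp$c_G))))
}

#' Subunit/genome mixture composition
#'
#' Total molar concentrations of capsid subunits and genome (or
#' polyelectrolyte) template.  The subunit-to-genome *mass* ratio `rho` is
#' the experimentalist's control variable; `m_ratio` converts it to a
#' molar ratio: c_S/c_G = rho * m_ratio.  For CCMV subunit dimers on the
#' 2980-nt genome, a molar ratio of 150 corresponds to rho = 6, i.e.
#' m_ratio = 25.
#'
#' Provide either both concentrations, or `c_S` together with `rho` (and
#' `m_ratio`), from which `c_G` is derived.
#'
#' @param c_S total subunit molar concentration (M, > 0).
#' @param c_G total genome molar concentration (M, >= 0; 0 is the
#'   degenerate pure-subunit solution used for baseline intensities).
#' @param rho subunit-to-genome mass ratio (optional).
#' @param m_ratio molar ratio per unit mass ratio (default 25).
#' @return An object of class `mixture_composition`.
#' @examples
#' mixture_composition(c_S = 24.6e-6, rho = 6)  # c_G = 0.164 uM
#' @export
mixture_composition <- function(c_S, c_G = NULL, rho = NULL, m_ratio = 25) {
  stopifnot(is.numeric(c_S), length(c_S) == 1L, c_S > 0, m_ratio > 0)
  if (is.null(c_G)) {
    if (is.null(rho)) stop("provide c_G or rho")
    stopifnot(rho > 0)
    c_G <- c_S / (rho * m_ratio)
  } else if (!is.null(rho) && c_G > 0) {
    if (abs(c_S / c_G - rho * m_ratio) > 1e-6 * (c_S / c_G))
      stop("inconsistent composition: c_S/c_G != rho * m_ratio")
  }
  stopifnot(is.numeric(c_G), length(c_G) == 1L, c_G >= 0)
  if (is.null(rho)) rho <- if (c_G > 0) (c_S / c_G) / m_ratio else NA_real_
  structure(list(c_S = c_S, c_G = c_G, rho = rho, m_ratio = m_ratio),
            class = "mixture_composition")
}

#' @export
print.mixture_composition <- function(x, ...) {
  cat(sprintf("Mixture: c_S = %.4g M, c_G = %.4g M (rho = %.3g, m_ratio = %g)\n",
              x$c_S, x$c_G, x$rho, x$m_ratio))
  invisible(x)
}

#' Distribution of subunit-genome complexes
#'
#' Molar concentrations `X[N]` of N-th order complexes for N = 0..n_max
#' (`X[1]` in R indexing is the bare genome, order 0) plus the free
#' subunit concentration `X_S`.  Validity requires non-negative entries
#' and the two conservation laws: sum(X) = c_G (genome) and
#' X_S + sum(N * X) = c_S (subunits).
#'
#' @param X numeric vector of complex concentrations, orders 0..n_max (M).
#' @param X_S free subunit concentration (M).
#' @param comp optional [mixture_composition()]; when supplied, the
#'   conservation laws are checked against it.
#' @param tol relative tolerance for the conservation checks.
#' @return An object of class `complex_distribution`.
#' @export
complex_distribution <- function(X, X_S, comp = NULL, tol = 1e-6) {
  stopifnot(is.numeric(X), length(X) >= 1L, is.numeric(X_S),
            length(X_S) == 1L)
  if (any(!is.finite(X)) || !is.finite(X_S))
    stop("non-finite concentrations")
  if (any(X < -tol * max(X, 1e-300)) || X_S < -tol * max(X_S, 1e-300))
    stop("negative concentrations in complex distribution")
  X <- pmax(X, 0)
  X_S <- max(X_S, 0)
  d <- structure(list(X = X, X_S = X_S, n_max = length(X) - 1L),
                 class = "complex_distribution")
  if (!is.null(comp)) assert_conserved(d, comp, tol = tol)
  d
}

#' Check conservation laws of a complex distribution
#'
#' @param dist a [complex_distribution()].
#' @param comp a [mixture_composition()].
#' @param tol relative tolerance.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
assert_conserved <- function(dist, comp, tol = 1e-6) {
  g <- sum(dist$X)
  s <- dist$X_S + bound_subunits(dist)
  if (abs(g - comp$c_G) > tol * max(comp$c_G, comp$c_S))
    stop(sprintf("genome conservation violated: sum(X) = %.6g, c_G = %.6g",
                 g, comp$c_G))
  if (abs(s - comp$c_S) > tol * comp$c_S)
    stop(sprintf("subunit conservation violated: X_S + sum(N X) = %.6g, c_S = %.6g",
                 s, comp$c_S))
  invisible(TRUE)
}

#' Concentration of bound subunits in a distribution
#' @param dist a [complex_distribution()].
#' @return sum over N of N * X[N] (molar).
#' @export
bound_subunits <- function(dist) {
  sum((seq_along(dist$X) - 1) * dist$X)
}

#' All-bare-genome initial distribution
#'
#' The canonical initial condition of a mixing experiment: all genome
#' bare, all subunits free.
#'
#' @param comp a [mixture_composition()].
#' @param n_max truncation order; defaults to [default_n_max()].
#' @return a [complex_distribution()].
#' @export
bare_genome_distribution <- function(comp, n_max = default_n_max(comp)) {
  X <- numeric(n_max + 1L)
  X[1L] <- comp$c_G
  complex_distribution(X, X_S = comp$c_S, comp = comp)
}

#' @export
print.complex_distribution <- function(x, ...) {
  m <- moments(x)
  cat(sprintf(
    "Complex distribution (n_max = %d): c_G = %.4g M, X_S = %.4g M, <N> = %.4g\n",
    x$n_max, sum(x$X), x$X_S, m[["mean"]]))
  invisible(x)
}

#' Mean and second moment of the occupancy distribution
#'
#' The mean number of subunits per complex, `<N> = sum(N X_N) / sum(X_N)`,
#' and the corresponding second moment `<N^2>`.
#'
#' @param dist a [complex_distribution()], or a bare numeric vector of
#'   concentrations for orders 0..n_max.
#' @return named numeric vector `c(mean = <N>, second = <N^2>)`.
#' @export
moments <- function(dist) {
  X <- if (inherits(dist, "complex_distribution")) dist$X else dist
  tot <- sum(X)
  if (tot <= 0) stop("moments undefined: total complex concentration is zero")
  N <- seq_along(X) - 1
  c(mean = sum(N * X) / tot, second = sum(N^2 * X) / tot)
}
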