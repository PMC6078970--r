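#' Stochastic simulation of templated assembly
#'
#' Exact (Gillespie) simulation of the binding ladder in a single
#' well-mixed volume.  The reaction volume is chosen so that the genome
#' concentration maps exactly onto `n_genome_copies` discrete genomes:
#' V = n_genome_copies / (N_A c_G).  The subunit copy number is the
#' rounded image of c_S in that volume; a copy number below 1 is
#' rejected.  Binding of a free subunit to a specific genome with
#' occupancy N < n_max has propensity k+ [S]; unbinding from a complex
#' with N >= 1 has propensity k- per complex.  The ensemble mean
#' occupancy is statistically exchangeable with [propagate_ode()].
#'
#' Identical seeds give bitwise-identical trajectories and event lists.
#'
#' @param params a [kinetic_parameters()].
#' @param comp a [mixture_composition()] with `c_G > 0`.
#' @param n_genome_copies number of genome copies simulated (>= 1).
#' @param seed integer RNG seed.
#' @param t_end end time, seconds.
#' @param record_times times (s) at which occupancies are recorded;
#'   default 101 points linearly spaced over `[0, t_end]`.
#' @param max_events number of reaction events to keep in the event log
#'   (0 disables logging; the simulation itself is unaffected).
#' @return An object of class `gillespie_trajectory`: list with `times`,
#'   `occupancy` (matrix, time x genome), `S` (free subunit copies),
#'   `mean_N`, `sem_N` (s.e.m. of the per-genome mean), `X_S` (molar),
#'   `events` (data.frame time/genome/delta), `volume_L`, and the call
#'   parameters.
#' @export
simulate_gillespie <- function(params, comp, n_genome_copies, seed, t_end,
                               record_times = NULL, max_events = 0L) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(comp, "mixture_composition"),
            n_genome_copies >= 1, t_end > 0)
  if (comp$c_G <= 0) stop("stochastic simulation requires c_G > 0")
  V_L <- n_genome_copies / (.N_AVOGADRO * comp$c_G)
  S0 <- round(comp$c_S * .N_AVOGADRO * V_L)
  if (S0 < 1)
    stop("copy number too small: c_S maps to ", S0,
         " subunits; increase n_genome_copies")
  if (is.null(record_times))
    record_times <- seq(0, t_end, length.out = 101L)
  stopifnot(all(diff(record_times) > 0), record_times[1L] >= 0,
            max(record_times) <= t_end)
  kb_mol <- params$k_plus / (.N_AVOGADRO * V_L)

  set.seed(as.integer(seed))
  res <- .gillespie_core(kb_mol, params$k_minus, params$n_max,
                         as.integer(n_genome_copies), as.integer(S0),
                         as.numeric(record_times), as.integer(max_events))
  occ <- res$occupancy
  mean_N <- rowMeans(occ)
  sem_N <- apply(occ, 1L, stats::sd) / sqrt(ncol(occ))
  structure(list(times = record_times, occupancy = occ, S = res$S,
                 mean_N = mean_N, sem_N = sem_N,
                 X_S = res$S / (.N_AVOGADRO * V_L),
                 events = data.frame(time = res$event_time,
                                     genome = res$event_genome,
                                     delta = res$event_delta),
                 volume_L = V_L, S0 = S0, params = params, comp = comp,
                 seed = seed),
            class = "gillespie_trajectory")
}

#' @export
print.gillespie_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "Gillespie trajectory: %d genomes, %d subunits, t_end = %g s, final <N> = %.4g +/- %.2g\n",
    ncol(x$occupancy), x$S0, max(x$times), x$mean_N[n], x$sem_N[n]))
  invisible(x)
}
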