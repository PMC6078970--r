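# Workflow orchestration: from a curve series to fitted quantities.

#' Occupancy-bound trace from a forward-intensity trace
#'
#' Applies [n_up_from_intensity()] frame by frame.
#'
#' @param I0_trace an [observable_trace()] of forward intensities.
#' @param comp a [mixture_composition()].
#' @param contrast a [contrast_set()].
#' @return an [observable_trace()] of the occupancy bound.
#' @export
n_up_trace <- function(I0_trace, comp, contrast) {
  vals <- t(vapply(seq_len(nrow(I0_trace)), function(i)
    suppressWarnings(
      n_up_from_intensity(I0_trace$value[i], comp, contrast,
                          sigma_I0 = I0_trace$sigma[i])),
    numeric(2)))
  observable_trace(I0_trace$t, vals[, 1L], vals[, 2L], label = "N_up")
}

#' Extract observable traces from a curve series
#'
#' Runs a Guinier fit on every frame and derives the I0, R_g and
#' occupancy-bound traces, plus the form-factor value at the probe
#' wavenumber.
#'
#' @param curves list of [scattering_curve()] frames.
#' @param times frame times (s).
#' @param comp a [mixture_composition()].
#' @param contrast a [contrast_set()].
#' @param q_probe probe wavenumber for the form-factor trace (default
#'   0.033); `NULL` skips it.
#' @param q_width q window averaged around the probe (see
#'   [form_factor_trace()]); default 0.
#' @param background optional background passed to [form_factor_trace()].
#' @param q_rg_max Guinier window criterion (default 1.3).
#' @return list of [observable_trace()]s: `I0`, `Rg`, `n_up`, `P_probe`.
#' @export
analyze_series <- function(curves, times, comp, contrast,
                           q_probe = 0.033, q_width = 0,
                           background = NULL, q_rg_max = 1.3) {
  stopifnot(length(curves) == length(times))
  gf <- lapply(curves, guinier_fit, q_rg_max = q_rg_max)
  I0 <- observable_trace(times, vapply(gf, `[[`, numeric(1), "I0"),
                         vapply(gf, `[[`, numeric(1), "sigma_I0"),
                         label = "I0")
  Rg <- observable_trace(times, vapply(gf, `[[`, numeric(1), "Rg"),
                         vapply(gf, `[[`, numeric(1), "sigma_Rg"),
                         label = "Rg")
  out <- list(I0 = I0, Rg = Rg,
              n_up = n_up_trace(I0, comp, contrast))
  if (!is.null(q_probe))
    out$P_probe <- form_factor_trace(curves, times, q_probe = q_probe,
                                     q_width = q_width,
                                     background = background,
                                     q_rg_max = q_rg_max)
  out
}

#' Classify the assembly pathway from its two relaxation times
#'
#' En masse assembly has binding much faster than structural relaxation
#' (`tau_struc / tau_bind >= threshold_ratio`); a synchronous pathway has
#' the two comparable (ratio `<= sync_ratio`); anything between is
#' indeterminate.
#'
#' @param tau_bind binding time (s, > 0).
#' @param tau_struc structural relaxation time (s, > 0).
#' @param threshold_ratio en-masse threshold (default 10).
#' @param sync_ratio synchronous threshold (default 3).
#' @return `"en_masse"`, `"synchronous"` or `"indeterminate"`.
#' @export
classify_pathway <- function(tau_bind, tau_struc, threshold_ratio = 10,
                             sync_ratio = 3) {
  stopifnot(tau_bind > 0, tau_struc > 0, sync_ratio <= threshold_ratio)
  ratio <- tau_struc / tau_bind
  if (ratio >= threshold_ratio) "en_masse"
  else if (ratio <= sync_ratio) "synchronous"
  else "indeterminate"
}

.workflow_options <- function(opts = list()) {
  defaults <- list(q_probe = 0.033, q_width = 0, q_rg_max = 1.3,
                   n_phases_bind = 1L, n_phases_struc = 2L,
                   through_origin = TRUE, tail_fraction = 0.25,
                   reference_conc = 1, R_C = 120e-10,
                   threshold_ratio = 10, sync_ratio = 3,
                   t_struc_min = 0, temperature = .T_ROOM)
  defaults[names(opts)] <- opts
  defaults
}

.load_series_input <- function(input) {
  if (!is.null(input$series)) {
    list(times = input$series$times, curves = input$series$curves)
  } else if (!is.null(input$manifest)) {
    read_frame_series(input$manifest)
  } else stop("input needs either a 'series' object or a 'manifest' path")
}

.fit_struc <- function(trace, opts) {
  keep <- trace$t >= opts$t_struc_min
  fit_exponential(trace[keep, , drop = FALSE],
                  n_phases = opts$n_phases_struc, direction = "decay")
}

#' Run a scripted analysis workflow
#'
#' Orchestrates the canonical analyses from a curve series (or several)
#' to fitted quantities.  Supported workflows:
#'
#' * `assembly`: mixing experiment.  Occupancy-bound rise through the
#'   origin gives the binding time; the structural trace (form factor at
#'   the probe q) gives the structural relaxation time; the pathway is
#'   classified from their ratio.
#' * `dilution`: single-exponential decay of the occupancy bound gives
#'   the unbinding time.
#' * `relaxation`: pre-assembled complexes driven towards the ordered
#'   state.  Multi-phase occupancy rise (longest time constant reported
#'   as the binding time, the usual convention) plus structural trace and
#'   pathway classification.
#' * `titration`: several series at different mass ratios; tail means of
#'   the occupancy bound are regressed through the origin against rho to
#'   give the critical concentration and binding free energy.
#' * `arrhenius`: relaxation times across temperatures (either given
#'   directly as `pairs`, or fitted per-temperature from traces) give the
#'   activation energy.
#'
#' @param config a list (or path to a JSON file) with elements
#'   `workflow`, `composition` (arguments of [mixture_composition()]),
#'   `contrast` (arguments of [contrast_set()]), `input` (a `series`
#'   object or `manifest` path; for titration a list of inputs each with
#'   a `rho`; for arrhenius either `pairs` with `temperature`/`tau` or a
#'   list of inputs each with a `temperature`), and optional `options`
#'   (q_probe, n_phases_*, through_origin, tail_fraction,
#'   reference_conc, R_C, threshold_ratio, sync_ratio, t_struc_min).
#' @return A structured report (class `workflow_report`): extracted
#'   traces, fit objects, derived quantities, and classification where
#'   applicable.  Deterministic given inputs.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  workflow <- match.arg(config$workflow,
                        c("assembly", "dilution", "relaxation",
                          "titration", "arrhenius"))
  opts <- .workflow_options(config$options)
  comp <- if (!is.null(config$composition))
    do.call(mixture_composition, config$composition) else NULL
  contrast <- if (!is.null(config$contrast))
    do.call(contrast_set, config$contrast) else NULL
  report <- list(workflow = workflow, options = opts)

  if (workflow %in% c("assembly", "dilution", "relaxation")) {
    stopifnot(!is.null(comp), !is.null(contrast))
    ser <- .load_series_input(config$input)
    traces <- analyze_series(ser$curves, ser$times, comp, contrast,
                             q_probe = opts$q_probe,
                             q_width = opts$q_width,
                             q_rg_max = opts$q_rg_max)
    report$traces <- traces
    if (workflow == "assembly") {
      fb <- fit_exponential(traces$n_up, n_phases = opts$n_phases_bind,
                            direction = "rise",
                            through_origin = opts$through_origin)
      fs <- .fit_struc(traces$P_probe, opts)
      report$fits <- list(binding = fb, structural = fs)
      report$derived <- list(tau_bind = fb$tau_slow,
                             tau_struc = fs$tau_slow)
      report$classification <- classify_pathway(
        fb$tau_slow, fs$tau_slow, opts$threshold_ratio, opts$sync_ratio)
    } else if (workflow == "dilution") {
      fu <- fit_exponential(traces$n_up, n_phases = opts$n_phases_bind,
                            direction = "decay", through_origin = FALSE)
      report$fits <- list(unbinding = fu)
      report$derived <- list(tau_unbind = fu$tau_slow)
    } else {
      fb <- fit_exponential(traces$n_up, n_phases = opts$n_phases_bind,
                            direction = "rise", through_origin = FALSE)
      fs <- .fit_struc(traces$P_probe, opts)
      report$fits <- list(binding = fb, structural = fs)
      report$derived <- list(tau_bind = fb$tau_slow,
                             tau_struc = fs$tau_slow)
      report$classification <- classify_pathway(
        fb$tau_slow, fs$tau_slow, opts$threshold_ratio, opts$sync_ratio)
    }
  } else if (workflow == "titration") {
    stopifnot(!is.null(comp), !is.null(contrast))
    rho <- N_inf <- sig <- numeric(length(config$input))
    for (i in seq_along(config$input)) {
      inp <- config$input[[i]]
      stopifnot(!is.null(inp$rho))
      comp_i <- mixture_composition(c_S = comp$c_S, rho = inp$rho,
                                    m_ratio = comp$m_ratio)
      ser <- .load_series_input(inp)
      tr <- analyze_series(ser$curves, ser$times, comp_i, contrast,
                           q_probe = NULL, q_rg_max = opts$q_rg_max)$n_up
      tail_n <- max(3L, ceiling(opts$tail_fraction * nrow(tr)))
      idx <- seq.int(nrow(tr) - tail_n + 1L, nrow(tr))
      w <- 1 / pmax(tr$sigma[idx], 1e-12)^2
      rho[i] <- inp$rho
      N_inf[i] <- sum(w * tr$value[idx]) / sum(w)
      sig[i] <- sqrt(1 / sum(w))
    }
    fit <- fit_critical_concentration(rho, N_inf, sig, c_S = comp$c_S,
                                      m_ratio = comp$m_ratio)
    G <- binding_free_energy(fit$K_inv, temperature = opts$temperature,
                             reference_conc = opts$reference_conc,
                             se_K_inv = fit$se_K_inv)
    report$fits <- list(critical_concentration = fit)
    report$derived <- list(K_inv = fit$K_inv, se_K_inv = fit$se_K_inv,
                           G_bind_kT0 = G$G_kT0,
                           G_bind_kJ_per_mol = G$G_kJ_per_mol,
                           reference_conc = G$reference_conc,
                           pairs = data.frame(rho = rho, N_inf = N_inf,
                                              sigma = sig))
  } else { # arrhenius
    if (!is.null(config$input$pairs)) {
      pr <- config$input$pairs
      temperature <- pr$temperature
      tau <- pr$tau
      sigma_tau <- pr$sigma_tau
    } else {
      temperature <- tau <- sigma_tau <- numeric(length(config$input))
      for (i in seq_along(config$input)) {
        inp <- config$input[[i]]
        stopifnot(!is.null(inp$temperature))
        ser <- .load_series_input(inp)
        comp_i <- if (!is.null(inp$rho))
          mixture_composition(c_S = comp$c_S, rho = inp$rho,
                              m_ratio = comp$m_ratio) else comp
        tr <- analyze_series(ser$curves, ser$times, comp_i, contrast,
                             q_probe = NULL)$n_up
        fb <- fit_exponential(tr, n_phases = opts$n_phases_bind,
                              direction = "rise", through_origin = FALSE)
        temperature[i] <- inp$temperature
        tau[i] <- fb$tau_slow
        sigma_tau[i] <- fb$se_tau[which.max(fb$tau)]
      }
    }
    # accept Celsius for convenience: anything below 200 is treated as C
    temperature <- ifelse(temperature < 200, temperature + 273.15,
                          temperature)
    fit <- fit_arrhenius(temperature, tau, sigma_tau)
    report$fits <- list(arrhenius = fit)
    report$derived <- list(E_a_kT0 = fit$E_a_kT0,
                           se_E_a_kT0 = fit$se_E_a_kT0,
                           E_a_kJ_per_mol = fit$E_a_J_per_mol / 1000)
  }
  structure(report, class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("Workflow report: %s\n", x$workflow))
  if (!is.null(x$derived)) {
    sc <- x$derived[vapply(x$derived, function(v)
      is.numeric(v) && length(v) == 1L, logical(1))]
    for (nm in names(sc)) cat(sprintf("  %s = %.6g\n", nm, sc[[nm]]))
  }
  if (!is.null(x$classification))
    cat(sprintf("  pathway: %s\n", x$classification))
  invisible(x)
}

#' Serialise a workflow report to JSON
#'
#' Fit objects are reduced to their scalar parameters; traces are kept
#' as data frames.  The output is hash-stable for identical inputs.
#'
#' @param report a `workflow_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, "exponential_fit"))
      list(n_phases = x$n_phases, direction = x$direction,
           tau = x$tau, se_tau = x$se_tau, amplitudes = x$amplitudes,
           offset = x$offset, tau_slow = x$tau_slow, sse = x$sse)
    else if (inherits(x, "critical_concentration_fit"))
      list(slope = x$slope, se_slope = x$se_slope, K_inv = x$K_inv,
           se_K_inv = x$se_K_inv)
    else if (inherits(x, "arrhenius_fit"))
      list(E_a_kT0 = x$E_a_kT0, se_E_a_kT0 = x$se_E_a_kT0,
           prefactor = x$prefactor)
    else if (inherits(x, "kinetic_fit"))
      list(k_plus = x$k_plus, se_k_plus = x$se_k_plus,
           k_minus = x$k_minus, D_S = x$D_S, tau_bind = x$tau_bind)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, simplify)
    else x
  }
  jsonlite::write_json(simplify(unclass(report)), path, digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}
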