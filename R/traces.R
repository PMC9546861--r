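#' Real-time biosensor trace
#'
#' A single time-resolved fluorescence record with per-point phase labels.
#' Phases are contiguous and ordered `baseline` -> `association` ->
#' `dissociation` (any prefix/suffix may be absent). Phase intervals are
#' half-open on the time axis: each phase's local clock starts at 0 at its
#' first point.
#'
#' @param time Numeric vector of times (s), strictly increasing, non-negative.
#' @param signal Numeric vector of fluorescence (arbitrary units), same length.
#' @param phase Character vector over {"baseline", "association",
#'   "dissociation"}.
#' @param analyte_conc Analyte concentration (molar); 0 for a blank run.
#' @param spot_role One of "measurement", "reference", "blank_measurement",
#'   "blank_reference".
#' @param trace_id Character identifier.
#' @return Object of class `sensor_trace` (a data frame with columns `time`,
#'   `signal`, `phase`, and attributes `analyte_conc`, `spot_role`,
#'   `trace_id`).
#' @export
sensor_trace <- function(time, signal, phase,
                         analyte_conc = 0,
                         spot_role = c("measurement", "reference",
                                       "blank_measurement", "blank_reference"),
                         trace_id = "trace") {
  spot_role <- match.arg(spot_role)
  if (length(time) != length(signal) || length(time) != length(phase)) {
    stop_multikin("time, signal and phase must have equal length")
  }
  assert_non_negative(time, "time")
  if (any(diff(time) <= 0)) stop_multikin("time must be strictly increasing")
  assert_non_negative(analyte_conc, "analyte_conc")
  ok_phases <- c("baseline", "association", "dissociation")
  if (any(!phase %in% ok_phases)) {
    stop_multikin("phase labels must be in {", paste(ok_phases, collapse = ", "), "}")
  }
  r <- rle(phase)$values
  if (any(duplicated(r)) || any(diff(match(r, ok_phases)) <= 0)) {
    stop_multikin("phases must be contiguous and ordered baseline -> association -> dissociation")
  }
  structure(data.frame(time = time, signal = signal, phase = phase,
                       stringsAsFactors = FALSE),
            analyte_conc = analyte_conc, spot_role = spot_role,
            trace_id = trace_id,
            class = c("sensor_trace", "data.frame"))
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %s [%s], C = %.3g M, %d points (%s)\n",
              attr(x, "trace_id"), attr(x, "spot_role"),
              attr(x, "analyte_conc"), nrow(x),
              paste(unique(x$phase), collapse = "/")))
  invisible(x)
}

trace_phase <- function(trace, phase) {
  trace[trace$phase == phase, , drop = FALSE]
}

# Local (phase-relative) time of each point in a phase slice.
phase_time <- function(tp) tp$time - tp$time[1L]

#' Simulate a set of FPS traces for one analyte concentration
#'
#' Forward model of a 1:1 interaction read out by fluorescence proximity
#' sensing. The measurement spot carries the binding signal: during
#' association \eqn{S(t) = A\,C/(C + K_D)\,(1 - e^{-(k_{on} C + k_{off}) t})}
#' (equilibrium-occupancy amplitude scaling); during dissociation the signal
#' decays from its association end level as \eqn{S(t) = S_{end} e^{-k_{off} t}}.
#' The real-time reference spot and the two blank (buffer) channels carry only
#' baseline drift and noise, so that double referencing
#' ([double_reference()]) recovers the pure binding component.
#'
#' An optional phenomenological concentration dependence of the apparent
#' on-rate, \eqn{k_{on,app} = k_{on} (C/C_{ref})^{\beta}}, is available for
#' robustness studies; the default \eqn{\beta = 0} is the clean 1:1 model.
#'
#' @param gt A [ground_truth_kinetics] object.
#' @param conc Analyte concentration (molar), >= 0.
#' @param t_assoc,t_dissoc Association / dissociation durations (s).
#' @param t_baseline Baseline duration (s) before the concentration jump.
#' @param dt Sampling interval (s).
#' @param amplitude Saturation amplitude A (a.u.) at full occupancy.
#' @param noise_sd Additive i.i.d. Gaussian noise SD per point (a.u.).
#' @param drift Linear baseline drift (a.u./s), common to all four channels.
#' @param beta Exponent of the apparent-on-rate concentration dependence.
#' @param c_ref Reference concentration (molar) for `beta`.
#' @param seed Integer seed; identical seeds give bitwise-identical traces.
#' @param trace_id Identifier prefix for the four channels.
#' @return Named list of four [sensor_trace]s: `measurement`, `reference`,
#'   `blank_measurement`, `blank_reference`.
#' @examples
#' gt <- ground_truth_kinetics(k_on = 1e5, k_off = 1e-3)
#' tr <- simulate_fps_trace(gt, conc = 1e-6, noise_sd = 0)
#' # observed association rate k_obs = k_on * C + k_off = 0.101 /s
#' @export
simulate_fps_trace <- function(gt, conc, t_assoc = 300, t_dissoc = 600,
                               t_baseline = 30, dt = 1,
                               amplitude = 100, noise_sd = 0, drift = 0,
                               beta = 0, c_ref = 1e-6,
                               seed = NULL, trace_id = "fps") {
  stopifnot(inherits(gt, "ground_truth_kinetics"))
  assert_non_negative(conc, "conc")
  assert_non_negative(noise_sd, "noise_sd")
  assert_positive(c(t_assoc, t_dissoc, dt), "durations and dt")
  assert_non_negative(t_baseline, "t_baseline")

  t_b <- if (t_baseline > 0) seq(0, t_baseline - dt, by = dt) else numeric(0)
  t_a <- seq(t_baseline, t_baseline + t_assoc - dt, by = dt)
  t_d <- seq(t_baseline + t_assoc, t_baseline + t_assoc + t_dissoc, by = dt)
  time <- c(t_b, t_a, t_d)
  phase <- c(rep("baseline", length(t_b)), rep("association", length(t_a)),
             rep("dissociation", length(t_d)))

  binding <- numeric(length(time))
  if (conc > 0) {
    k_on_app <- gt$k_on * (conc / c_ref)^beta
    k_obs <- k_on_app * conc + gt$k_off
    s_eq <- amplitude * conc / (conc + gt$K_D)
    ta <- t_a - t_a[1L]
    s_assoc <- s_eq * (1 - exp(-k_obs * ta))
    s_end <- s_eq * (1 - exp(-k_obs * t_assoc))
    td <- t_d - t_d[1L]
    s_dissoc <- s_end * exp(-gt$k_off * td)
    binding <- c(rep(0, length(t_b)), s_assoc, s_dissoc)
  }

  channels <- c("measurement", "reference", "blank_measurement", "blank_reference")
  out <- lapply(seq_along(channels), function(i) {
    role <- channels[[i]]
    noise <- if (noise_sd > 0) {
      with_seed(child_seed(seed, i), stats::rnorm(length(time), sd = noise_sd))
    } else 0
    base <- drift * time + noise
    sig <- if (role == "measurement") binding + base else base
    sensor_trace(time = time, signal = sig, phase = phase,
                 analyte_conc = if (grepl("^blank", role)) 0 else conc,
                 spot_role = role,
                 trace_id = paste(trace_id, role, sep = "_"))
  })
  stats::setNames(out, channels)
}
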