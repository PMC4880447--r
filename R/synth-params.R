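# Parameter objects of the synthetic worm generator: kinematics of the
# crawling wave, the O2 stimulus protocol, and the stimulus-behavior
# coupling model.

#' Kinematic parameters of the synthetic crawling worm
#'
#' Defaults describe an adult hermaphrodite crawling on agar recorded at
#' 10 frames/s: a traveling dorsoventral bending wave of about 0.45
#' cycles/s and roughly 1.5 wavelengths along the body, sparse shallow-turn
#' transients, and occasional reversals, pauses and omega turns.
#'
#' @param frame_rate frames per second (> 0)
#' @param undulation_amp peak bend per inter-segment angle (rad)
#' @param undulation_freq undulation frequency (cycles/s)
#' @param phase_per_segment spatial phase advance of the wave per segment
#'   (rad); the default puts ~1.5 wavelengths on the body
#' @param turn_event_rate shallow-turn transient rate (events/min)
#' @param turn_amp_scale peak angle of a shallow-turn transient (rad)
#' @param turn_onset_lag temporal lag of turn onsets behind the undulation
#'   phase zero-crossing they lock to (s)
#' @param turn_width duration of a raised-cosine turn transient (s)
#' @param reversal_rate reversal rate (events/min)
#' @param reversal_dur mean reversal duration (s)
#' @param pause_rate pause rate (events/min)
#' @param pause_dur mean pause duration (s)
#' @param omega_rate omega-turn rate (events/min)
#' @param omega_dur omega-turn duration (s)
#' @param angle_noise_sd per-angle Gaussian noise (rad)
#' @param speed_gain centroid speed per unit (amplitude x frequency)
#'   (mm/s per rad/s-ish); default yields ~0.2 mm/s at the default wave
#' @param curvature_gain heading change per unit net body bend per mm
#'   travelled (rad/mm per rad)
#' @param heading_noise_sd heading diffusion of the centroid path
#'   (rad per sqrt(s)); real centroid tracks always wander
#' @param wobble_mm amplitude of the gait-locked lateral centroid
#'   oscillation (mm); the centroid of a crawling worm sways with the
#'   undulation cycle
#' @param seed integer seed; a fixed seed makes every generator output
#'   bit-reproducible
#' @return an object of class `kinematic_params`
#' @export
kinematic_params <- function(frame_rate = 10,
                             undulation_amp = 0.4,
                             undulation_freq = 0.45,
                             phase_per_segment = 2 * pi * 1.5 / 24,
                             turn_event_rate = 6,
                             turn_amp_scale = 0.35,
                             turn_onset_lag = 0.6,
                             turn_width = 1.0,
                             reversal_rate = 1,
                             reversal_dur = 2,
                             pause_rate = 0.5,
                             pause_dur = 4,
                             omega_rate = 0.5,
                             omega_dur = 1.5,
                             angle_noise_sd = 0.05,
                             speed_gain = 1.2,
                             curvature_gain = 1.1,
                             heading_noise_sd = 0.04,
                             wobble_mm = 0.008,
                             seed = 1L) {
  check_pos(frame_rate, "frame_rate")
  for (f in c("undulation_amp", "undulation_freq", "phase_per_segment",
              "turn_event_rate", "turn_amp_scale", "turn_onset_lag",
              "turn_width", "reversal_rate", "reversal_dur", "pause_rate",
              "pause_dur", "omega_rate", "omega_dur", "angle_noise_sd",
              "speed_gain", "curvature_gain", "heading_noise_sd",
              "wobble_mm"))
    check_nonneg(get(f), f)
  if (length(seed) != 1L || !is.finite(seed))
    stop("parameter 'seed' must be a single finite integer", call. = FALSE)
  structure(as.list(environment()), class = "kinematic_params")
}

#' O2 stimulus protocol as a piecewise-linear concentration time course
#'
#' @param times breakpoint times (s), strictly increasing
#' @param o2 O2 concentration (%) at each breakpoint, in \[0, 21\]
#' @param kind one of `"constant"`, `"shift"`, `"ramp"` (descriptive tag)
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(times, o2, kind = c("constant", "shift", "ramp")) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(o2), length(times) >= 1)
  if (any(diff(times) <= 0))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  if (any(o2 < 0 | o2 > 21))
    stop("O2 values must lie in [0, 21] %", call. = FALSE)
  structure(list(times = as.numeric(times), o2 = as.numeric(o2), kind = kind),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param level,duration constant-protocol level (%) and length (s)
#' @export
protocol_constant <- function(level = 21, duration = 600)
  stimulus_protocol(c(0, duration), c(level, level), "constant")

#' @rdname stimulus_protocol
#' @param from,to O2 levels (%) before/after
#' @param at shift time (s)
#' @export
protocol_shift <- function(from = 21, to = 10, at = 0, duration = 600) {
  if (at <= 0)
    stimulus_protocol(c(at, at + 1e-3, at + duration), c(from, to, to), "shift")
  else
    stimulus_protocol(c(0, at, at + 1e-3, at + duration),
                      c(from, from, to, to), "shift")
}

#' @rdname stimulus_protocol
#' @param ramp_duration length of the linear ramp (s); the default
#'   21->4 % over 180 s corresponds to 0.094 %/s
#' @param start ramp onset time (s)
#' @export
protocol_ramp <- function(from = 21, to = 4, start = 0, ramp_duration = 180,
                          duration = 600) {
  tb <- c(0, start, start + ramp_duration, duration)
  ob <- c(from, from, to, to)
  keep <- !duplicated(tb)
  stimulus_protocol(tb[keep], ob[keep], "ramp")
}

#' O2 concentration of a protocol at given times
#' @param protocol a [stimulus_protocol()]
#' @param t times (s); clamped to the protocol span
#' @return O2 (%) at each time
#' @export
o2_at_time <- function(protocol, t)
  stats::approx(protocol$times, protocol$o2, xout = t, rule = 2)$y

#' Absolute O2 change rate of a ramp protocol (%/s)
#' @param protocol a [stimulus_protocol()]
#' @return the maximum absolute slope between breakpoints
#' @export
ramp_rate <- function(protocol) {
  sl <- abs(diff(protocol$o2) / diff(protocol$times))
  max(sl)
}

#' Stimulus-behavior coupling model
#'
#' An O2 downshift drives a transient behavioral-state change: turning
#' (event rate and amplitude) is scaled up by `turn_gain`, the undulation
#' wave (amplitude and frequency) is scaled down by `und_gain`, and both
#' relax back to baseline with time constant `recovery_tau`. Each
#' controlled parameter responds monophasically.
#'
#' @param turn_gain dimensionless up-regulation gain (>= 0)
#' @param und_gain dimensionless down-regulation gain (>= 0)
#' @param recovery_tau return-to-baseline time constant (s)
#' @return an object of class `coupling_model`
#' @export
coupling_model <- function(turn_gain = 1.5, und_gain = 0.35,
                           recovery_tau = 90) {
  check_nonneg(turn_gain, "turn_gain")
  check_nonneg(und_gain, "und_gain")
  check_pos(recovery_tau, "recovery_tau")
  structure(list(turn_gain = turn_gain, und_gain = und_gain,
                 recovery_tau = recovery_tau), class = "coupling_model")
}

# Normalized downshift drive in [0, ~1]: leaky integration of negative O2
# steps, scaled by the full 21->4 % range, decaying with recovery_tau.
coupling_drive <- function(o2, frame_rate, recovery_tau) {
  drops <- pmax(0, -diff(c(o2[1], o2))) / 17
  decay <- exp(-1 / (frame_rate * recovery_tau))
  as.numeric(stats::filter(drops, decay, method = "recursive"))
}
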