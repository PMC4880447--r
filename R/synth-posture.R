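# Synthetic posture/track generator: a traveling undulation wave plus
# phase-locked turning transients, interleaved reversals, pauses and omega
# turns, with per-frame ground-truth labels.

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# The two undulation shape vectors (quadrature pair of the traveling wave)
# for a given spatial phase advance; columns orthonormalized.
undulation_shapes <- function(phase_per_segment) {
  k <- seq_len(24)
  u <- cbind(sin(k * phase_per_segment), cos(k * phase_per_segment))
  qr.Q(qr(u))
}

# A smooth spatial bump over segments, orthogonalized against the
# undulation subspace and scaled to unit peak. Used for shallow turns.
turn_shape <- function(center, width, phase_per_segment) {
  k <- seq_len(24)
  v <- ifelse(abs(k - center) < width / 2,
              0.5 * (1 + cos(2 * pi * (k - center) / width)), 0)
  u <- undulation_shapes(phase_per_segment)
  v <- v - u %*% crossprod(u, v)
  as.numeric(v / max(abs(v)))
}

# Raised-cosine temporal envelope of an event, unit peak.
raised_cosine_env <- function(t, onset, width) {
  z <- (t - onset) / width
  ifelse(z > 0 & z < 1, 0.5 * (1 - cos(2 * pi * z)), 0)
}

# Tapered-plateau (Tukey) envelope: cosine rise and fall (30 % each) with
# a full-amplitude hold in between; omega coils are held, not pulsed.
plateau_env <- function(t, onset, width, taper = 0.3) {
  z <- (t - onset) / width
  out <- numeric(length(t))
  rise <- z > 0 & z < taper
  hold <- z >= taper & z <= 1 - taper
  fall <- z > 1 - taper & z < 1
  out[rise] <- 0.5 * (1 - cos(pi * z[rise] / taper))
  out[hold] <- 1
  out[fall] <- 0.5 * (1 - cos(pi * (1 - z[fall]) / taper))
  out
}

# Draw non-overlapping exclusive state events (reverse/pause/omega) from
# per-frame Bernoulli approximations of Poisson processes with the given
# time-varying per-minute rates.
schedule_states <- function(n, frame_rate, rates, durations) {
  types <- names(rates)
  events <- list()
  busy_until <- 0L
  i <- 1L
  dt <- 1 / frame_rate
  u <- matrix(stats::runif(n * length(types)), n, length(types))
  jit <- stats::runif(n, 0.85, 1.15)
  while (i <= n) {
    if (i > busy_until) {
      p <- vapply(types, function(ty) rates[[ty]][i] / 60 * dt, numeric(1))
      hit <- which(u[i, ] < p)
      if (length(hit)) {
        ty <- types[hit[1]]
        dur <- durations[[ty]] * jit[i]
        len <- max(1L, as.integer(round(dur * frame_rate)))
        events[[length(events) + 1L]] <-
          data.frame(type = ty, onset_s = (i - 1) / frame_rate,
                     duration_s = len / frame_rate)
        busy_until <- min(n, i + len - 1L)
      }
    }
    i <- i + 1L
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(type = character(), onset_s = numeric(),
                  duration_s = numeric())
}

#' Generate a synthetic worm recording with ground truth
#'
#' Builds a posture series in which angle k at time t is
#' `A(t) sin(psi(t) - k phi) + turning transients + noise`: a traveling
#' undulation wave whose phase advances forward, reverses during reversal
#' events and freezes during pauses, plus smooth raised-cosine turning
#' transients in directions orthogonal to the two leading undulation
#' shapes. Turn onsets lock to undulation phase zero-crossings delayed by
#' `turn_onset_lag`. An O2 downshift (via `stimulus` and `coupling`)
#' up-regulates turning rate/amplitude and down-regulates undulation
#' amplitude/frequency, each relaxing back with `recovery_tau`. A matching
#' centroid track is integrated from the wave (speed) and the turning field
#' (heading change), and every frame carries its ground-truth state label.
#'
#' @param params a [kinematic_params()]
#' @param stimulus a [stimulus_protocol()]; default constant 21 % O2
#' @param coupling a [coupling_model()]
#' @param duration recording length (s), at least 10
#' @return an object of class `synthetic_recording`: list with elements
#'   `posture` ([posture_series()]), `track` ([worm_track()]), `labels`
#'   (per-frame [state_labels()]), and `truth` (generator internals: event
#'   table, undulation phase, phase zero-crossing times, per-frame
#'   amplitude/frequency, stimulus drive, parameters)
#' @export
generate_posture_series <- function(params = kinematic_params(),
                                    stimulus = NULL,
                                    coupling = coupling_model(),
                                    duration = 60) {
  stopifnot(inherits(params, "kinematic_params"))
  if (duration < 10) stop("duration must be at least 10 s", call. = FALSE)
  if (is.null(stimulus)) stimulus <- protocol_constant(21, duration)
  fr <- params$frame_rate
  n <- as.integer(round(duration * fr))
  t <- (seq_len(n) - 1L) / fr
  dt <- 1 / fr

  o2 <- o2_at_time(stimulus, t)
  drive <- coupling_drive(o2, fr, coupling$recovery_tau)
  A <- params$undulation_amp * pmax(0.1, 1 - coupling$und_gain * drive)
  f <- params$undulation_freq * pmax(0.1, 1 - coupling$und_gain * drive)
  turn_rate <- params$turn_event_rate * (1 + coupling$turn_gain * drive)
  turn_amp <- params$turn_amp_scale * (1 + coupling$turn_gain * drive)

  with_seed(params$seed, {
    ## exclusive state events
    ev <- schedule_states(
      n, fr,
      rates = list(reverse = rep(params$reversal_rate, n),
                   pause = rep(params$pause_rate, n),
                   omega = rep(params$omega_rate, n)),
      durations = list(reverse = params$reversal_dur,
                       pause = params$pause_dur,
                       omega = params$omega_dur))
    labels <- rep("forward", n)
    for (j in seq_len(nrow(ev))) {
      i0 <- as.integer(round(ev$onset_s[j] * fr)) + 1L
      i1 <- min(n, i0 + as.integer(round(ev$duration_s[j] * fr)) - 1L)
      labels[i0:i1] <- ev$type[j]
    }

    ## wave phase: forward +, reversal -, pause 0
    dirphase <- ifelse(labels == "reverse", -1, ifelse(labels == "pause", 0, 1))
    psi <- cumsum(2 * pi * f * dirphase * dt)
    k <- seq_len(24)
    wave <- A * sin(outer(psi, k * params$phase_per_segment, `-`))

    ## phase zero-crossings (rising through multiples of 2 pi, forward only)
    wraps <- diff(floor(psi / (2 * pi)))
    crossings <- which(wraps > 0)            # frame indices
    crossings_s <- t[pmin(n, crossings + 1L)]

    ## shallow-turn transients locked to crossings + lag
    turn_field <- matrix(0, n, 24)
    turn_steer <- numeric(n)     # signed reorientation drive per frame
    turn_events <- list()
    cand <- which(stats::runif(n) < turn_rate / 60 * dt & labels == "forward")
    amp_jit <- stats::runif(n, 0.8, 1.2)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    ctr <- stats::runif(n, 9, 16)
    for (i in cand) {
      nxt <- crossings_s[crossings_s >= t[i]]
      if (!length(nxt)) next
      onset <- nxt[1] + params$turn_onset_lag
      if (onset + params$turn_width > t[n]) next
      ampl <- turn_amp[i] * amp_jit[i] * sgn[i]
      shape <- turn_shape(ctr[i], 12, params$phase_per_segment)
      env <- raised_cosine_env(t, onset, params$turn_width)
      turn_field <- turn_field + (ampl * env) %o% shape
      turn_steer <- turn_steer + 8 * ampl * env
      turn_events[[length(turn_events) + 1L]] <-
        data.frame(type = "turn", onset_s = onset,
                   duration_s = params$turn_width, amplitude = ampl,
                   locked_crossing_s = nxt[1])
    }
    turn_events <- if (length(turn_events)) do.call(rbind, turn_events)
    else data.frame(type = character(), onset_s = numeric(),
                    duration_s = numeric(), amplitude = numeric(),
                    locked_crossing_s = numeric())

    ## omega turns: one deep bend of just under a full turn; the
    ## undulation wave is suspended while the coil forms
    omega_field <- matrix(0, n, 24)
    omega_env <- numeric(n)
    oev <- ev[ev$type == "omega", , drop = FALSE]
    seg_prof <- raised_cosine_env(seq_len(24), 2, 22)
    seg_prof <- seg_prof / sum(seg_prof)
    osgn <- sample(c(-1, 1), max(1L, nrow(oev)), replace = TRUE)
    ototal <- stats::runif(max(1L, nrow(oev)), 5.4, 5.7)
    for (j in seq_len(nrow(oev))) {
      env <- plateau_env(t, oev$onset_s[j], oev$duration_s[j])
      omega_field <- omega_field +
        (osgn[j] * ototal[j] * env) %o% seg_prof
      omega_env <- pmax(omega_env, env)
    }

    noise <- matrix(stats::rnorm(n * 24, sd = params$angle_noise_sd), n, 24)
    angles <- (wave + turn_field) * (1 - omega_env) + omega_field + noise

    ## centroid track
    v <- params$speed_gain * A * f
    v[labels == "pause"] <- 0.004
    v[labels == "omega"] <- 0.05
    net_bend <- turn_steer
    heading <- cumsum(params$curvature_gain * net_bend * v * dt +
                        params$heading_noise_sd * sqrt(dt) *
                          stats::rnorm(n)) +
      stats::runif(1, 0, 2 * pi)
    step_dir <- ifelse(labels == "reverse", -1, 1)
    xy <- cbind(cumsum(step_dir * v * cos(heading) * dt),
                cumsum(step_dir * v * sin(heading) * dt))
    ## gait-locked lateral sway of the centroid
    xy <- xy + params$wobble_mm * sin(psi) *
      cbind(-sin(heading), cos(heading))

    posture <- posture_series(angles, fr)
    track <- worm_track(xy, fr, posture = posture)
    structure(list(
      posture = posture,
      track = track,
      labels = state_labels(labels),
      truth = list(params = params, stimulus = stimulus, coupling = coupling,
                   events = {
                     ev$amplitude <- rep(NA_real_, nrow(ev))
                     ev$locked_crossing_s <- rep(NA_real_, nrow(ev))
                     rbind(ev, turn_events)
                   },
                   psi = psi, crossings_s = crossings_s,
                   undulation_amp = A, undulation_freq = f,
                   turning_envelope = rowSums(abs(turn_field)),
                   speed = v, drive = drive, o2 = o2)
    ), class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %.0f s @ %g fps; states: %s\n",
    n_frames(x$posture) / x$posture$frame_rate, x$posture$frame_rate,
    paste(sprintf("%s %.0f%%", levels(x$labels),
                  100 * prop.table(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Generate an ensemble of synthetic recordings
#'
#' @param n_recordings number of recordings
#' @param params a [kinematic_params()] template; each recording gets seed
#'   `params$seed + i - 1`
#' @param ... passed to [generate_posture_series()]
#' @return list of `synthetic_recording`
#' @export
generate_ensemble <- function(n_recordings, params = kinematic_params(), ...) {
  lapply(seq_len(n_recordings), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    generate_posture_series(p, ...)
  })
}
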