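# Synthetic worm populations navigating a linear O2 gradient arena:
# run-and-turn agents with three independently switchable strategies
# (weathervaning, biased random walk, area-restricted-search modulation),
# each coupled to the bearing toward the preferred isoline.

#' Navigation strategy gains of the population generator
#'
#' Each gain couples one behavior to the bearing B toward the optimum
#' isoline and can be enabled alone: `weathervane` biases continuous
#' heading change toward the optimum (curving bias); `reversal_bias`
#' scales the reversal rate up when heading away (biased random walk);
#' `speed_ars` scales forward speed with cos(B) (negative = slower when
#' heading toward the optimum); `turn_ars` scales shallow-turn amplitude
#' linearly with B (positive = larger turns when heading away).
#'
#' @param weathervane heading relaxation rate toward the optimum (rad/s)
#' @param reversal_bias dimensionless reversal-rate modulation depth
#' @param speed_ars dimensionless speed modulation (can be negative)
#' @param turn_ars dimensionless turn-amplitude modulation depth
#' @return an object of class `navigation_gains`
#' @export
navigation_gains <- function(weathervane = 0, reversal_bias = 0,
                             speed_ars = 0, turn_ars = 0) {
  structure(list(weathervane = weathervane, reversal_bias = reversal_bias,
                 speed_ars = speed_ars, turn_ars = turn_ars),
            class = "navigation_gains")
}

# One agent worm; returns a worm_track with posture, labels and truth.
simulate_gradient_worm <- function(arena, gains, params, duration, seed) {
  fr <- params$frame_rate
  n <- as.integer(round(duration * fr))
  dt <- 1 / fr
  xopt <- position_of_o2(arena, arena$optimum)
  with_seed(seed, {
    x <- stats::runif(1, arena$edge_margin, arena$length - arena$edge_margin)
    y <- stats::runif(1, arena$edge_margin, arena$width - arena$edge_margin)
    H <- stats::runif(1, 0, 2 * pi)
    v0 <- params$speed_gain * params$undulation_amp * params$undulation_freq
    head_sd <- 0.25 * sqrt(dt)              # heading diffusion (rad)
    kern_len <- as.integer(round(params$turn_width * fr))
    kern <- raised_cosine_env(seq_len(kern_len) / fr, 0, params$turn_width)
    kern <- kern / sum(kern)
    xs <- ys <- hs <- numeric(n)
    lab <- rep("forward", n)
    head_incr <- numeric(n + kern_len)      # scheduled turn heading change
    ev_list <- list()
    rev_left <- 0L
    rev_onsets <- numeric(0)
    u_rev <- stats::runif(n); u_trn <- stats::runif(n)
    g_rnd <- stats::rnorm(n)
    trn_sgn <- sample(c(-1, 1), n, replace = TRUE)
    trn_jit <- stats::runif(n, 0.8, 1.2)
    trn_ctr <- stats::runif(n, 9, 16)
    for (i in seq_len(n)) {
      beta <- wrap_angle(H - (if (x <= xopt) 0 else pi))
      B <- abs(beta)
      if (rev_left > 0L) {
        lab[i] <- "reverse"
        rev_left <- rev_left - 1L
        if (rev_left == 0L) H <- H + pi + 0.5 * g_rnd[i]
        v <- v0
        step <- -1
      } else {
        rev_rate <- params$reversal_rate *
          (1 + gains$reversal_bias * (1 - cos(beta)) / 2)
        if (u_rev[i] < rev_rate / 60 * dt) {
          rev_left <- as.integer(round(params$reversal_dur * fr))
          rev_onsets <- c(rev_onsets, (i - 1) * dt)
        }
        trn_rate <- params$turn_event_rate
        if (u_trn[i] < trn_rate / 60 * dt) {
          amp <- params$turn_amp_scale * trn_jit[i] *
            max(0.1, 1 + gains$turn_ars * (B * 180 / pi - 90) / 90)
          idx <- i:(i + kern_len - 1L)
          head_incr[idx] <- head_incr[idx] + trn_sgn[i] * 1.2 * amp * kern
          ev_list[[length(ev_list) + 1L]] <-
            data.frame(onset_s = (i - 1) * dt, amplitude = amp,
                       sign = trn_sgn[i], center = trn_ctr[i],
                       bearing_deg = B * 180 / pi)
        }
        v <- v0 * max(0.05, 1 + gains$speed_ars * cos(beta))
        H <- H - gains$weathervane * sin(beta) * dt
        step <- 1
      }
      H <- H + head_incr[i] + head_sd * g_rnd[i]
      x <- x + step * v * cos(H) * dt
      y <- y + step * v * sin(H) * dt
      ## reflecting walls
      if (x < 0) { x <- -x; H <- pi - H }
      if (x > arena$length) { x <- 2 * arena$length - x; H <- pi - H }
      if (y < 0) { y <- -y; H <- -H }
      if (y > arena$width) { y <- 2 * arena$width - y; H <- -H }
      xs[i] <- x; ys[i] <- y; hs[i] <- H
    }

    ## posture: traveling wave (reversed during reversals) + turn bumps
    t <- (seq_len(n) - 1L) * dt
    dirphase <- ifelse(lab == "reverse", -1, 1)
    psi <- cumsum(2 * pi * params$undulation_freq * dirphase * dt)
    k <- seq_len(24)
    ang <- params$undulation_amp * sin(outer(psi, k * params$phase_per_segment, `-`))
    events <- if (length(ev_list)) do.call(rbind, ev_list)
    else data.frame(onset_s = numeric(), amplitude = numeric(),
                    sign = numeric(), center = numeric(),
                    bearing_deg = numeric())
    for (j in seq_len(nrow(events))) {
      shape <- turn_shape(events$center[j], 12, params$phase_per_segment)
      env <- raised_cosine_env(t, events$onset_s[j], params$turn_width)
      ang <- ang + (events$sign[j] * events$amplitude[j] * env) %o% shape
    }
    ang <- ang + matrix(stats::rnorm(n * 24, sd = params$angle_noise_sd),
                        n, 24)
    margin <- xs < arena$edge_margin | xs > arena$length - arena$edge_margin |
      ys < arena$edge_margin | ys > arena$width - arena$edge_margin
    posture <- posture_series(ang, fr)
    track <- worm_track(cbind(xs, ys), fr, posture = posture,
                        margin_mask = margin)
    structure(list(track = track, labels = state_labels(lab),
                   truth = list(events = events, rev_onsets_s = rev_onsets,
                                gains = gains, params = params,
                                heading = hs, seed = seed)),
              class = "gradient_worm")
  })
}

#' Generate a population of worms navigating the O2 gradient arena
#'
#' Each worm follows run-and-turn dynamics: constant-speed forward crawling
#' with heading diffusion, Poisson shallow turns and reversals, and the
#' navigation couplings of [navigation_gains()], each independently
#' switchable. Tracks carry a matching posture series (undulation wave
#' plus the same turn transients that steer the centroid) so the full
#' posture pipeline runs on them.
#'
#' @param arena a [gradient_arena()]
#' @param n_worms number of animals (>= 1)
#' @param gains a [navigation_gains()]
#' @param params a [kinematic_params()] (rates/amplitudes reused here)
#' @param duration seconds per worm
#' @param seed integer; worm i uses `seed + i - 1`
#' @return list of `gradient_worm` (each with `track`, `labels`, `truth`)
#' @export
generate_gradient_population <- function(arena, n_worms,
                                         gains = navigation_gains(),
                                         params = kinematic_params(),
                                         duration = 240, seed = 1L) {
  if (n_worms < 1) stop("n_worms must be >= 1", call. = FALSE)
  if (arena$length <= 0) stop("arena with zero length", call. = FALSE)
  lapply(seq_len(n_worms), function(i)
    simulate_gradient_worm(arena, gains, params, duration,
                           seed + i - 1L))
}
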