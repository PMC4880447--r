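# Synthetic two-channel fluorescence traces coupled to behavior with a
# fixed lag, emulating ratiometric recordings from a freely moving neuron.

#' Generate a synthetic calcium trace coupled to behavior
#'
#' The reference channel is a constant plus noise; the signal channel is
#' `baseline * (1 + gain_speed * speed(t - lag) + gain_turn *
#' turning_amp(t - lag))` plus noise. With both gains zero and no noise,
#' dR/R is identically zero after normalization.
#'
#' @param track a [worm_track()] (its frame rate sets the trace rate)
#' @param turning_amp per-frame turning amplitude (rad); defaults to the
#'   recording's ground-truth turning envelope when `track` came from
#'   [generate_posture_series()] is not available, so pass it explicitly
#'   for decomposed data
#' @param gain_speed ratio units per mm/s
#' @param gain_turn ratio units per rad
#' @param lag temporal lag of activity behind behavior (s, >= 0)
#' @param noise_sd channel noise standard deviation (a.u.)
#' @param baseline signal-channel baseline (a.u.)
#' @param ref_level reference-channel level (a.u.)
#' @param seed RNG seed
#' @return a [calcium_trace()] (not yet normalized) with attribute
#'   `truth` (the gains, lag, and lagged regressors)
#' @export
generate_calcium_trace <- function(track, turning_amp = NULL,
                                   gain_speed = 0, gain_turn = 0,
                                   lag = 0, noise_sd = 0.01,
                                   baseline = 100, ref_level = 100,
                                   seed = 1L) {
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  check_nonneg(noise_sd, "noise_sd")
  fr <- track$frame_rate
  n <- nrow(track$xy)
  sp <- centroid_speed(track)
  sp[!is.finite(sp)] <- stats::median(sp, na.rm = TRUE)
  if (is.null(turning_amp)) turning_amp <- rep(0, n)
  ta <- turning_amp
  ta[!is.finite(ta)] <- 0
  sp_l <- shift_series(sp, lag, fr)
  ta_l <- shift_series(ta, lag, fr)
  with_seed(seed, {
    signal <- baseline * (1 + gain_speed * sp_l + gain_turn * ta_l) +
      stats::rnorm(n, sd = noise_sd)
    reference <- ref_level + stats::rnorm(n, sd = noise_sd)
    tr <- calcium_trace(signal, reference, frame_rate = fr)
    attr(tr, "truth") <- list(gain_speed = gain_speed,
                              gain_turn = gain_turn, lag = lag,
                              speed_lagged = sp_l, turn_lagged = ta_l)
    tr
  })
}
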