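# Shared fixtures, built once per test session and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A default-parameter wild-type-like ensemble (50 recordings x 60 s).
wt_ensemble <- function() fixture("wt_ens", function()
  generate_ensemble(50, kinematic_params(seed = 100), duration = 60))

wt_basis <- function() fixture("wt_basis", function()
  fit_eigenworms(lapply(wt_ensemble(), function(r) r$posture)))

# A longer ensemble with all event types, for detector scoring.
event_ensemble <- function() fixture("event_ens", function()
  generate_ensemble(15, kinematic_params(seed = 50), duration = 180))

event_basis <- function() fixture("event_basis", function()
  fit_eigenworms(lapply(event_ensemble(), function(r) r$posture)))

# A smooth random posture frame within +-0.4 rad (wave + one turn bump),
# the shape family the skeleton roundtrip is specified over.
random_smooth_frame <- function() {
  k <- 1:24
  a <- 0.38 * sin(k * 0.39 + stats::runif(1, 0, 2 * pi)) *
    stats::runif(1, 0.5, 1) +
    stats::runif(1, -0.25, 0.25) *
    exp(-((k - stats::runif(1, 8, 16)) / 4)^2)
  pmax(pmin(a, 0.4), -0.4)
}

random_smooth_frame_seeded <- function(seed) {
  set.seed(seed)
  random_smooth_frame()
}

# Align extracted angles to a reference: head assignment is arbitrary for
# a single frame, and reversing the skeleton negates and reverses angles.
align_to_reference <- function(angles, reference) {
  if (sum((angles - reference)^2) <= sum((-rev(angles) - reference)^2))
    angles
  else -rev(angles)
}
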