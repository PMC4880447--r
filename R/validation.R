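# Ground-truth validation utilities for synthetic recordings: event-set
# matching and detector performance scoring.

#' Match detected events against ground-truth events
#'
#' Greedy one-to-one matching by interval overlap: each truth event is
#' matched to the first unused detected event whose interval overlaps it.
#'
#' @param detected,truth data.frames with `onset_s` and `duration_s`
#' @return named vector with `tp`, `fp`, `fn`
#' @export
match_event_sets <- function(detected, truth) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (j in seq_len(nrow(truth))) {
    t0 <- truth$onset_s[j]
    t1 <- t0 + truth$duration_s[j]
    hit <- which(!used & detected$onset_s < t1 &
                   (detected$onset_s + detected$duration_s) > t0)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}

#' Detector sensitivity and precision on a synthetic ensemble
#'
#' Runs [classify_states()] on every recording and scores the reversal,
#' omega and pause event detectors against the generator's ground-truth
#' event table.
#'
#' @param ensemble list of `synthetic_recording`
#' @param basis an [eigenworm_basis()]; fitted on the ensemble when `NULL`
#' @return data.frame with one row per detector: `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`
#' @export
detector_performance <- function(ensemble, basis = NULL) {
  if (is.null(basis))
    basis <- fit_eigenworms(lapply(ensemble, function(r) r$posture))
  agg <- list(reverse = c(tp = 0, fp = 0, fn = 0),
              omega = c(tp = 0, fp = 0, fn = 0),
              pause = c(tp = 0, fp = 0, fn = 0))
  for (r in ensemble) {
    cs <- classify_states(r$track, basis)
    tru <- r$truth$events
    for (ty in names(agg))
      agg[[ty]] <- agg[[ty]] +
        match_event_sets(cs$events[[ty]],
                         tru[tru$type == ty, , drop = FALSE])
  }
  out <- do.call(rbind, lapply(names(agg), function(ty) {
    v <- agg[[ty]]
    data.frame(detector = ty, tp = v["tp"], fp = v["fp"], fn = v["fn"],
               sensitivity = v["tp"] / (v["tp"] + v["fn"]),
               precision = v["tp"] / (v["tp"] + v["fp"]),
               row.names = NULL)
  }))
  out
}

#' Canonical eigenworm basis fitted on the synthetic wild-type ensemble
#'
#' A basis fitted once on a 50-recording default-parameter synthetic
#' ensemble and shipped as a plain-text package fixture (the file name
#' marks it as synthetic). Used for cross-condition comparisons so that
#' every condition is decomposed in the same coordinate system.
#'
#' @return an [eigenworm_basis()]
#' @export
canonical_eigenworms <- function() {
  path <- system.file("extdata", "canonical_eigenworms_synthetic.txt",
                      package = "wormgait")
  if (path == "") stop("canonical basis fixture not installed", call. = FALSE)
  read_basis(path)
}
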