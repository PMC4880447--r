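# Track-table and basis file formats, pipeline configuration, and the
# stage-chaining pipeline driver.

TRACK_SCHEMA_VERSION <- "wormgait-track-v1"
ANGLE_COLS <- sprintf("angle_%02d", 1:24)
TRACK_COLS <- c("track_id", "frame_index", "time_s", "centroid_x_mm",
                "centroid_y_mm", "state", "valid", ANGLE_COLS)

#' Write tracks to the delimited track-table format
#'
#' One row per frame with columns `track_id`, `frame_index`, `time_s`,
#' `centroid_x_mm`, `centroid_y_mm`, `state`, `valid`,
#' `angle_01...angle_24` (rad). The first line carries the schema version
#' as a `#` comment; missing values are written as `NA`.
#'
#' @param tracks a [worm_track()], a `synthetic_recording`, or a list of
#'   either
#' @param path output file
#' @param labels optional per-frame state labels (single track only);
#'   recordings carry their own
#' @return `path`, invisibly
#' @export
write_track_table <- function(tracks, path, labels = NULL) {
  as_row_df <- function(obj, id, labels = NULL) {
    if (inherits(obj, "synthetic_recording")) {
      labels <- obj$labels
      tr <- obj$track
    } else if (inherits(obj, "gradient_worm")) {
      labels <- obj$labels
      tr <- obj$track
    } else tr <- obj
    n <- nrow(tr$xy)
    ang <- if (!is.null(tr$posture)) tr$posture$angles
    else matrix(NA_real_, n, 24)
    valid <- if (!is.null(tr$posture)) tr$posture$valid else rep(TRUE, n)
    if (is.null(labels)) labels <- rep("forward", n)
    df <- data.frame(track_id = id, frame_index = seq_len(n) - 1L,
                     time_s = tr$timestamps,
                     centroid_x_mm = tr$xy[, 1], centroid_y_mm = tr$xy[, 2],
                     state = as.character(labels), valid = valid)
    ang_df <- as.data.frame(ang)
    names(ang_df) <- ANGLE_COLS
    cbind(df, ang_df)
  }
  if (inherits(tracks, c("worm_track", "synthetic_recording",
                         "gradient_worm")))
    tracks <- list(tracks)
  rows <- do.call(rbind, lapply(seq_along(tracks), function(i)
    as_row_df(tracks[[i]], i, if (i == 1) labels else NULL)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRACK_SCHEMA_VERSION), con)
  utils::write.table(format(rows, digits = 17, trim = TRUE,
                            scientific = FALSE), con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track-table file
#'
#' Validates the schema version line and required columns, checks the
#' angle unit convention (|angle| <= pi), and reconstructs one
#' [worm_track()] (with posture and labels) per `track_id`.
#'
#' @param path track-table file from [write_track_table()]
#' @return list of lists, each with `track` and `labels`
#' @export
read_track_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl(TRACK_SCHEMA_VERSION, first, fixed = TRUE))
    stop(sprintf("track table schema mismatch: expected '%s'",
                 TRACK_SCHEMA_VERSION), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("track table missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  angm <- as.matrix(df[ANGLE_COLS])
  if (any(abs(angm) > pi + 1e-9, na.rm = TRUE))
    stop("angle unit violation: |angle| > pi (degrees instead of rad?)",
         call. = FALSE)
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame_index), ]
    dt <- diff(d$time_s)
    fr <- 1 / stats::median(dt)
    posture <- posture_series(as.matrix(d[ANGLE_COLS]), fr,
                              valid = as.logical(d$valid),
                              t0 = d$time_s[1])
    list(track = worm_track(cbind(d$centroid_x_mm, d$centroid_y_mm), fr,
                            posture = posture, t0 = d$time_s[1]),
         labels = state_labels(d$state))
  })
}

#' Write / read an eigenworm basis as a plain-text matrix file
#'
#' Header lines (`#` comments) carry the frame count; the body is a
#' whitespace-delimited matrix whose first row is the per-angle means,
#' second row the variance fractions, followed by the 24 eigenvectors as
#' rows (EW1 first; columns ordered head to tail).
#'
#' @param basis an [eigenworm_basis()]
#' @param path file path
#' @return `path` (write) or the basis (read)
#' @export
write_basis <- function(basis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# wormgait eigenworm basis v1",
               sprintf("# n_frames %d", basis$n_frames)), con)
  utils::write.table(rbind(basis$means, basis$variance_fractions,
                           t(basis$vectors)), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  hdr <- readLines(path, n = 2L)
  n_frames <- as.integer(sub("# n_frames ", "", hdr[2]))
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  structure(list(vectors = t(unname(m[-(1:2), , drop = FALSE])),
                 means = unname(m[1, ]),
                 variance_fractions = unname(m[2, ]),
                 n_frames = n_frames), class = "eigenworm_basis")
}

#' Default pipeline configuration
#'
#' Every numeric default equals the documented value of the module it
#' configures; see the methods vignette for provenance.
#'
#' @return nested list of per-module settings
#' @export
default_config <- function() {
  list(
    posture = list(threshold = 0.5, scale_mm_per_px = 0.003,
                   short_skeleton_frac = 0.6, spline_df = 14),
    eigenmodes = list(phase_smooth_s = 0.5, min_fit_frames = 1000),
    locomotion = list(speed_half_window_s = 0.5, max_speed = 0.6,
                      curvature_min_speed = 0.03, max_curvature = 31,
                      pause_threshold = 0.05, pause_min_dur_s = 2,
                      pause_max_gap_s = 1, reversal_min_dur_s = 0.3,
                      omega_e_min = 0.85, omega_omega_min = 2,
                      rate_bin_s = 10, displacement_bin_s = 30),
    navigation = list(arena_length = 33, arena_width = 15,
                      o2_low = 4, o2_high = 21, optimum = 16,
                      edge_margin = 0.55, bearing_bin_deg = 20,
                      turn_bin_deg = 5, run_min_dur_s = 3,
                      run_min_disp_mm = 1, n_profile_bins = 13,
                      zero_cross_o2 = 13.8),
    neuro = list(ref_drop_frac = 0.3, ratio_mads = 5,
                 trigger_window_s = 8, min_pause_s = 60,
                 block_s = 0.5),
    seed = 1)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML document and merges it over [default_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file; `NULL` returns the defaults
#' @return nested configuration list
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  merge_strict <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop(sprintf("unknown config key%s under '%s': %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    for (k in names(user)) {
      base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
        merge_strict(base[[k]], user[[k]], paste0(where, "/", k))
      else user[[k]]
    }
    base
  }
  merge_strict(base, user, "config")
}

validate_config <- function(config) {
  pos_keys <- list(
    c("posture", "scale_mm_per_px"), c("eigenmodes", "phase_smooth_s"),
    c("locomotion", "rate_bin_s"), c("locomotion", "displacement_bin_s"),
    c("navigation", "bearing_bin_deg"), c("navigation", "turn_bin_deg"),
    c("navigation", "arena_length"), c("neuro", "block_s"))
  for (k in pos_keys) {
    v <- config[[k[1]]][[k[2]]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop(sprintf("config %s/%s must be a positive number", k[1], k[2]),
           call. = FALSE)
  }
  invisible(config)
}

#' Run the analysis pipeline on a set of recordings
#'
#' Executes the stages in dependency order - eigenworm fit, mode
#' decomposition, locomotion state detection, per-track metrics, report
#' tables - and writes every output with the configuration hash and seed
#' into `out_dir`. Outputs are a pure function of (inputs, config, seed).
#'
#' @param recordings list of `synthetic_recording` (or of lists with
#'   `track`/`labels` as returned by [read_track_table()])
#' @param config configuration list from [load_config()]
#' @param out_dir output directory (created if needed)
#' @param basis optional pre-fitted [eigenworm_basis()]
#' @return invisibly, a list with the fitted `basis`, per-track `states`,
#'   `decompositions`, and the output `manifest`
#' @export
run_pipeline <- function(recordings, config = default_config(),
                         out_dir = tempfile("wormgait_run_"),
                         basis = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  log_lines <- c(sprintf("config_hash %s", cfg_hash),
                 sprintf("seed %s", config$seed),
                 sprintf("n_recordings %d", length(recordings)))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s ok", name))
    res
  }
  tracks <- lapply(recordings, function(r) r$track)
  postures <- lapply(tracks, function(tr) tr$posture)

  if (is.null(basis))
    basis <- stage("fit_eigenworms", fit_eigenworms(
      postures, min_frames = config$eigenmodes$min_fit_frames))
  write_basis(basis, file.path(out_dir, "eigenworm_basis.txt"))

  decomps <- stage("decompose", lapply(postures, decompose, basis = basis,
                                       phase_smooth_s = config$eigenmodes$phase_smooth_s))
  states <- stage("locomotion", lapply(tracks, classify_states,
                                       basis = basis))

  per_frame <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, time_s = tr$timestamps,
               speed_mm_s = centroid_speed(tr),
               curvature_rad_mm = track_curvature(tr),
               state = as.character(states[[i]]$state),
               undulation_amp = decomps[[i]]$undulation_amp,
               turning_amp = decomps[[i]]$turning_amp,
               phase_velocity = decomps[[i]]$phase_velocity)
  }))
  rates <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track_id = i, states[[i]]$reversals$rates,
          omega_rate_per_min = states[[i]]$omegas$rates$rate_per_min)))
  disp <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track_id = i,
          displacement_binned(tracks[[i]],
                              bin = config$locomotion$displacement_bin_s))))
  header <- sprintf("# wormgait pipeline config=%s seed=%s", cfg_hash,
                    config$seed)
  wrt <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    p
  }
  manifest <- c(wrt(per_frame, "per_frame_metrics.csv"),
                wrt(rates, "event_rates.csv"),
                wrt(disp, "displacement.csv"))
  vf <- data.frame(component = seq_len(24),
                   variance_fraction = basis$variance_fractions,
                   cumulative = cumsum(basis$variance_fractions))
  manifest <- c(manifest, wrt(vf, "variance_fractions.csv"))
  log_lines <- c(log_lines, sprintf("frames_total %d",
                                    sum(vapply(tracks, function(t)
                                      nrow(t$xy), numeric(1)))),
                 sprintf("frames_invalid %d",
                         sum(vapply(postures, function(p)
                           sum(!p$valid), numeric(1)))))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  invisible(list(basis = basis, states = states,
                 decompositions = decomps, manifest = manifest,
                 out_dir = out_dir))
}
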