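#' Scanpath specification for the synthetic generator
#'
#' Describes one ground-truthed binocular recording: a plan of fixations
#' (positions and durations), saccade durations, measurement noise,
#' data loss and sampling rate. Defaults emulate a 250 Hz screen-based
#' binocular tracker with moderate infant-quality noise.
#'
#' @param fixations Tibble/data.frame with columns `x`, `y` (px) and
#'   `duration` (ms): the planted fixation sequence.
#' @param saccade_ms Length-2 range of saccade durations (ms) between
#'   successive fixations; each saccade's duration is drawn uniformly.
#' @param noise_sd Isotropic per-eye measurement noise, in degrees of
#'   visual angle (converted via [pixels_per_degree()]).
#' @param missing_rate Per-sample, per-eye probability of data loss.
#' @param interocular_offset Horizontal disparity between the two recorded
#'   eye positions (px); each eye is offset half of it.
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return A list of class `scanpath_spec`.
#' @export
scanpath_spec <- function(fixations,
                          saccade_ms = c(30, 60),
                          noise_sd = 0.3,
                          missing_rate = 0.02,
                          interocular_offset = 4,
                          rate = 250,
                          seed = 1L) {
  fixations <- tibble::as_tibble(fixations)
  stopifnot(all(c("x", "y", "duration") %in% names(fixations)),
            nrow(fixations) >= 1L, all(fixations$duration > 0),
            length(saccade_ms) == 2L, all(saccade_ms > 0),
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1, rate > 0)
  structure(list(fixations = fixations, saccade_ms = as.numeric(saccade_ms),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 interocular_offset = interocular_offset, rate = rate,
                 seed = as.integer(seed)),
            class = "scanpath_spec")
}

#' Random main-sequence-consistent fixation plan
#'
#' Draws a random sequence of fixation positions and durations for
#' [scanpath_spec()]. Consecutive positions are kept at least
#' `min_step_px` apart: saccades of 30-60 ms correspond, via the
#' oculomotor main sequence, to amplitudes of several degrees, so
#' sub-degree "saccades" would be kinematically inconsistent with the
#' saccade durations the generator plants.
#'
#' @param n_fixations Number of fixations.
#' @param geometry A [screen_geometry()].
#' @param duration_ms Length-2 range of fixation durations (ms).
#' @param min_step_px Minimum distance between consecutive fixations (px).
#' @param margin Margin kept from the screen edges (px).
#' @param seed Integer seed.
#' @return A tibble with `x`, `y`, `duration`, usable as a fixation plan.
#' @export
random_fixation_plan <- function(n_fixations, geometry,
                                 duration_ms = c(150, 400),
                                 min_step_px = 250, margin = 100,
                                 seed = 1L) {
  stopifnot(inherits(geometry, "screen_geometry"), n_fixations >= 1L)
  W <- geometry$raster_width
  H <- geometry$raster_height
  stopifnot(min_step_px < sqrt((W - 2 * margin)^2 + (H - 2 * margin)^2))
  with_seed(seed, {
    x <- y <- numeric(n_fixations)
    x[1L] <- stats::runif(1, margin, W - margin)
    y[1L] <- stats::runif(1, margin, H - margin)
    for (i in seq_len(n_fixations)[-1L]) {
      repeat {
        cx <- stats::runif(1, margin, W - margin)
        cy <- stats::runif(1, margin, H - margin)
        if (sqrt((cx - x[i - 1L])^2 + (cy - y[i - 1L])^2) >= min_step_px) break
      }
      x[i] <- cx; y[i] <- cy
    }
    tibble::tibble(x = x, y = y,
                   duration = stats::runif(n_fixations, duration_ms[1L],
                                           duration_ms[2L]))
  })
}

# Run code with a private RNG state so simulation never disturbs (and is
# never disturbed by) the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one ground-truthed binocular gaze trace
#'
#' Samples the planted scanpath at the nominal rate: constant position
#' during fixations, constant-velocity linear interpolation during
#' saccades, independent isotropic Gaussian noise per eye, horizontal
#' interocular offset, and per-eye sample dropout. Returns both the raw
#' trace and the planted events so detection can be scored against truth.
#'
#' @param spec A [scanpath_spec()].
#' @param geometry A [screen_geometry()]; plan positions must be on screen.
#' @param participant_id,group,stimulus_id Identifiers for the trace.
#' @return A list with `trace` (a [gaze_trace()]) and `truth` (tibble of
#'   planted fixations: `x`, `y`, `onset`, `offset`, `duration`).
#' @export
generate_trace <- function(spec, geometry, participant_id = "sim",
                           group = "sim", stimulus_id = "stim") {
  stopifnot(inherits(spec, "scanpath_spec"), inherits(geometry, "screen_geometry"))
  plan <- spec$fixations
  if (!all(is_on_screen(plan$x, plan$y, geometry))) {
    stop("generate_trace: fixation plan positions must be on screen", call. = FALSE)
  }
  with_seed(spec$seed, {
    nfix <- nrow(plan)
    sacc <- if (nfix > 1L) {
      stats::runif(nfix - 1L, spec$saccade_ms[1L], spec$saccade_ms[2L])
    } else numeric(0)
    onset <- cumsum(c(0, plan$duration[-nfix] + sacc))
    offset <- onset + plan$duration
    total <- offset[nfix]
    dt <- 1000 / spec$rate
    t <- seq(0, total, by = dt)
    # ideal cyclopean position: piecewise constant + linear saccade ramps
    px <- py <- numeric(length(t))
    for (i in seq_len(nfix)) {
      infix <- t >= onset[i] & t <= offset[i]
      px[infix] <- plan$x[i]
      py[infix] <- plan$y[i]
      if (i < nfix) {
        insac <- t > offset[i] & t < onset[i + 1L]
        frac <- (t[insac] - offset[i]) / (onset[i + 1L] - offset[i])
        px[insac] <- plan$x[i] + frac * (plan$x[i + 1L] - plan$x[i])
        py[insac] <- plan$y[i] + frac * (plan$y[i + 1L] - plan$y[i])
      }
    }
    sigma <- spec$noise_sd * pixels_per_degree(geometry)
    half <- spec$interocular_offset / 2
    n <- length(t)
    eye <- function(sign) {
      list(x = px + sign * half + stats::rnorm(n, 0, sigma),
           y = py + stats::rnorm(n, 0, sigma))
    }
    L <- eye(-1); R <- eye(1)
    lval <- stats::runif(n) >= spec$missing_rate
    rval <- stats::runif(n) >= spec$missing_rate
    samples <- tibble::tibble(
      t = t,
      left_x = ifelse(lval, L$x, NA_real_),
      left_y = ifelse(lval, L$y, NA_real_),
      right_x = ifelse(rval, R$x, NA_real_),
      right_y = ifelse(rval, R$y, NA_real_),
      left_valid = lval, right_valid = rval
    )
    list(
      trace = gaze_trace(participant_id, group, stimulus_id, samples,
                         nominal_rate = spec$rate, geometry = geometry),
      truth = tibble::tibble(x = plan$x, y = plan$y, onset = onset,
                             offset = offset, duration = plan$duration)
    )
  })
}

#' Experiment specification for the synthetic generator
#'
#' A multi-group, multi-stimulus design: each group has a dwell-propensity
#' map giving the mean fraction of fixation time its members spend on each
#' semantic region; the residual propensity goes to `Background`.
#'
#' @param groups Named integer vector: group name -> number of
#'   participants.
#' @param stimuli Tibble/data.frame with `stimulus_id`, `condition`
#'   (`"static"`/`"dynamic"`) and `duration_ms`.
#' @param propensities Named list: group name -> named numeric vector of
#'   mean dwell fractions per semantic label (sum <= 1; remainder is
#'   Background).
#' @param anchors Named list: semantic label -> c(x, y) hotspot (px) where
#'   that region's fixations concentrate. Must include `Background`.
#' @param anchor_sd Within-region fixation scatter around the hotspot (px).
#' @param propensity_sd Between-participant SD of individual dwell
#'   propensities around the group mean (on the fraction scale).
#' @param fixation_ms Length-2 range of planted fixation durations (ms).
#' @param noise_sd,missing_rate,rate Passed to [scanpath_spec()].
#' @param seed Master seed; per-trace seeds are derived from it.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(groups,
                            stimuli,
                            propensities,
                            anchors,
                            anchor_sd = 25,
                            propensity_sd = 0.08,
                            fixation_ms = c(150, 400),
                            noise_sd = 0.3,
                            missing_rate = 0.02,
                            rate = 250,
                            seed = 1L) {
  stimuli <- tibble::as_tibble(stimuli)
  stopifnot(length(groups) >= 1L, !is.null(names(groups)), all(groups >= 1),
            all(c("stimulus_id", "condition", "duration_ms") %in% names(stimuli)),
            all(names(groups) %in% names(propensities)),
            "Background" %in% names(anchors))
  for (g in names(groups)) {
    p <- propensities[[g]]
    stopifnot(all(p >= 0), sum(p) <= 1 + 1e-12,
              all(names(p) %in% names(anchors)))
  }
  structure(list(groups = groups, stimuli = stimuli,
                 propensities = propensities, anchors = anchors,
                 anchor_sd = anchor_sd, propensity_sd = propensity_sd,
                 fixation_ms = as.numeric(fixation_ms), noise_sd = noise_sd,
                 missing_rate = missing_rate, rate = rate,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Generate a full synthetic experiment with ground truth
#'
#' For each participant x stimulus, draws an individual dwell-propensity
#' vector around the group means, plans a scanpath whose fixations land
#' near the semantic anchors in proportion to those propensities, and
#' generates the binocular trace with [generate_trace()]. Emits complete
#' truth tables (planted fixations, intended labels, intended RFD) for
#' end-to-end recovery tests.
#'
#' @param spec An [experiment_spec()].
#' @param geometry A [screen_geometry()].
#' @return A list with `traces` (list of `gaze_trace`), `truth_fixations`
#'   (tibble incl. intended label per planted fixation), and `truth_rfd`
#'   (intended per-participant RFD per label, from planted durations).
#' @export
generate_experiment <- function(spec, geometry) {
  stopifnot(inherits(spec, "experiment_spec"), inherits(geometry, "screen_geometry"))
  labels <- names(spec$anchors)
  traces <- list()
  truth_fix <- list()
  with_seed(spec$seed, {
    for (g in names(spec$groups)) {
      base_p <- spec$propensities[[g]]
      for (pi in seq_len(spec$groups[[g]])) {
        pid <- sprintf("%s_%02d", g, pi)
        # individual propensity: jitter group means, fill Background, renormalize
        p <- stats::setNames(numeric(length(labels)), labels)
        p[names(base_p)] <- pmax(base_p + stats::rnorm(length(base_p), 0, spec$propensity_sd), 0.01)
        p["Background"] <- max(1 - sum(p[names(base_p)]), 0.02)
        p <- p / sum(p)
        for (si in seq_len(nrow(spec$stimuli))) {
          stim <- spec$stimuli[si, ]
          nfix <- max(2L, round(stim$duration_ms / mean(spec$fixation_ms) / 1.2))
          labs <- sample(labels, nfix, replace = TRUE, prob = p)
          anchor <- t(vapply(spec$anchors[labs], as.numeric, numeric(2)))
          x <- pmin(pmax(anchor[, 1L] + stats::rnorm(nfix, 0, spec$anchor_sd), 5),
                    geometry$raster_width - 5)
          y <- pmin(pmax(anchor[, 2L] + stats::rnorm(nfix, 0, spec$anchor_sd), 5),
                    geometry$raster_height - 5)
          dur <- stats::runif(nfix, spec$fixation_ms[1L], spec$fixation_ms[2L])
          sp <- scanpath_spec(
            tibble::tibble(x = x, y = y, duration = dur),
            noise_sd = spec$noise_sd, missing_rate = spec$missing_rate,
            rate = spec$rate,
            seed = sample.int(.Machine$integer.max, 1L)
          )
          out <- generate_trace(sp, geometry, participant_id = pid,
                                group = g, stimulus_id = stim$stimulus_id)
          key <- paste(pid, stim$stimulus_id, sep = "/")
          traces[[key]] <- out$trace
          truth_fix[[key]] <- dplyr::bind_cols(
            tibble::tibble(participant_id = pid, group = g,
                           stimulus_id = stim$stimulus_id,
                           condition = stim$condition),
            out$truth, tibble::tibble(aoi_label = labs)
          )
        }
      }
    }
  })
  truth_fixations <- dplyr::bind_rows(truth_fix)
  truth_rfd <- truth_fixations |>
    dplyr::group_by(.data$participant_id, .data$group, .data$stimulus_id,
                    .data$condition, .data$aoi_label) |>
    dplyr::summarise(label_ms = sum(.data$duration), .groups = "drop_last") |>
    dplyr::mutate(rfd = .data$label_ms / sum(.data$label_ms)) |>
    dplyr::ungroup()
  list(traces = traces, truth_fixations = truth_fixations,
       truth_rfd = truth_rfd)
}
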