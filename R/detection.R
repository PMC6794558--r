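#' Event-detection configuration
#'
#' Tunable parameters of the fixation/saccade classifier. Defaults are
#' conservative values for 250 Hz screen-based recordings; every parameter
#' is surfaced here so the classification is fully auditable.
#'
#' @param min_fixation_ms Candidate fixations shorter than this are
#'   discarded as noise (ms). 60 ms is 15 samples at 250 Hz.
#' @param merge_max_gap_ms Successive fixations separated by at most this
#'   gap are candidates for merging (ms).
#' @param merge_max_dist_deg Maximum centroid separation for merging, in
#'   degrees of visual angle (converted with [pixels_per_degree()]).
#' @param smooth_window Width (odd number of samples) of the moving-average
#'   position filter applied to the cyclopean trace before velocity
#'   computation; 1 disables smoothing. At 250 Hz with typical measurement
#'   noise, raw sample-to-sample velocities are noise-dominated; a 3-sample
#'   boxcar suppresses that noise while blurring event edges by at most one
#'   sample on each side.
#' @param threshold_method `"adaptive"` (bimodal log-velocity density, with
#'   robust fallback) or `"fixed"`.
#' @param fixed_threshold Velocity threshold in px/s when
#'   `threshold_method = "fixed"`.
#' @param mad_multiplier Multiplier for the robust fallback threshold
#'   `median(v) + k * mad(v)`.
#' @param refine_edges Snap fixation onsets/offsets to the unsmoothed
#'   positions after velocity classification (see [classify_events()]).
#'   Velocity thresholding on smoothed positions locates events robustly
#'   but blurs their edges by a sample or two; the refinement pass walks
#'   each boundary on the raw cyclopean trace, keeping samples within a
#'   robust radius of the fixation's core position.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(min_fixation_ms = 60,
                             merge_max_gap_ms = 75,
                             merge_max_dist_deg = 0.7,
                             smooth_window = 3,
                             threshold_method = c("adaptive", "fixed"),
                             fixed_threshold = NULL,
                             mad_multiplier = 5,
                             refine_edges = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_fixation_ms >= 0, merge_max_gap_ms >= 0,
            merge_max_dist_deg >= 0, smooth_window >= 1,
            smooth_window %% 2 == 1, mad_multiplier > 0)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold <= 0)) {
    stop("detection_config: fixed threshold_method needs fixed_threshold > 0",
         call. = FALSE)
  }
  structure(list(
    min_fixation_ms = min_fixation_ms,
    merge_max_gap_ms = merge_max_gap_ms,
    merge_max_dist_deg = merge_max_dist_deg,
    smooth_window = as.integer(smooth_window),
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    mad_multiplier = mad_multiplier,
    refine_edges = isTRUE(refine_edges)
  ), class = "detection_config")
}

#' Fuse the two eyes into a cyclopean trace
#'
#' Averages left- and right-eye coordinates where both are valid; where one
#' eye is missing the other eye's coordinates are substituted (cross-eye
#' interpolation). Samples with both eyes missing stay missing — no
#' fabrication across time.
#'
#' @param trace A [gaze_trace()].
#' @return A tibble of class `cyclopean_trace` with columns `t`, `x`, `y`
#'   and `source` (one of `both_eyes`, `left_only`, `right_only`,
#'   `missing`), carrying the trace identifiers and geometry as attributes.
#' @export
fuse_eyes <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  s <- trace$samples
  both <- s$left_valid & s$right_valid
  lonly <- s$left_valid & !s$right_valid
  ronly <- !s$left_valid & s$right_valid
  x <- y <- rep(NA_real_, nrow(s))
  x[both] <- (s$left_x[both] + s$right_x[both]) / 2
  y[both] <- (s$left_y[both] + s$right_y[both]) / 2
  x[lonly] <- s$left_x[lonly]; y[lonly] <- s$left_y[lonly]
  x[ronly] <- s$right_x[ronly]; y[ronly] <- s$right_y[ronly]
  source <- rep("missing", nrow(s))
  source[both] <- "both_eyes"
  source[lonly] <- "left_only"
  source[ronly] <- "right_only"
  ct <- tibble::tibble(t = s$t, x = x, y = y, source = source)
  attr(ct, "trace_id") <- trace_id(trace)
  attr(ct, "participant_id") <- trace$participant_id
  attr(ct, "group") <- trace$group
  attr(ct, "stimulus_id") <- trace$stimulus_id
  attr(ct, "geometry") <- trace$geometry
  class(ct) <- c("cyclopean_trace", class(ct))
  ct
}

#' Moving-average position smoothing
#'
#' Boxcar-averages valid cyclopean samples over a centred window of
#' `window` samples. A sample that is itself missing stays missing; valid
#' neighbours inside the window are averaged regardless of interior gaps.
#'
#' @param ct A `cyclopean_trace` from [fuse_eyes()].
#' @param window Odd window width in samples; 1 returns the input.
#' @return A `cyclopean_trace` with smoothed coordinates.
#' @export
smooth_positions <- function(ct, window = 3) {
  stopifnot(inherits(ct, "cyclopean_trace"), window >= 1, window %% 2 == 1)
  if (window == 1L || nrow(ct) < 2L) return(ct)
  half <- (window - 1L) %/% 2L
  valid <- !is.na(ct$x)
  xs <- ifelse(valid, ct$x, 0)
  ys <- ifelse(valid, ct$y, 0)
  vn <- as.numeric(valid)
  ksum <- function(z) {
    # centred running sum over the window, edge-truncated
    cz <- cumsum(z)
    n <- length(z)
    hi <- pmin(seq_len(n) + half, n)
    lo <- pmax(seq_len(n) - half, 1L)
    cz[hi] - c(0, cz)[lo]
  }
  denom <- ksum(vn)
  sx <- ksum(xs) / denom
  sy <- ksum(ys) / denom
  out <- ct
  out$x[valid] <- sx[valid]
  out$y[valid] <- sy[valid]
  out
}

#' Point-to-point gaze velocity
#'
#' For each consecutive pair of valid samples, the Euclidean distance
#' between the two points divided by the elapsed time, in px/s. Pairs that
#' span a missing sample are omitted.
#'
#' @param ct A `cyclopean_trace`.
#' @return A tibble of class `velocity_series` with columns `t` (midpoint
#'   of the pair, ms), `v` (px/s), and `i` (row index of the pair's first
#'   sample in the input trace).
#' @export
compute_velocity <- function(ct) {
  stopifnot(inherits(ct, "cyclopean_trace"))
  valid <- which(!is.na(ct$x))
  if (length(valid) < 2L) {
    stop("compute_velocity: insufficient data (fewer than 2 valid samples)",
         call. = FALSE)
  }
  i1 <- valid[-length(valid)]
  i2 <- valid[-1L]
  keep <- i2 == i1 + 1L  # consecutive samples only: never bridge a gap
  i1 <- i1[keep]; i2 <- i2[keep]
  if (!length(i1)) {
    stop("compute_velocity: no consecutive valid sample pairs", call. = FALSE)
  }
  dt <- (ct$t[i2] - ct$t[i1]) / 1000  # s
  d <- sqrt((ct$x[i2] - ct$x[i1])^2 + (ct$y[i2] - ct$y[i1])^2)
  vs <- tibble::tibble(t = (ct$t[i1] + ct$t[i2]) / 2, v = d / dt, i = i1)
  attr(vs, "trace_id") <- attr(ct, "trace_id")
  class(vs) <- c("velocity_series", class(vs))
  vs
}

# Local maxima of a density estimate (interior points only).
density_peaks <- function(y) {
  n <- length(y)
  which(y[-c(1, 2)] < y[-c(1, n)] & y[-c(n - 1, n)] < y[-c(1, n)]) + 1L
}

#' Adaptive velocity threshold
#'
#' Estimates, for one trace, the velocity separating the slow (fixation)
#' mode from the fast (saccade) mode. The density of log10 velocity is
#' smoothed ([stats::density()]); when two substantial modes are present
#' the threshold is placed at the density minimum between the two highest
#' modes (`method = "adaptive_bimodal"`). When the series is effectively
#' unimodal or degenerate the robust fallback `median(v) + k * mad(v)` is
#' used (`method = "fallback_robust"`). The estimate is deterministic given
#' the series and configuration, so each participant x trial gets its own
#' data-quality-dependent threshold.
#'
#' @param vs A `velocity_series` from [compute_velocity()].
#' @param config A [detection_config()].
#' @return A list of class `velocity_threshold` with fields `value` (px/s),
#'   `method`, and `trace_id`.
#' @export
estimate_threshold <- function(vs, config = detection_config()) {
  stopifnot(inherits(vs, "velocity_series"))
  if (!nrow(vs)) stop("estimate_threshold: empty velocity series", call. = FALSE)
  tid <- attr(vs, "trace_id")
  if (is.null(tid)) tid <- NA_character_
  mk <- function(value, method) {
    structure(list(value = value, method = method, trace_id = tid),
              class = "velocity_threshold")
  }
  if (config$threshold_method == "fixed") {
    return(mk(config$fixed_threshold, "fixed"))
  }
  v <- vs$v[vs$v > 0]
  fallback <- function() {
    med <- stats::median(vs$v)
    spread <- stats::mad(vs$v)
    if (spread == 0) spread <- max(med, 1) * 0.1
    mk(med + config$mad_multiplier * spread, "fallback_robust")
  }
  if (length(v) < 10L || length(unique(v)) < 3L) {
    warning("estimate_threshold: degenerate velocity series for trace '",
            tid, "'; using robust fallback", call. = FALSE)
    return(fallback())
  }
  if (length(v) < 0.5 * nrow(vs)) {
    # zero-inflated series (noiseless stationary gaze): the slow mode sits
    # at exactly zero and the log-density would only see saccade speeds
    return(fallback())
  }
  lv <- log10(v)
  den <- stats::density(lv, n = 512)
  peaks <- density_peaks(den$y)
  peaks <- peaks[den$y[peaks] >= 0.05 * max(den$y)]
  if (length(peaks) < 2L) return(fallback())
  top2 <- sort(peaks[order(den$y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  valley <- between[which.min(den$y[between])]
  # require a real dip between the two modes, else treat as unimodal
  if (den$y[valley] > 0.8 * min(den$y[top2])) return(fallback())
  mk(10^den$x[valley], "adaptive_bimodal")
}

#' Classify fixations and saccades
#'
#' Samples belonging to sub-threshold velocity runs become candidate
#' fixations ("if the gaze moves faster than the usual speed of the eye it
#' is a saccade, otherwise a fixation"); candidates shorter than
#' `config$min_fixation_ms` are discarded as noise. Fixation position is
#' the duration-weighted centroid of the run's samples (each sample
#' weighted by the time interval it covers within the run).
#'
#' @param ct A `cyclopean_trace` (smoothed or not).
#' @param threshold A `velocity_threshold` estimated from the same trace.
#' @param config A [detection_config()].
#' @param raw Optional unsmoothed `cyclopean_trace` (same samples as `ct`)
#'   used for edge refinement and fixation positions when
#'   `config$refine_edges` is `TRUE`; defaults to `ct` itself.
#' @return A `fixation_set`: identifiers, a tibble of fixations (`x`, `y`,
#'   `onset`, `offset`, `duration`, `n_samples`, `merged_from`), the
#'   threshold used, and `total_on_screen_duration` (ms).
#' @export
classify_events <- function(ct, threshold, config = detection_config(),
                            raw = NULL) {
  stopifnot(inherits(ct, "cyclopean_trace"),
            inherits(threshold, "velocity_threshold"))
  if (is.null(raw)) raw <- ct
  stopifnot(nrow(raw) == nrow(ct))
  vs <- compute_velocity(ct)
  slow <- vs$v <= threshold$value
  # runs of consecutive slow pairs; a run of pairs i..j spans samples i..j+1
  runs <- list()
  if (any(slow)) {
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      # pair indices must also be consecutive in the sample index (no gap)
      idx <- vs$i[starts[k]:ends[k]]
      brk <- c(0L, which(diff(idx) != 1L), length(idx))
      for (b in seq_len(length(brk) - 1L)) {
        seg <- idx[(brk[b] + 1L):brk[b + 1L]]
        runs[[length(runs) + 1L]] <- c(seg[1L], seg[length(seg)] + 1L)
      }
    }
  }
  if (config$refine_edges && length(runs)) {
    runs <- refine_run_edges(raw, runs)
  }
  pos_trace <- if (config$refine_edges) raw else ct
  fixrows <- lapply(runs, function(ab) {
    fixation_from_samples(pos_trace, ab[1L]:ab[2L])
  })
  fx <- if (length(fixrows)) dplyr::bind_rows(fixrows) else empty_fixation_tbl()
  fx <- fx[fx$duration >= config$min_fixation_ms, , drop = FALSE]
  new_fixation_set(ct, fx, threshold)
}

# Snap run boundaries to the unsmoothed trace: for each run, estimate the
# fixation's core position and noise scale robustly, then grow/shrink each
# boundary to the contiguous block of samples within a 3-sigma radius of
# the core. Boundaries never cross the neighbouring run.
refine_run_edges <- function(raw, runs) {
  n <- nrow(raw)
  m <- length(runs)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    a <- runs[[k]][1L]; b <- runs[[k]][2L]
    lo <- if (k == 1L) 1L else out[[k - 1L]][2L] + 1L
    hi <- if (k == m) n else runs[[k + 1L]][1L] - 1L
    idx <- a:b
    core <- if (length(idx) >= 9L) idx[4:(length(idx) - 3L)] else idx
    cx <- stats::median(raw$x[core], na.rm = TRUE)
    cy <- stats::median(raw$y[core], na.rm = TRUE)
    d <- sqrt((raw$x - cx)^2 + (raw$y - cy)^2)
    sigma <- stats::median(d[core], na.rm = TRUE) / 1.1774  # Rayleigh median
    r <- max(3 * sigma, 1e-6)
    # offset: extend over contiguous near samples, else shrink past far ones
    nb <- b
    while (nb < hi && !is.na(d[nb + 1L]) && d[nb + 1L] <= r) nb <- nb + 1L
    while (nb > a && (is.na(d[nb]) || d[nb] > r)) nb <- nb - 1L
    na_ <- a
    while (na_ > lo && !is.na(d[na_ - 1L]) && d[na_ - 1L] <= r) na_ <- na_ - 1L
    while (na_ < nb && (is.na(d[na_]) || d[na_] > r)) na_ <- na_ + 1L
    out[[k]] <- c(na_, nb)
  }
  out
}

fixation_from_samples <- function(ct, smp) {
  t <- ct$t[smp]
  # trapezoidal per-sample dwell weights: half-gap to each neighbour in run
  if (length(smp) > 1L) {
    gaps <- diff(t)
    w <- (c(gaps, 0) + c(0, gaps)) / 2
  } else {
    w <- 1
  }
  tibble::tibble(
    x = sum(ct$x[smp] * w) / sum(w),
    y = sum(ct$y[smp] * w) / sum(w),
    onset = t[1L], offset = t[length(t)],
    duration = t[length(t)] - t[1L],
    n_samples = length(smp), merged_from = 1L
  )
}

empty_fixation_tbl <- function() {
  tibble::tibble(x = numeric(), y = numeric(), onset = numeric(),
                 offset = numeric(), duration = numeric(),
                 n_samples = integer(), merged_from = integer())
}

new_fixation_set <- function(ct, fx, threshold) {
  geom <- attr(ct, "geometry")
  on <- is_on_screen(fx$x, fx$y, geom)
  structure(list(
    trace_id = attr(ct, "trace_id"),
    participant_id = attr(ct, "participant_id"),
    group = attr(ct, "group"),
    stimulus_id = attr(ct, "stimulus_id"),
    fixations = fx,
    threshold = threshold,
    total_on_screen_duration = sum(fx$duration[on]),
    geometry = geom
  ), class = "fixation_set")
}

#' @export
print.fixation_set <- function(x, ...) {
  cat(sprintf(
    "<fixation_set> %s: %d fixations, %.0f ms on screen (threshold %.0f px/s, %s)\n",
    x$trace_id, nrow(x$fixations), x$total_on_screen_duration,
    x$threshold$value, x$threshold$method
  ))
  invisible(x)
}

#' Merge successive nearby fixations
#'
#' Successive fixations separated by a gap of at most
#' `config$merge_max_gap_ms` whose centroids lie within
#' `config$merge_max_dist_deg` (converted to px) are merged into one event:
#' onset of the first, offset of the last, duration-weighted centroid.
#' Passes repeat until no pair merges, so the operation is idempotent.
#'
#' @param fs A `fixation_set`.
#' @param config A [detection_config()].
#' @return A `fixation_set` with merged events; `merged_from` counts the
#'   original events absorbed into each row.
#' @export
merge_fixations <- function(fs, config = detection_config()) {
  stopifnot(inherits(fs, "fixation_set"))
  fx <- fs$fixations
  max_dist <- config$merge_max_dist_deg * pixels_per_degree(fs$geometry)
  repeat {
    if (nrow(fx) < 2L) break
    merged_any <- FALSE
    out <- fx[1L, , drop = FALSE]
    for (i in 2L:nrow(fx)) {
      cur <- out[nrow(out), ]
      nxt <- fx[i, ]
      gap <- nxt$onset - cur$offset
      dist <- sqrt((nxt$x - cur$x)^2 + (nxt$y - cur$y)^2)
      if (gap <= config$merge_max_gap_ms && dist <= max_dist) {
        w <- c(cur$duration, nxt$duration)
        if (sum(w) == 0) w <- c(1, 1)
        out[nrow(out), ] <- tibble::tibble(
          x = sum(c(cur$x, nxt$x) * w) / sum(w),
          y = sum(c(cur$y, nxt$y) * w) / sum(w),
          onset = cur$onset, offset = nxt$offset,
          duration = nxt$offset - cur$onset,
          n_samples = cur$n_samples + nxt$n_samples,
          merged_from = cur$merged_from + nxt$merged_from
        )
        merged_any <- TRUE
      } else {
        out <- dplyr::bind_rows(out, nxt)
      }
    }
    fx <- out
    if (!merged_any) break
  }
  fs$fixations <- fx
  on <- is_on_screen(fx$x, fx$y, fs$geometry)
  fs$total_on_screen_duration <- sum(fx$duration[on])
  fs
}

#' Full fixation detection for one trace
#'
#' Convenience wrapper running the whole event-detection chain:
#' [fuse_eyes()] -> [smooth_positions()] -> [compute_velocity()] ->
#' [estimate_threshold()] -> [classify_events()] -> [merge_fixations()].
#'
#' @param trace A [gaze_trace()].
#' @param config A [detection_config()].
#' @return A `fixation_set`.
#' @export
detect_fixations <- function(trace, config = detection_config()) {
  raw <- fuse_eyes(trace)
  ct <- smooth_positions(raw, config$smooth_window)
  vs <- compute_velocity(ct)
  thr <- estimate_threshold(vs, config)
  merge_fixations(classify_events(ct, thr, config, raw = raw), config)
}

#' Write a fixation set (or list of them) as a delimited audit table
#'
#' @param fixsets A `fixation_set` or list of them.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(fixsets, path) {
  if (inherits(fixsets, "fixation_set")) fixsets <- list(fixsets)
  rows <- lapply(fixsets, function(fs) {
    if (!nrow(fs$fixations)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(participant = fs$participant_id, group = fs$group,
                     stimulus = fs$stimulus_id),
      fs$fixations,
      tibble::tibble(threshold_px_s = fs$threshold$value,
                     threshold_method = fs$threshold$method)
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}
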