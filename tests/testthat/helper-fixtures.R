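# Shared fixtures and independent oracles for the test suite.

study_geometry <- function() screen_geometry(1280, 1024, 34.7, 25.9, 60)

# A gaze_trace from explicit cyclopean coordinates (both eyes identical).
trace_from_xy <- function(t, x, y, geometry = study_geometry(),
                          participant = "p1", stimulus = "s1", group = "g") {
  ok <- !is.na(x)
  gaze_trace(
    participant, group, stimulus,
    samples = tibble::tibble(
      t = t,
      left_x = x, left_y = y, right_x = x, right_y = y,
      left_valid = ok, right_valid = ok
    ),
    geometry = geometry
  )
}

# A cyclopean_trace built directly (bypassing fuse_eyes) for unit tests.
make_ct <- function(t, x, y, geometry = study_geometry(), id = "p1/s1") {
  ct <- tibble::tibble(t = t, x = x, y = y,
                       source = ifelse(is.na(x), "missing", "both_eyes"))
  attr(ct, "trace_id") <- id
  attr(ct, "participant_id") <- "p1"
  attr(ct, "group") <- "g"
  attr(ct, "stimulus_id") <- "s1"
  attr(ct, "geometry") <- geometry
  class(ct) <- c("cyclopean_trace", class(ct))
  ct
}

# A velocity_series built directly, for threshold tests.
make_vs <- function(v, id = "vs") {
  vs <- tibble::tibble(t = seq_along(v) * 4, v = v, i = seq_along(v))
  attr(vs, "trace_id") <- id
  class(vs) <- c("velocity_series", class(vs))
  vs
}

# A fixation_set built directly from a fixation tibble.
make_fixset <- function(fx, geometry = study_geometry(), participant = "p1",
                        stimulus = "s1", group = "g") {
  structure(list(
    trace_id = paste(participant, stimulus, sep = "/"),
    participant_id = participant, group = group, stimulus_id = stimulus,
    fixations = fx,
    threshold = structure(list(value = 1000, method = "fixed",
                               trace_id = "fixture"),
                          class = "velocity_threshold"),
    total_on_screen_duration = sum(fx$duration[
      is_on_screen(fx$x, fx$y, geometry)]),
    geometry = geometry
  ), class = "fixation_set")
}

fix_row <- function(x, y, onset, duration, n_samples = 10L) {
  tibble::tibble(x = x, y = y, onset = onset, offset = onset + duration,
                 duration = duration, n_samples = as.integer(n_samples),
                 merged_from = 1L)
}

# Planted-event scoring: a planted fixation is recovered when some detected
# fixation matches both its onset and offset within `tol_ms`.
count_recovered <- function(fs, truth, tol_ms) {
  ok <- 0L
  for (i in seq_len(nrow(truth))) {
    hit <- abs(fs$fixations$onset - truth$onset[i]) <= tol_ms &
      abs(fs$fixations$offset - truth$offset[i]) <= tol_ms
    if (any(hit)) ok <- ok + 1L
  }
  ok
}

# Independent KDE oracle: Gaussian KDE evaluated on the 1-px integer
# lattice, maximised by greedy 8-neighbour hill climbing from a start.
kde_value <- function(gx, gy, pts, h) {
  colSums(exp(-(outer(pts$x, gx, "-")^2 + outer(pts$y, gy, "-")^2) / (2 * h^2)))
}

grid_hill_climb <- function(x0, y0, pts, h, max_steps = 10000L) {
  cur <- c(round(x0), round(y0))
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  for (step in seq_len(max_steps)) {
    vals <- kde_value(cur[1L] + nb[, 1L], cur[2L] + nb[, 2L], pts, h)
    best <- which.max(vals)
    if (all(nb[best, ] == 0)) return(cur)
    cur <- cur + nb[best, ]
  }
  cur
}

# Exhaustive threshold-sweep oracle: best achievable fixation/saccade label
# agreement over all midpoint thresholds.
sweep_oracle_agreement <- function(v, planted_fast) {
  cand <- sort(v)
  cand <- (cand[-1L] + cand[-length(cand)]) / 2
  max(vapply(cand, function(th) mean((v > th) == planted_fast), numeric(1)))
}

demo_anchors <- function() {
  list(Face = c(640, 300), Target = c(1000, 700), Background = c(220, 850))
}
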