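#' Screen and stimulus geometry
#'
#' Describes the presentation screen: pixel raster, physical dimensions and
#' the participant's viewing distance. All gaze coordinates in the package
#' use this raster convention: origin at the top-left corner, x increasing
#' rightward, y increasing downward, units of pixels, 0-based, with the
#' half-open on-screen region `[0, raster_width) x [0, raster_height)`.
#'
#' @param raster_width,raster_height Screen raster size in pixels.
#' @param physical_width,physical_height Physical screen size in cm.
#' @param viewing_distance Eye-to-screen distance in cm.
#'
#' @return An object of class `screen_geometry`.
#'
#' @examples
#' geom <- screen_geometry(1280, 1024, 34.7, 25.9, 60)
#' pixels_per_degree(geom)
#' @export
screen_geometry <- function(raster_width, raster_height,
                            physical_width, physical_height,
                            viewing_distance) {
  fields <- list(
    raster_width = raster_width, raster_height = raster_height,
    physical_width = physical_width, physical_height = physical_height,
    viewing_distance = viewing_distance
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("screen_geometry: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  pitch_x <- physical_width / raster_width
  pitch_y <- physical_height / raster_height
  ratio <- pitch_x / pitch_y
  if (ratio > 2 || ratio < 0.5) {
    stop("screen_geometry: horizontal and vertical pixel pitch differ by ",
         "more than a factor of 2; check dimensions", call. = FALSE)
  }
  structure(fields, class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm (%.1f px/deg)\n",
    x$raster_width, x$raster_height, x$physical_width, x$physical_height,
    x$viewing_distance, pixels_per_degree(x)
  ))
  invisible(x)
}

#' Pixels per degree of visual angle
#'
#' Converts one degree of visual angle at screen centre into pixels, along
#' the horizontal or vertical raster axis:
#' `raster * viewing_distance * tan(1 deg) / physical`.
#'
#' @param geometry A [screen_geometry()].
#' @param axis `"horizontal"` (default), `"vertical"`, or `"mean"` of both.
#' @return Pixels per degree (scalar).
#' @export
pixels_per_degree <- function(geometry, axis = c("horizontal", "vertical", "mean")) {
  stopifnot(inherits(geometry, "screen_geometry"))
  axis <- match.arg(axis)
  tan1 <- tan(pi / 180)
  h <- geometry$raster_width * geometry$viewing_distance * tan1 / geometry$physical_width
  v <- geometry$raster_height * geometry$viewing_distance * tan1 / geometry$physical_height
  switch(axis, horizontal = h, vertical = v, mean = (h + v) / 2)
}

#' Trial window
#'
#' A time window (in ms, relative to the trace clock) delimiting the part of
#' a recording that belongs to one stimulus presentation.
#'
#' @param stimulus_id Stimulus identifier.
#' @param start,end Window bounds in ms; `end > start`. Samples with
#'   `start <= t < end` are inside the window.
#' @return An object of class `trial_window`.
#' @export
trial_window <- function(stimulus_id, start, end) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L)
  if (end <= start) stop("trial_window: end must be greater than start", call. = FALSE)
  structure(list(stimulus_id = as.character(stimulus_id),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "trial_window")
}

#' Restrict a gaze trace to a trial window
#'
#' Keeps samples with `window$start <= t < window$end` and re-zeroes
#' timestamps to the window start, so each trial segment gets its own clock.
#'
#' @param trace A [gaze_trace()].
#' @param window A [trial_window()].
#' @return A `gaze_trace` carrying the window's `stimulus_id`.
#' @export
clip_to_window <- function(trace, window) {
  stopifnot(inherits(trace, "gaze_trace"), inherits(window, "trial_window"))
  keep <- trace$samples$t >= window$start & trace$samples$t < window$end
  if (!any(keep)) {
    stop("clip_to_window: empty trial window for trace '", trace_id(trace),
         "'", call. = FALSE)
  }
  samples <- trace$samples[keep, , drop = FALSE]
  samples$t <- samples$t - window$start
  gaze_trace(
    participant_id = trace$participant_id, group = trace$group,
    stimulus_id = window$stimulus_id, samples = samples,
    nominal_rate = trace$nominal_rate, geometry = trace$geometry
  )
}

#' Test whether points are on screen
#'
#' @param x,y Coordinates in pixels.
#' @param geometry A [screen_geometry()].
#' @return Logical vector; `NA` coordinates give `FALSE`.
#' @export
is_on_screen <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  ok <- !is.na(x) & !is.na(y) &
    x >= 0 & x < geometry$raster_width &
    y >= 0 & y < geometry$raster_height
  ok
}
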