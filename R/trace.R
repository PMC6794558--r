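#' Binocular gaze trace
#'
#' A time-ordered binocular recording for one participant watching one
#' stimulus. Samples are stored as a tibble with columns `t` (ms since trial
#' start), `left_x`, `left_y`, `right_x`, `right_y` (pixels, `NA` when the
#' eye was not tracked) and logical `left_valid`, `right_valid`. A
#' coordinate is missing exactly when its validity flag is `FALSE`;
#' off-screen coordinates are retained (velocity estimation needs the full
#' kinematic record) and only excluded when metrics are computed.
#'
#' @param participant_id,group,stimulus_id Identifiers (coerced to character).
#' @param samples Tibble/data.frame with the columns described above.
#' @param nominal_rate Nominal sampling rate in Hz (> 0). Informational:
#'   all time arithmetic uses the actual timestamps.
#' @param geometry A [screen_geometry()].
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(participant_id, group = NA_character_, stimulus_id,
                       samples, nominal_rate = 250, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  samples <- tibble::as_tibble(samples)
  required <- c("t", "left_x", "left_y", "right_x", "right_y",
                "left_valid", "right_valid")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("gaze_trace: samples lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples <- samples[required]
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    stop("gaze_trace: nominal_rate must be > 0", call. = FALSE)
  }
  if (nrow(samples) > 1L && any(diff(samples$t) <= 0)) {
    stop("gaze_trace: non-monotonic timestamps in trace '",
         paste(participant_id, stimulus_id, sep = "/"), "'", call. = FALSE)
  }
  for (eye in c("left", "right")) {
    val <- samples[[paste0(eye, "_valid")]]
    cx <- samples[[paste0(eye, "_x")]]
    cy <- samples[[paste0(eye, "_y")]]
    if (!is.logical(val)) stop("gaze_trace: validity flags must be logical", call. = FALSE)
    bad <- (val & (is.na(cx) | is.na(cy))) | (!val & (!is.na(cx) | !is.na(cy)))
    if (any(bad)) {
      stop("gaze_trace: ", eye, "-eye coordinates must be missing exactly ",
           "when the validity flag is FALSE (sample ", which(bad)[1L], ")",
           call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         stimulus_id = as.character(stimulus_id),
         samples = samples,
         nominal_rate = as.numeric(nominal_rate),
         geometry = geometry),
    class = "gaze_trace"
  )
}

trace_id <- function(trace) {
  paste(trace$participant_id, trace$stimulus_id, sep = "/")
}

#' @export
print.gaze_trace <- function(x, ...) {
  n <- nrow(x$samples)
  span <- if (n) diff(range(x$samples$t)) else 0
  cat(sprintf(
    "<gaze_trace> %s  group=%s  stimulus=%s  %d samples over %.0f ms @ %g Hz nominal\n",
    x$participant_id, x$group, x$stimulus_id, n, span, x$nominal_rate
  ))
  invisible(x)
}
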