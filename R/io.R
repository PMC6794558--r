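#' Gaze-log dialect
#'
#' Declarative column mapping for delimited gaze-sample logs, so exports
#' from different trackers can be read without a vendor-specific parser.
#' The `columns` mapping gives, for each canonical field, the column name
#' used in the file.
#'
#' @param delim Field delimiter (default tab).
#' @param columns Named list mapping canonical fields (`participant`,
#'   `group`, `stimulus`, `time`, `l_x`, `l_y`, `r_x`, `r_y`, `l_valid`,
#'   `r_valid`) to file column names. `group` is optional.
#' @return An object of class `gaze_dialect`.
#' @export
gaze_dialect <- function(delim = "\t", columns = NULL) {
  default <- list(
    participant = "participant", group = "group", stimulus = "stimulus",
    time = "time", l_x = "l_x", l_y = "l_y", r_x = "r_x", r_y = "r_y",
    l_valid = "l_valid", r_valid = "r_valid"
  )
  if (!is.null(columns)) default[names(columns)] <- columns
  required <- setdiff(names(default), "group")
  if (any(vapply(default[required], is.null, logical(1)))) {
    stop("gaze_dialect: all column names except `group` are required", call. = FALSE)
  }
  structure(list(delim = delim, columns = default), class = "gaze_dialect")
}

#' Read a delimited gaze log
#'
#' Parses a delimited text log of raw binocular samples into one
#' [gaze_trace()] per participant x stimulus segment. Missing coordinates
#' stay missing (`NA`); they are never zero-filled.
#'
#' @param path Path to the log file.
#' @param geometry A [screen_geometry()] shared by all traces in the file.
#' @param dialect A [gaze_dialect()] describing delimiter and column names.
#' @param nominal_rate Nominal sampling rate recorded on each trace (Hz).
#' @return A named list of `gaze_trace` objects (`participant/stimulus`).
#' @export
read_gaze_log <- function(path, geometry, dialect = gaze_dialect(),
                          nominal_rate = 250) {
  stopifnot(inherits(geometry, "screen_geometry"),
            inherits(dialect, "gaze_dialect"))
  if (!file.exists(path)) stop("read_gaze_log: no such file: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", ""), progress = FALSE, show_col_types = FALSE
  )
  cols <- dialect$columns
  need <- unlist(cols[c("participant", "stimulus", "time", "l_x", "l_y",
                        "r_x", "r_y", "l_valid", "r_valid")])
  absent <- setdiff(need, names(raw))
  if (length(absent)) {
    stop("read_gaze_log: column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  num <- function(field) {
    x <- raw[[cols[[field]]]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("read_gaze_log: unparseable value '", x[bad[1L]], "' in column '",
           cols[[field]], "' at line ", bad[1L] + 1L, " of ", path,
           call. = FALSE)
    }
    out
  }
  lgl <- function(field) {
    x <- toupper(trimws(raw[[cols[[field]]]]))
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1")] <- TRUE
    out[x %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("read_gaze_log: unparseable validity flag '", raw[[cols[[field]]]][bad[1L]],
           "' at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
    }
    out
  }
  df <- tibble::tibble(
    participant = raw[[cols$participant]],
    group = if (!is.null(cols$group) && cols$group %in% names(raw))
      raw[[cols$group]] else NA_character_,
    stimulus = raw[[cols$stimulus]],
    t = num("time"),
    left_x = num("l_x"), left_y = num("l_y"),
    right_x = num("r_x"), right_y = num("r_y"),
    left_valid = lgl("l_valid"), right_valid = lgl("r_valid")
  )
  if (anyNA(df$t)) {
    stop("read_gaze_log: missing timestamp at line ",
         which(is.na(df$t))[1L] + 1L, " of ", path, call. = FALSE)
  }
  key <- paste(df$participant, df$stimulus, sep = "/")
  traces <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                   function(idx) {
    seg <- df[idx, , drop = FALSE]
    gaze_trace(
      participant_id = seg$participant[1L], group = seg$group[1L],
      stimulus_id = seg$stimulus[1L],
      samples = seg[c("t", "left_x", "left_y", "right_x", "right_y",
                      "left_valid", "right_valid")],
      nominal_rate = nominal_rate, geometry = geometry
    )
  })
  traces
}

#' Write gaze traces as a delimited log
#'
#' Inverse of [read_gaze_log()]: writes one row per sample in the dialect's
#' column naming. `read_gaze_log(write_gaze_log(x))` reproduces the samples
#' bit-exactly (doubles are serialized with round-trip precision).
#'
#' @param traces A `gaze_trace` or list of them.
#' @param path Output file path.
#' @param dialect A [gaze_dialect()].
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(traces, path, dialect = gaze_dialect()) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  cols <- dialect$columns
  rows <- lapply(traces, function(tr) {
    s <- tr$samples
    out <- tibble::tibble(
      tr$participant_id, tr$group, tr$stimulus_id, s$t,
      s$left_x, s$left_y, s$right_x, s$right_y, s$left_valid, s$right_valid
    )
    names(out) <- unlist(cols[c("participant", "group", "stimulus", "time",
                                "l_x", "l_y", "r_x", "r_y", "l_valid", "r_valid")])
    out
  })
  readr::write_delim(dplyr::bind_rows(rows), path, delim = dialect$delim, na = "NA")
  invisible(path)
}
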