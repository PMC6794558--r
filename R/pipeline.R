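#' Pipeline configuration
#'
#' Bundles everything one experiment run needs: screen geometry, log
#' dialect, detection and clustering parameters, per-stimulus label maps,
#' stimulus conditions, output directory and seed. Serializes to a single
#' human-editable YAML file ([write_pipeline_config()] /
#' [read_pipeline_config()]) that round-trips unchanged.
#'
#' @param geometry A [screen_geometry()].
#' @param dialect A [gaze_dialect()].
#' @param detection A [detection_config()].
#' @param clustering A [clustering_config()].
#' @param labels Named list: stimulus id -> named list (cell index ->
#'   label), as consumed by [label_cells()].
#' @param conditions Named character vector: stimulus id -> condition.
#' @param input Path to the gaze log (optional when traces are passed to
#'   [run_pipeline()] directly).
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry,
                            dialect = gaze_dialect(),
                            detection = detection_config(),
                            clustering = clustering_config(),
                            labels = list(),
                            conditions = NULL,
                            input = NULL,
                            out_dir = "gazeaoi_out",
                            seed = 1L) {
  stopifnot(inherits(geometry, "screen_geometry"),
            inherits(dialect, "gaze_dialect"),
            inherits(detection, "detection_config"),
            inherits(clustering, "clustering_config"))
  structure(list(geometry = geometry, dialect = dialect,
                 detection = detection, clustering = clustering,
                 labels = labels, conditions = conditions,
                 input = input, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    geometry = unclass(config$geometry),
    dialect = unclass(config$dialect),
    detection = unclass(config$detection),
    clustering = unclass(config$clustering),
    labels = config$labels,
    conditions = as.list(config$conditions),
    input = config$input,
    out_dir = config$out_dir,
    seed = config$seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  conditions <- if (length(raw$conditions)) {
    unlist(raw$conditions)
  } else NULL
  pipeline_config(
    geometry = do.call(screen_geometry, raw$geometry),
    dialect = gaze_dialect(raw$dialect$delim, raw$dialect$columns),
    detection = do.call(detection_config, raw$detection[
      !vapply(raw$detection, is.null, logical(1))]),
    clustering = do.call(clustering_config, raw$clustering[
      !vapply(raw$clustering, is.null, logical(1))]),
    labels = if (is.null(raw$labels)) list() else raw$labels,
    conditions = conditions,
    input = raw$input,
    out_dir = raw$out_dir,
    seed = raw$seed
  )
}

#' Run the full bottom-up AOI pipeline
#'
#' Orchestrates read -> detect -> cluster -> tessellate -> label -> RFD ->
#' overlays, writing every stage artifact plus a JSON manifest (file list,
#' config hash, package version) into `config$out_dir`. One structured log
#' line per stage reports counts (traces read, fixations kept, centroids
#' found, cells built) so silent data loss is visible. Reruns on identical
#' input produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param traces Optional list of [gaze_trace()] objects; when `NULL` the
#'   log at `config$input` is read with the config's dialect.
#' @param render_figures Write per-stimulus overlay PNGs (default TRUE).
#' @param quiet Suppress stage log lines on the console.
#' @return Invisibly, a list with the stage results (`fixsets`,
#'   `centroids`, `aois`, `rfd`) and the manifest.
#' @export
run_pipeline <- function(config, traces = NULL, render_figures = TRUE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  loglines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    loglines <<- c(loglines, line)
    if (!quiet) message(line)
  }
  files <- character()
  emit <- function(path) files <<- c(files, basename(path))

  # -- read ----------------------------------------------------------------
  if (is.null(traces)) {
    if (is.null(config$input)) {
      stop("run_pipeline [read]: no traces given and config$input is NULL",
           call. = FALSE)
    }
    traces <- read_gaze_log(config$input, config$geometry, config$dialect)
  }
  say("read", "%d traces", length(traces))

  # -- detect --------------------------------------------------------------
  fixsets <- lapply(traces, function(tr) {
    tryCatch(detect_fixations(tr, config$detection),
             error = function(e) {
               stop("run_pipeline [detect]: trace '", trace_id(tr), "': ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  fixation_path <- file.path(out_dir, "fixations.tsv")
  write_fixation_table(fixsets, fixation_path)
  emit(fixation_path)
  say("detect", "%d fixations across %d traces",
      sum(vapply(fixsets, function(f) nrow(f$fixations), integer(1))),
      length(fixsets))

  # -- cluster + tessellate + label + assign, per stimulus ----------------
  stimuli <- unique(vapply(fixsets, `[[`, character(1), "stimulus_id"))
  centroid_sets <- list()
  aois <- list()
  assigned <- list()
  for (stim in stimuli) {
    pool <- pool_fixations(fixsets, stimulus_id = stim)
    cs <- find_centroids(pool, config$clustering)
    centroid_sets[[stim]] <- cs
    cpath <- file.path(out_dir, paste0("centroids_", stim, ".tsv"))
    write_centroid_table(cs, cpath)
    emit(cpath)
    say("cluster", "stimulus %s: %d centroids from %d points (bandwidth %.1f px)",
        stim, nrow(cs$centroids), nrow(pool), cs$bandwidth)

    aoi <- build_voronoi(cs, config$geometry)
    aoi <- label_cells(aoi, config$labels[[stim]] %||% list())
    aois[[stim]] <- aoi
    apath <- file.path(out_dir, paste0("aoi_", stim, ".tsv"))
    write_aoi_table(aoi, apath)
    emit(apath)
    say("tessellate", "stimulus %s: %d cells, labels: %s", stim,
        length(aoi$cells),
        paste(unique(vapply(aoi$cells, `[[`, character(1), "label")),
              collapse = ", "))

    sel <- Filter(function(f) f$stimulus_id == stim, fixsets)
    assigned[[stim]] <- assign_fixations(sel, aoi)

    if (render_figures) {
      fpath <- file.path(out_dir, paste0("overlay_", stim, ".png"))
      render_overlays(aoi, cs, assigned[[stim]], path = fpath)
      emit(fpath)
    }
  }

  # -- rfd -----------------------------------------------------------------
  all_labels <- unique(unlist(lapply(aois, function(a) {
    vapply(a$cells, `[[`, character(1), "label")
  })))
  rfd <- compute_rfd(dplyr::bind_rows(assigned), all_labels,
                     condition = config$conditions)
  rfd_path <- file.path(out_dir, "rfd.tsv")
  export_long_table(rfd, rfd_path)
  emit(rfd_path)
  say("rfd", "%d records (%d participants, %d stimuli, %d labels)",
      nrow(rfd), length(unique(rfd$participant_id)), length(stimuli),
      length(all_labels))

  # -- manifest ------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  emit(cfg_path)
  writeLines(loglines, logfile)
  emit(logfile)
  manifest <- list(
    package = "gazeaoi",
    version = as.character(utils::packageVersion("gazeaoi")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    files = sort(unique(files))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fixsets = fixsets, centroids = centroid_sets, aois = aois,
                 rfd = rfd, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlay figure: cells, centroids and fixations for one stimulus
#'
#' Renders the AOI map the way the workflow is usually illustrated: the
#' screen rectangle, Voronoi cell boundaries (equidistance lines between
#' centroids), labeled centroids and the fixation scatter. Without a
#' background image a plain canvas is used.
#'
#' @param aoi An `aoi_map`.
#' @param centroids Optional `centroid_set` (defaults to the cell sites).
#' @param fixations Optional tibble from [assign_fixations()].
#' @param background Optional path to a raster background image (PNG); a
#'   missing file falls back to the plain canvas with a warning.
#' @param path Output file; when `NULL` the ggplot object is returned.
#' @return `path` (invisibly) or the ggplot object.
#' @export
render_overlays <- function(aoi, centroids = NULL, fixations = NULL,
                            background = NULL, path = NULL) {
  stopifnot(inherits(aoi, "aoi_map"))
  geom <- aoi$geometry
  polys <- dplyr::bind_rows(lapply(seq_along(aoi$cells), function(i) {
    one <- aoi$cells[[i]]
    tibble::tibble(cell = factor(i), label = one$label,
                   x = one$polygon[, 1L], y = one$polygon[, 2L])
  }))
  sites <- tibble::tibble(
    x = vapply(aoi$cells, function(c) c$centroid[[1L]], numeric(1)),
    y = vapply(aoi$cells, function(c) c$centroid[[2L]], numeric(1)),
    label = vapply(aoi$cells, `[[`, character(1), "label")
  )
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    if (file.exists(background)) {
      img <- png::readPNG(background)
      p <- p + ggplot2::annotation_raster(img, 0, geom$raster_width,
                                          -geom$raster_height, 0)
    } else {
      warning("render_overlays: background image not found; using plain canvas",
              call. = FALSE)
    }
  }
  p <- p +
    ggplot2::geom_polygon(
      data = polys, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                 fill = .data$label),
      alpha = 0.25, colour = "grey20", linewidth = 0.4
    )
  if (!is.null(fixations) && nrow(fixations)) {
    p <- p + ggplot2::geom_point(
      data = fixations, ggplot2::aes(.data$x, .data$y, size = .data$duration),
      alpha = 0.3, colour = "grey10", show.legend = FALSE
    ) + ggplot2::scale_size_area(max_size = 3)
  }
  p <- p +
    ggplot2::geom_point(data = sites, ggplot2::aes(.data$x, .data$y),
                        shape = 4, size = 3, stroke = 1.2, colour = "red") +
    ggplot2::geom_text(data = sites,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::scale_y_reverse(limits = c(geom$raster_height, 0),
                             expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, geom$raster_width),
                                expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("AOI map:", aoi$stimulus_id),
                  x = "x (px)", y = "y (px)", fill = "AOI") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7,
                  height = 7 * geom$raster_height / geom$raster_width + 0.8,
                  dpi = 96)
  invisible(path)
}
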