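#' Voronoi-cell areas of interest
#'
#' Partitions the screen rectangle into one convex cell per
#' fixation-density centroid. Each cell is the set of screen locations
#' closer to its centroid than to any other centroid; cell boundaries are
#' the perpendicular bisectors between centroid pairs. Cells are computed
#' by clipping the screen rectangle with the bisector half-planes
#' (Sutherland-Hodgman), so unbounded outer regions are automatically cut
#' to the raster and the cells exactly tile the screen.
#'
#' @param cs A `centroid_set` from [mean_shift()], or a two-column
#'   matrix/data frame of centroid coordinates (px).
#' @param geometry A [screen_geometry()]; all centroids must lie on screen.
#' @return An `aoi_map`: the `stimulus_id`, the geometry, and `cells` — a
#'   list with one entry per centroid carrying `centroid` (x, y), `polygon`
#'   (matrix of vertices, counter-clockwise in raster coordinates), `area`
#'   (px^2) and `label` (initially `"unlabeled"`).
#' @export
build_voronoi <- function(cs, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (inherits(cs, "centroid_set")) {
    sites <- as.matrix(cs$centroids[, c("x", "y")])
    stimulus_id <- cs$stimulus_id
  } else {
    sites <- as.matrix(as.data.frame(cs))[, 1:2, drop = FALSE]
    colnames(sites) <- c("x", "y")
    stimulus_id <- NA_character_
  }
  n <- nrow(sites)
  if (n < 1L) stop("build_voronoi: need at least one centroid", call. = FALSE)
  if (!all(is_on_screen(sites[, 1L], sites[, 2L], geometry))) {
    stop("build_voronoi: all centroids must lie inside the screen rectangle",
         call. = FALSE)
  }
  if (n > 1L) {
    d <- as.matrix(stats::dist(sites))
    diag(d) <- Inf
    if (min(d) == 0) stop("build_voronoi: degenerate sites (duplicate centroids)", call. = FALSE)
  }
  W <- geometry$raster_width
  H <- geometry$raster_height
  rect <- cbind(x = c(0, W, W, 0), y = c(0, 0, H, H))
  cells <- lapply(seq_len(n), function(i) {
    poly <- rect
    for (j in seq_len(n)[-i]) {
      m <- (sites[i, ] + sites[j, ]) / 2
      d <- sites[j, ] - sites[i, ]
      # keep the half-plane (p - m) . d <= 0 (closer to site i)
      poly <- clip_halfplane(poly, m, d)
      if (nrow(poly) < 3L) break
    }
    list(centroid = sites[i, ], polygon = poly,
         area = polygon_area(poly), label = "unlabeled")
  })
  structure(list(stimulus_id = stimulus_id, cells = cells, geometry = geometry),
            class = "aoi_map")
}

# Sutherland-Hodgman clip of a convex polygon against (p - m) . d <= 0.
clip_halfplane <- function(poly, m, d) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  s <- (poly[, 1L] - m[1L]) * d[1L] + (poly[, 2L] - m[2L]) * d[2L]
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    inside_i <- s[i] <= 0
    inside_j <- s[j] <= 0
    if (inside_i) out <- rbind(out, poly[i, ])
    if (xor(inside_i, inside_j)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  colnames(out) <- c("x", "y")
  out
}

# Shoelace area (positive for the raster-coordinate winding used here).
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' @export
print.aoi_map <- function(x, ...) {
  labs <- vapply(x$cells, `[[`, character(1), "label")
  cat(sprintf("<aoi_map> stimulus=%s: %d cells (%s)\n", x$stimulus_id,
              length(x$cells), paste(unique(labs), collapse = ", ")))
  invisible(x)
}

#' Attach semantic labels to AOI cells
#'
#' Cell naming is a manual, auditable step: the analyst inspects the cells
#' over the stimulus and assigns semantic names (e.g. `"Face"`,
#' `"Target"`). Cells left unnamed default to `"Background"` — background
#' is thus defined by the data density, not by a drawn region. Several
#' cells may share one label; downstream RFD pools them.
#'
#' @param aoi An `aoi_map`.
#' @param labels Named list or vector, `cell index -> label`. Indices are
#'   1-based. An empty map labels every cell `"Background"`.
#' @return The `aoi_map` with labels set (geometry untouched).
#' @export
label_cells <- function(aoi, labels = list()) {
  stopifnot(inherits(aoi, "aoi_map"))
  n <- length(aoi$cells)
  for (i in seq_len(n)) aoi$cells[[i]]$label <- "Background"
  if (length(labels)) {
    idx <- as.integer(names(labels))
    if (anyNA(idx) || any(idx < 1L | idx > n)) {
      stop("label_cells: unknown cell index in label map", call. = FALSE)
    }
    for (k in seq_along(labels)) {
      aoi$cells[[idx[k]]]$label <- as.character(labels[[k]])
    }
  }
  aoi
}

#' Cell index containing each point
#'
#' Assigns points to cells by nearest centroid (which coincides with
#' polygon containment for a Voronoi partition); ties on a boundary break
#' deterministically to the lowest centroid index.
#'
#' @param x,y Point coordinates (px).
#' @param aoi An `aoi_map`.
#' @return Integer vector of 1-based cell indices (`NA` for `NA` input).
#' @export
nearest_cell <- function(x, y, aoi) {
  stopifnot(inherits(aoi, "aoi_map"))
  sites <- t(vapply(aoi$cells, `[[`, numeric(2), "centroid"))
  d2 <- outer(x, sites[, 1L], function(a, b) (a - b)^2) +
    outer(y, sites[, 2L], function(a, b) (a - b)^2)
  apply(d2, 1L, function(r) if (anyNA(r)) NA_integer_ else which.min(r))
}

#' Point-in-cell test by polygon containment
#'
#' Independent of [nearest_cell()]: tests each point against each cell's
#' convex polygon (all-edges-inside test with boundary tolerance), breaking
#' boundary ties to the lowest cell index.
#'
#' @param x,y Point coordinates (px).
#' @param aoi An `aoi_map`.
#' @param tol Boundary tolerance (px).
#' @return Integer vector of 1-based cell indices.
#' @export
cell_containing <- function(x, y, aoi, tol = 1e-9) {
  stopifnot(inherits(aoi, "aoi_map"))
  n <- length(x)
  out <- rep(NA_integer_, n)
  for (ci in seq_along(aoi$cells)) {
    poly <- aoi$cells[[ci]]$polygon
    inside <- point_in_convex(x, y, poly, tol)
    out[is.na(out) & inside] <- ci
  }
  out
}

# Vectorized convex containment: point is inside iff on the inner side of
# every directed edge (consistent winding), within tolerance.
point_in_convex <- function(x, y, poly, tol = 1e-9) {
  m <- nrow(poly)
  if (m < 3L) return(rep(FALSE, length(x)))
  jx <- c(2:m, 1L)
  ex <- poly[jx, 1L] - poly[, 1L]
  ey <- poly[jx, 2L] - poly[, 2L]
  # determine winding from signed area
  xx <- poly[, 1L]; yy <- poly[, 2L]
  sgn <- sign(sum(xx * yy[jx] - xx[jx] * yy))
  inside <- rep(TRUE, length(x))
  for (e in seq_len(m)) {
    cross <- ex[e] * (y - poly[e, 2L]) - ey[e] * (x - poly[e, 1L])
    inside <- inside & (sgn * cross >= -tol)
  }
  inside
}

#' Build a label map from named anchor points
#'
#' Convenience for constructing the `cell index -> label` map that
#' [label_cells()] consumes: each centroid takes the label of the nearest
#' anchor within `max_dist`; centroids with no anchor nearby are left out
#' of the map (and so default to `"Background"`). The anchor list is an
#' explicit, auditable input — typically the semantic landmarks of the
#' stimulus (face, target) located once by the experimenter.
#'
#' @param cs A `centroid_set`.
#' @param anchors Named list: label -> `c(x, y)` in px.
#' @param max_dist Maximum centroid-to-anchor distance (px).
#' @return Named list suitable for [label_cells()].
#' @export
anchor_label_map <- function(cs, anchors, max_dist = 150) {
  stopifnot(inherits(cs, "centroid_set"), length(anchors) >= 1L,
            !is.null(names(anchors)))
  out <- list()
  for (i in seq_len(nrow(cs$centroids))) {
    d <- vapply(anchors, function(a) {
      sqrt((cs$centroids$x[i] - a[[1L]])^2 + (cs$centroids$y[i] - a[[2L]])^2)
    }, numeric(1))
    if (min(d) <= max_dist) out[[as.character(i)]] <- names(anchors)[which.min(d)]
  }
  out
}

#' Assign fixations to labeled AOI cells
#'
#' Maps each fixation to the cell containing its centroid; off-screen
#' fixations get the label `"off_screen"`. Nearest-centroid and
#' polygon-containment assignment agree by construction (Voronoi duality);
#' [cell_containing()] is available as an independent cross-check.
#'
#' @param fs A `fixation_set` or list of them.
#' @param aoi An `aoi_map` (same geometry).
#' @return A tibble: identifiers, fixation coordinates and durations,
#'   `cell` (index, `NA` off screen) and `aoi_label`.
#' @export
assign_fixations <- function(fs, aoi) {
  stopifnot(inherits(aoi, "aoi_map"))
  if (inherits(fs, "fixation_set")) fs <- list(fs)
  labs <- vapply(aoi$cells, `[[`, character(1), "label")
  rows <- lapply(fs, function(one) {
    fx <- one$fixations
    if (!nrow(fx)) return(NULL)
    on <- is_on_screen(fx$x, fx$y, one$geometry)
    cell <- rep(NA_integer_, nrow(fx))
    if (any(on)) cell[on] <- nearest_cell(fx$x[on], fx$y[on], aoi)
    tibble::tibble(
      participant_id = one$participant_id, group = one$group,
      stimulus_id = one$stimulus_id,
      x = fx$x, y = fx$y, onset = fx$onset, duration = fx$duration,
      cell = cell,
      aoi_label = ifelse(on, labs[ifelse(is.na(cell), 1L, cell)], "off_screen")
    )
  })
  dplyr::bind_rows(rows)
}

#' Export an AOI map as a delimited polygon table
#'
#' One row per polygon vertex: stimulus, cell index, label, centroid and
#' vertex coordinates.
#'
#' @param aoi An `aoi_map`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_aoi_table <- function(aoi, path) {
  rows <- lapply(seq_along(aoi$cells), function(i) {
    one <- aoi$cells[[i]]
    tibble::tibble(
      stimulus = aoi$stimulus_id, cell = i, label = one$label,
      centroid_x = one$centroid[1L], centroid_y = one$centroid[2L],
      area_px2 = one$area,
      vertex = seq_len(nrow(one$polygon)),
      vx = one$polygon[, 1L], vy = one$polygon[, 2L]
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}
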