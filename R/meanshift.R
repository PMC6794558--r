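#' Clustering configuration
#'
#' @param fixed_bandwidth Optional bandwidth override in px; `NULL` selects
#'   it from the data ([select_bandwidth()]).
#' @param weight_by_duration Weight fixation points by their duration when
#'   estimating the density. Off by default: each fixation counts once.
#' @param min_cluster_size Centroids supported by fewer points are pruned
#'   (their points reassigned to the nearest surviving centroid). Default 1
#'   = no pruning, to avoid silent data loss.
#' @param bandwidth_factor Multiplier on the normal-reference scale in
#'   [select_bandwidth()]; > 1 oversmooths slightly, which stabilises mode
#'   seeking against spurious sample-level density wiggles.
#' @param max_bandwidth Upper cap on the selected bandwidth (px). Pooled
#'   fixations from several well-separated areas of interest inflate the
#'   global dispersion far beyond the within-area scale; the cap (default
#'   60 px, about 1.5 degrees on a typical screen setup) keeps the kernel
#'   at the spatial scale of a single AOI.
#' @param tol Convergence tolerance of the mean-shift iteration (px).
#' @param max_iter Iteration cap per point.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(fixed_bandwidth = NULL,
                              weight_by_duration = FALSE,
                              min_cluster_size = 1,
                              bandwidth_factor = 2,
                              max_bandwidth = 60,
                              tol = 1e-3, max_iter = 500) {
  stopifnot(is.null(fixed_bandwidth) || fixed_bandwidth > 0,
            min_cluster_size >= 1, bandwidth_factor > 0, max_bandwidth > 0,
            tol > 0, max_iter >= 1)
  structure(list(fixed_bandwidth = fixed_bandwidth,
                 weight_by_duration = isTRUE(weight_by_duration),
                 min_cluster_size = min_cluster_size,
                 bandwidth_factor = bandwidth_factor,
                 max_bandwidth = max_bandwidth,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "clustering_config")
}

#' Pool fixations across participants into weighted points
#'
#' Flattens a list of fixation sets for one stimulus into fixation points
#' (x, y, weight = duration, identifiers), keeping only on-screen
#' fixations. The default scope pools all groups together, which is the
#' shared-AOI workflow: one centroid/AOI map per stimulus, derived from
#' every participant's fixations independently of group.
#'
#' @param fixsets List of `fixation_set` objects sharing one geometry.
#' @param stimulus_id Keep only sets for this stimulus (`NULL` = all).
#' @param scope `"all_groups"` (one pool) or `"per_group"` (named list of
#'   pools, one per group).
#' @return A tibble of fixation points, or a named list of tibbles when
#'   `scope = "per_group"`.
#' @export
pool_fixations <- function(fixsets, stimulus_id = NULL,
                           scope = c("all_groups", "per_group")) {
  scope <- match.arg(scope)
  if (inherits(fixsets, "fixation_set")) fixsets <- list(fixsets)
  if (!is.null(stimulus_id)) {
    fixsets <- Filter(function(fs) fs$stimulus_id == stimulus_id, fixsets)
  }
  rows <- lapply(fixsets, function(fs) {
    fx <- fs$fixations
    if (!nrow(fx)) return(NULL)
    on <- is_on_screen(fx$x, fx$y, fs$geometry)
    fx <- fx[on, , drop = FALSE]
    if (!nrow(fx)) return(NULL)
    tibble::tibble(x = fx$x, y = fx$y, weight = fx$duration,
                   participant_id = fs$participant_id, group = fs$group,
                   stimulus_id = fs$stimulus_id)
  })
  pool <- dplyr::bind_rows(rows)
  if (!nrow(pool)) stop("pool_fixations: empty fixation pool", call. = FALSE)
  if (scope == "per_group") {
    return(split(pool, pool$group))
  }
  pool
}

#' Rule-of-thumb kernel bandwidth
#'
#' Normal-reference bandwidth on the pooled x and y deviations:
#' `factor * sigma_hat * n^(-1/6)` with `sigma_hat` the root mean of the
#' two marginal variances (the standard bivariate rule-of-thumb scale for
#' a Gaussian kernel), capped at `config$max_bandwidth` so multi-area
#' pools are not oversmoothed by their between-area spread.
#' `config$fixed_bandwidth` overrides the estimate entirely.
#'
#' @param points Tibble with `x`, `y` columns (e.g. [pool_fixations()]).
#' @param config A [clustering_config()].
#' @return Bandwidth in px.
#' @export
select_bandwidth <- function(points, config = clustering_config()) {
  if (!is.null(config$fixed_bandwidth)) return(config$fixed_bandwidth)
  if (nrow(points) < 2L) stop("select_bandwidth: need at least 2 points", call. = FALSE)
  s <- sqrt((stats::var(points$x) + stats::var(points$y)) / 2)
  if (s == 0) stop("select_bandwidth: zero dispersion (all points identical)", call. = FALSE)
  min(config$bandwidth_factor * s * nrow(points)^(-1 / 6), config$max_bandwidth)
}

#' Mean-shift fixation-density centroids
#'
#' Gaussian-kernel mean shift: every fixation point is iterated uphill
#' under the kernel-weighted local mean until the step is below
#' `config$tol` or `config$max_iter` is reached, so each point converges on
#' a mode (density peak) of the fixation distribution. Converged locations
#' closer than `bandwidth / 2` are merged into one centroid, and each input
#' point is assigned to the centroid its trajectory reached. The procedure
#' is deterministic and invariant to the order of the input points
#' (centroids are reported in reading order: y, then x).
#'
#' @param points Tibble with `x`, `y` (px) and optionally `weight` (ms).
#' @param bandwidth Gaussian kernel bandwidth in px ([select_bandwidth()]).
#' @param config A [clustering_config()].
#' @param stimulus_id Optional stimulus identifier stored on the result.
#' @return A `centroid_set`: tibble `centroids` (`x`, `y`, `n_assigned`),
#'   integer `assignments` (one per input point), `bandwidth`, and
#'   per-point `iterations`.
#' @export
mean_shift <- function(points, bandwidth, config = clustering_config(),
                       stimulus_id = NULL) {
  stopifnot(nrow(points) >= 1L, bandwidth > 0)
  X <- cbind(points$x, points$y)
  w <- if (config$weight_by_duration && "weight" %in% names(points)) {
    points$weight
  } else {
    rep(1, nrow(X))
  }
  n <- nrow(X)
  Y <- X
  active <- rep(TRUE, n)
  iters <- integer(n)
  h2 <- 2 * bandwidth^2
  it <- 0L
  while (any(active) && it < config$max_iter) {
    it <- it + 1L
    idx <- which(active)
    # squared distances from active walkers to all data points
    d2 <- outer(rowSums(Y[idx, , drop = FALSE]^2), rowSums(X^2), "+") -
      2 * Y[idx, , drop = FALSE] %*% t(X)
    K <- exp(-d2 / h2) * rep(w, each = length(idx))
    denom <- rowSums(K)
    newY <- (K %*% X) / denom
    step <- sqrt(rowSums((newY - Y[idx, , drop = FALSE])^2))
    Y[idx, ] <- newY
    iters[idx] <- it
    active[idx] <- step >= config$tol
  }
  if (any(active)) {
    warning("mean_shift: ", sum(active), " point(s) did not converge in ",
            config$max_iter, " iterations; assigned to nearest mode",
            call. = FALSE)
  }
  # merge converged locations within bandwidth/2 (connected components)
  comp <- merge_modes(Y, bandwidth / 2)
  k <- max(comp)
  cx <- vapply(seq_len(k), function(j) mean(Y[comp == j, 1L]), numeric(1))
  cy <- vapply(seq_len(k), function(j) mean(Y[comp == j, 2L]), numeric(1))
  # prune small clusters if requested
  sizes <- tabulate(comp, k)
  keep <- which(sizes >= config$min_cluster_size)
  if (!length(keep)) keep <- which.max(sizes)
  if (length(keep) < k) {
    d2c <- outer(points$x, cx[keep], function(a, b) (a - b)^2) +
      outer(points$y, cy[keep], function(a, b) (a - b)^2)
    comp <- keep[apply(d2c, 1L, which.min)]
    cx <- cx[keep]; cy <- cy[keep]
    relab <- match(comp, keep)
    comp <- relab
    k <- length(keep)
  }
  # canonical centroid order: reading order (y, then x) for order invariance
  ord <- order(cy, cx)
  rank <- match(seq_len(k), ord)
  assignments <- rank[comp]
  centroids <- tibble::tibble(
    x = cx[ord], y = cy[ord],
    n_assigned = tabulate(assignments, k)
  )
  structure(list(
    stimulus_id = if (is.null(stimulus_id)) {
      if ("stimulus_id" %in% names(points)) points$stimulus_id[1L] else NA_character_
    } else stimulus_id,
    centroids = centroids,
    assignments = assignments,
    bandwidth = bandwidth,
    iterations = iters
  ), class = "centroid_set")
}

# Connected components of points under a distance threshold.
merge_modes <- function(Y, radius) {
  n <- nrow(Y)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      d <- sqrt((Y[, 1L] - Y[j, 1L])^2 + (Y[, 2L] - Y[j, 2L])^2)
      nb <- which(d <= radius & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set> stimulus=%s: %d centroids from %d points (bandwidth %.1f px)\n",
              x$stimulus_id, nrow(x$centroids), length(x$assignments), x$bandwidth))
  invisible(x)
}

#' Find fixation-density centroids for a pool of fixations
#'
#' Convenience wrapper: [select_bandwidth()] then [mean_shift()].
#'
#' @param points Tibble from [pool_fixations()].
#' @param config A [clustering_config()].
#' @return A `centroid_set`.
#' @export
find_centroids <- function(points, config = clustering_config()) {
  mean_shift(points, select_bandwidth(points, config), config)
}

#' Write a centroid set as a delimited table
#'
#' @param cs A `centroid_set`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_centroid_table <- function(cs, path) {
  tab <- dplyr::bind_cols(
    tibble::tibble(stimulus = cs$stimulus_id,
                   centroid = seq_len(nrow(cs$centroids))),
    cs$centroids
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
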