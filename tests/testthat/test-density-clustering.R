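test_that("select_bandwidth follows the capped normal-reference rule", {
  set.seed(3)
  pts <- tibble::tibble(x = rnorm(500, 400, 20), y = rnorm(500, 300, 20))
  bw <- select_bandwidth(pts)
  expect_gt(bw, 5)
  expect_lt(bw, 40)
  # override wins regardless of data
  expect_equal(select_bandwidth(pts, clustering_config(fixed_bandwidth = 50)), 50)
  # scale equivariance below the cap
  pts2 <- tibble::tibble(x = 2 * pts$x, y = 2 * pts$y)
  expect_equal(select_bandwidth(pts2), 2 * bw)
  # degenerate input
  same <- tibble::tibble(x = rep(5, 10), y = rep(7, 10))
  expect_error(select_bandwidth(same), "zero dispersion")
})

test_that("mean_shift finds the mode of a single Gaussian blob", {
  set.seed(11)
  pts <- tibble::tibble(x = rnorm(200, 400, 20), y = rnorm(200, 300, 20))
  cs <- mean_shift(pts, select_bandwidth(pts))
  expect_equal(nrow(cs$centroids), 1)
  expect_lt(sqrt((cs$centroids$x - mean(pts$x))^2 +
                 (cs$centroids$y - mean(pts$y))^2), 5)
  expect_length(cs$assignments, 200)
  expect_true(all(cs$assignments == 1))
})

test_that("mean_shift separates two planted blobs without cross-assignment", {
  set.seed(12)
  pts <- tibble::tibble(
    x = c(rnorm(200, 200, 20), rnorm(200, 1000, 20)),
    y = c(rnorm(200, 200, 20), rnorm(200, 800, 20))
  )
  cs <- mean_shift(pts, select_bandwidth(pts))
  expect_equal(nrow(cs$centroids), 2)
  # centroid order is canonical (y then x): blob at (200,200) first
  expect_lt(sqrt((cs$centroids$x[1] - mean(pts$x[1:200]))^2 +
                 (cs$centroids$y[1] - mean(pts$y[1:200]))^2), 5)
  expect_lt(sqrt((cs$centroids$x[2] - mean(pts$x[201:400]))^2 +
                 (cs$centroids$y[2] - mean(pts$y[201:400]))^2), 5)
  expect_true(all(cs$assignments[1:200] == 1))
  expect_true(all(cs$assignments[201:400] == 2))
})

test_that("a single point is its own centroid", {
  cs <- mean_shift(tibble::tibble(x = 123, y = 456), bandwidth = 30)
  expect_equal(nrow(cs$centroids), 1)
  expect_equal(cs$centroids$x, 123)
  expect_equal(cs$centroids$y, 456)
  expect_equal(cs$assignments, 1L)
})

test_that("permuting point order changes neither centroids nor assignments", {
  set.seed(13)
  pts <- tibble::tibble(
    x = c(rnorm(120, 300, 25), rnorm(80, 900, 25)),
    y = c(rnorm(120, 700, 25), rnorm(80, 250, 25))
  )
  bw <- select_bandwidth(pts)
  cs1 <- mean_shift(pts, bw)
  perm <- sample(nrow(pts))
  cs2 <- mean_shift(pts[perm, ], bw)
  expect_equal(cs2$centroids$x, cs1$centroids$x, tolerance = 1e-9)
  expect_equal(cs2$centroids$y, cs1$centroids$y, tolerance = 1e-9)
  expect_equal(cs2$assignments, cs1$assignments[perm])
})

test_that("every point gets exactly one assignment (conservation)", {
  set.seed(14)
  for (k in 1:5) {
    n <- sample(30:150, 1)
    pts <- tibble::tibble(x = runif(n, 0, 1280), y = runif(n, 0, 1024))
    cs <- suppressWarnings(mean_shift(pts, 40))
    expect_length(cs$assignments, n)
    expect_true(all(cs$assignments >= 1 & cs$assignments <= nrow(cs$centroids)))
    expect_equal(sum(cs$centroids$n_assigned), n)
  }
})

test_that("pool_fixations flattens, filters off-screen, respects scope", {
  geom <- study_geometry()
  mk <- function(p, g, n, stim = "s1") {
    fx <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      fix_row(runif(1, 10, 1270), runif(1, 10, 1014),
              onset = i * 300, duration = 100)
    }))
    make_fixset(fx, geom, participant = p, group = g, stimulus = stim)
  }
  set.seed(15)
  sets <- list(mk("p1", "asd", 4), mk("p2", "td", 5), mk("p3", "tc", 6))
  pool <- pool_fixations(sets, "s1")
  expect_equal(nrow(pool), 15)
  # an off-screen fixation is excluded
  off <- sets
  off[[1]]$fixations$x[1] <- -30
  expect_equal(nrow(pool_fixations(off, "s1")), 14)
  # per-group pools partition the all-groups pool
  by_group <- pool_fixations(sets, "s1", scope = "per_group")
  expect_setequal(names(by_group), c("asd", "td", "tc"))
  expect_equal(sum(vapply(by_group, nrow, integer(1))), 15)
  # empty pool errors
  expect_error(pool_fixations(sets, "nope"), "empty")
})

test_that("fixation-plan hotspots are recovered by the full detection + clustering chain", {
  geom <- study_geometry()
  set.seed(16)
  hot <- cbind(x = c(320, 960), y = c(700, 260))
  sets <- list()
  for (p in 1:6) {
    idx <- rep(1:2, length.out = 6)
    if (p %% 2 == 0) idx <- rev(idx)
    plan <- tibble::tibble(
      x = hot[idx, 1] + rnorm(6, 0, 15),
      y = hot[idx, 2] + rnorm(6, 0, 15),
      duration = runif(6, 150, 400)
    )
    out <- generate_trace(scanpath_spec(plan, seed = 900 + p), geom,
                          participant_id = paste0("p", p))
    sets[[p]] <- detect_fixations(out$trace)
  }
  pool <- pool_fixations(sets, "stim")
  cs <- find_centroids(pool)
  expect_equal(nrow(cs$centroids), 2)
  for (i in 1:2) {
    d <- sqrt((cs$centroids$x - hot[i, 1])^2 + (cs$centroids$y - hot[i, 2])^2)
    expect_lt(min(d), cs$bandwidth / 2)
  }
})
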