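test_that("fuse_eyes averages, substitutes across eyes, never fabricates", {
  geom <- study_geometry()
  s <- tibble::tibble(
    t = c(0, 4, 8),
    left_x = c(100, NA, NA), left_y = c(100, NA, NA),
    right_x = c(104, 250, NA), right_y = c(104, 300, NA),
    left_valid = c(TRUE, FALSE, FALSE), right_valid = c(TRUE, TRUE, FALSE)
  )
  ct <- fuse_eyes(gaze_trace("p", "g", "s", s, geometry = geom))
  expect_equal(ct$x, c(102, 250, NA))
  expect_equal(ct$y, c(102, 300, NA))
  expect_equal(ct$source, c("both_eyes", "right_only", "missing"))
})

test_that("compute_velocity is Euclidean distance over elapsed time", {
  # 3-4-5 triangle over 4 ms -> 5 px / 0.004 s
  ct <- make_ct(c(0, 4), c(100, 103), c(100, 104))
  vs <- compute_velocity(ct)
  expect_equal(vs$v, 1250)
  # constant position -> zero velocity
  ct0 <- make_ct(seq(0, 40, 4), rep(5, 11), rep(5, 11))
  expect_true(all(compute_velocity(ct0)$v == 0))
  # a missing middle sample removes both adjacent pairs
  ctg <- make_ct(seq(0, 16, 4), c(1, 2, NA, 4, 5), c(1, 2, NA, 4, 5))
  expect_equal(nrow(compute_velocity(ctg)), 2)
  expect_error(compute_velocity(make_ct(0, 1, 1)), "insufficient data")
})

test_that("adaptive threshold separates planted two-mode mixtures", {
  set.seed(31)
  lab <- rep(c(FALSE, TRUE), each = 200)
  v <- 10^(ifelse(lab, rnorm(400, log10(6000), 0.18), rnorm(400, log10(120), 0.18)))
  thr <- estimate_threshold(make_vs(v))
  expect_equal(thr$method, "adaptive_bimodal")
  expect_gte(mean((v > thr$value) == lab), 0.99)
})

test_that("degenerate velocity series fall back to a robust threshold", {
  expect_warning(thr <- estimate_threshold(make_vs(rep(10, 50))), "degenerate")
  expect_equal(thr$method, "fallback_robust")
  expect_gt(thr$value, 10)
})

test_that("thresholds adapt per trace to the speed of the fast mode", {
  mk <- function(fast, seed) {
    set.seed(seed)
    make_vs(10^(c(rnorm(300, log10(100), 0.15), rnorm(100, log10(fast), 0.15))))
  }
  t1 <- estimate_threshold(mk(3000, 1))
  t2 <- estimate_threshold(mk(15000, 2))
  expect_gt(t2$value, t1$value)
})

test_that("classification recovers simple planted structures", {
  geom <- study_geometry()
  cfg <- detection_config()
  # 1 s constant-position noiseless trace -> one ~1000 ms fixation
  sp <- scanpath_spec(tibble::tibble(x = 640, y = 512, duration = 1000),
                      noise_sd = 0, missing_rate = 0, seed = 5)
  out <- generate_trace(sp, geom)
  fs <- suppressWarnings(detect_fixations(out$trace, cfg))
  expect_equal(nrow(fs$fixations), 1)
  expect_equal(fs$fixations$duration, 1000, tolerance = 0.01)
  # two 300 ms dwells joined by a 40 ms sweep -> exactly 2 fixations
  sp2 <- scanpath_spec(tibble::tibble(x = c(300, 900), y = c(300, 700),
                                      duration = c(300, 300)),
                       saccade_ms = c(40, 40), noise_sd = 0.1,
                       missing_rate = 0, seed = 6)
  out2 <- generate_trace(sp2, geom)
  fs2 <- detect_fixations(out2$trace, cfg)
  expect_equal(nrow(fs2$fixations), 2)
  expect_equal(count_recovered(fs2, out2$truth, tol_ms = 8), 2)
})

test_that("sub-minimum candidate fixations are discarded as noise", {
  # 20 ms sub-threshold blip amid fast motion, min_fixation_ms = 60
  x <- c(seq(0, 200, by = 20), rep(210, 6), seq(220, 400, by = 20))
  t <- seq_along(x) * 4
  ct <- make_ct(t, x, rep(500, length(x)))
  thr <- structure(list(value = 500, method = "fixed", trace_id = "t"),
                   class = "velocity_threshold")
  fs <- classify_events(ct, thr, detection_config(min_fixation_ms = 60,
                                                  smooth_window = 1,
                                                  refine_edges = FALSE))
  expect_equal(nrow(fs$fixations), 0)
})

test_that("merge_fixations merges near successors, is idempotent, keeps far apart", {
  geom <- study_geometry()
  cfg <- detection_config()
  fs <- make_fixset(dplyr::bind_rows(
    fix_row(400, 300, onset = 0, duration = 200),
    fix_row(403, 301, onset = 220, duration = 150)
  ), geom)
  m <- merge_fixations(fs, cfg)
  expect_equal(nrow(m$fixations), 1)
  expect_equal(m$fixations$onset, 0)
  expect_equal(m$fixations$offset, 370)
  expect_equal(m$fixations$merged_from, 2L)
  # duration-weighted centroid
  expect_equal(m$fixations$x, (400 * 200 + 403 * 150) / 350)

  # far-apart fixations stay separate regardless of gap
  fs2 <- make_fixset(dplyr::bind_rows(
    fix_row(100, 100, onset = 0, duration = 200),
    fix_row(400, 100, onset = 205, duration = 200)
  ), geom)
  expect_equal(nrow(merge_fixations(fs2, cfg)$fixations), 2)

  # idempotence on random fixation sets
  set.seed(12)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    onsets <- cumsum(runif(n, 10, 300))
    fx <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      fix_row(runif(1, 0, 1280), runif(1, 0, 1024), onsets[i],
              duration = runif(1, 60, 200))
    }))
    # enforce non-overlap
    fx <- fx[order(fx$onset), ]
    once <- merge_fixations(make_fixset(fx, geom), cfg)
    twice <- merge_fixations(once, cfg)
    expect_equal(twice$fixations, once$fixations)
  }
})

test_that("every sample is fixation member, saccade, or missing (partition)", {
  geom <- study_geometry()
  plan <- random_fixation_plan(6, geom, seed = 71)
  out <- generate_trace(scanpath_spec(plan, seed = 72), geom)
  raw <- fuse_eyes(out$trace)
  cfg <- detection_config()
  ct <- smooth_positions(raw, cfg$smooth_window)
  thr <- estimate_threshold(compute_velocity(ct), cfg)
  fs <- classify_events(ct, thr, cfg, raw = raw)
  n <- nrow(raw)
  in_fix <- rep(FALSE, n)
  for (i in seq_len(nrow(fs$fixations))) {
    sel <- raw$t >= fs$fixations$onset[i] & raw$t <= fs$fixations$offset[i]
    # no sample may belong to two fixations
    expect_false(any(in_fix & sel))
    in_fix <- in_fix | sel
  }
  missing <- is.na(raw$x)
  # the rest are saccade/discarded samples; everything is accounted for
  expect_equal(sum(in_fix) + sum(!in_fix & missing) + sum(!in_fix & !missing), n)
  expect_equal(sum(fs$fixations$n_samples), sum(in_fix))
})

test_that("classification is invariant under rigid translation", {
  geom <- screen_geometry(4000, 3200, 80, 64, 60)
  plan <- random_fixation_plan(5, geom, margin = 600, seed = 81)
  out <- generate_trace(scanpath_spec(plan, seed = 82), geom)
  fs1 <- detect_fixations(out$trace)
  shifted <- out$trace
  for (cc in c("left_x", "right_x")) {
    shifted$samples[[cc]] <- shifted$samples[[cc]] + 500
  }
  for (cc in c("left_y", "right_y")) {
    shifted$samples[[cc]] <- shifted$samples[[cc]] + 300
  }
  fs2 <- detect_fixations(shifted)
  expect_equal(nrow(fs2$fixations), nrow(fs1$fixations))
  expect_equal(fs2$fixations$onset, fs1$fixations$onset)
  expect_equal(fs2$fixations$offset, fs1$fixations$offset)
  expect_equal(fs2$fixations$x, fs1$fixations$x + 500, tolerance = 1e-6)
  expect_equal(fs2$fixations$y, fs1$fixations$y + 300, tolerance = 1e-6)
})

test_that("lower measurement noise never hurts planted-fixation recovery", {
  geom <- study_geometry()
  recovered <- sapply(c(0.5, 0.3, 0.15, 0.05, 0), function(ns) {
    tot <- 0L
    for (r in 1:8) {
      plan <- random_fixation_plan(7, geom, seed = 500 + r)
      out <- generate_trace(
        scanpath_spec(plan, noise_sd = ns, missing_rate = 0, seed = 600 + r),
        geom)
      fs <- suppressWarnings(detect_fixations(out$trace))
      tot <- tot + count_recovered(fs, out$truth, tol_ms = 8)
    }
    tot
  })
  expect_true(all(diff(recovered) >= 0))
})
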