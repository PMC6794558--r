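test_that("screen_geometry enforces positive fields and sane pixel pitch", {
  expect_s3_class(study_geometry(), "screen_geometry")
  expect_error(screen_geometry(0, 1024, 34.7, 25.9, 60), "positive")
  expect_error(screen_geometry(1280, 1024, -1, 25.9, 60), "positive")
  # anisotropic pitch beyond a factor of 2
  expect_error(screen_geometry(1280, 1024, 100, 10, 60), "pitch")
})

test_that("pixels_per_degree matches the trigonometric oracle", {
  geom <- study_geometry()
  # oracle: viewing_distance * tan(1 deg) / pixel pitch
  expect_equal(pixels_per_degree(geom),
               60 * tan(pi / 180) / (34.7 / 1280), tolerance = 1e-12)
  expect_equal(pixels_per_degree(geom), 38.63, tolerance = 1e-3)
  expect_equal(pixels_per_degree(geom, "vertical"),
               60 * tan(pi / 180) / (25.9 / 1024), tolerance = 1e-12)
  expect_equal(pixels_per_degree(geom, "vertical"), 41.41, tolerance = 1e-3)
  # small-angle proportionality in viewing distance
  geom2 <- screen_geometry(1280, 1024, 34.7, 25.9, 120)
  expect_equal(pixels_per_degree(geom2), 2 * pixels_per_degree(geom))
  # randomized geometries against the same closed form
  set.seed(42)
  for (k in 1:100) {
    rw <- sample(500:3000, 1); rh <- sample(400:2000, 1)
    pw <- runif(1, 20, 80); ph <- pw * rh / rw * runif(1, 0.8, 1.25)
    d <- runif(1, 30, 120)
    g <- screen_geometry(rw, rh, pw, ph, d)
    expect_equal(pixels_per_degree(g), rw * d * tan(pi / 180) / pw,
                 tolerance = 1e-9)
  }
})

test_that("gaze_trace validates timestamps and validity/coordinate coupling", {
  geom <- study_geometry()
  s <- tibble::tibble(t = c(0, 4, 4), left_x = 1, left_y = 1, right_x = 1,
                      right_y = 1, left_valid = TRUE, right_valid = TRUE)
  expect_error(gaze_trace("p", "g", "s", s, geometry = geom), "non-monotonic")
  s2 <- tibble::tibble(t = c(0, 4), left_x = c(1, NA), left_y = c(1, 1),
                       right_x = 1, right_y = 1,
                       left_valid = c(TRUE, TRUE), right_valid = TRUE)
  expect_error(gaze_trace("p", "g", "s", s2, geometry = geom), "validity")
})

test_that("clip_to_window keeps the half-open window and re-zeroes time", {
  geom <- study_geometry()
  t <- seq(0, 3996, by = 4)
  tr <- trace_from_xy(t, rep(100, 1000), rep(100, 1000), geom)
  half <- clip_to_window(tr, trial_window("s1", 0, 2000))
  expect_equal(nrow(half$samples), 500)
  expect_equal(half$samples$t[1], 0)
  # full-span window is the identity on samples
  full <- clip_to_window(tr, trial_window("s1", 0, 4000))
  expect_equal(full$samples, tr$samples)
  # offset window re-zeroes
  late <- clip_to_window(tr, trial_window("s2", 1000, 2000))
  expect_equal(late$samples$t[1], 0)
  expect_equal(late$stimulus_id, "s2")
  expect_error(clip_to_window(tr, trial_window("s1", 9000, 9999)),
               "empty trial window")
})

test_that("read_gaze_log parses toy logs, preserves missing, reports errors", {
  geom <- study_geometry()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "participant\tgroup\tstimulus\ttime\tl_x\tl_y\tr_x\tr_y\tl_valid\tr_valid",
    "p1\tasd\ts1\t0\t100\t100\t104\t104\tTRUE\tTRUE",
    "p1\tasd\ts1\t4\tNA\tNA\t250\t300\tFALSE\tTRUE",
    "p1\tasd\ts1\t8\t101\t99\t105\t103\tTRUE\tTRUE"
  ), path)
  traces <- read_gaze_log(path, geom)
  expect_length(traces, 1)
  tr <- traces[[1]]
  expect_equal(nrow(tr$samples), 3)
  expect_true(is.na(tr$samples$left_x[2]))
  expect_false(tr$samples$left_valid[2])
  expect_equal(tr$samples$right_x[2], 250)

  # non-monotonic timestamps
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "participant\tgroup\tstimulus\ttime\tl_x\tl_y\tr_x\tr_y\tl_valid\tr_valid",
    "p1\tasd\ts1\t0\t100\t100\t104\t104\tTRUE\tTRUE",
    "p1\tasd\ts1\t4\t100\t100\t104\t104\tTRUE\tTRUE",
    "p1\tasd\ts1\t4\t100\t100\t104\t104\tTRUE\tTRUE"
  ), path2)
  expect_error(read_gaze_log(path2, geom), "non-monotonic")

  # unparseable coordinate names its line
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "participant\tgroup\tstimulus\ttime\tl_x\tl_y\tr_x\tr_y\tl_valid\tr_valid",
    "p1\tasd\ts1\t0\toops\t100\t104\t104\tTRUE\tTRUE"
  ), path3)
  expect_error(read_gaze_log(path3, geom), "line 2")
})

test_that("write/read round-trips random gaze traces bit-exactly", {
  geom <- study_geometry()
  set.seed(7)
  for (k in 1:5) {
    n <- sample(20:60, 1)
    lv <- runif(n) > 0.1
    rv <- runif(n) > 0.1
    s <- tibble::tibble(
      t = cumsum(runif(n, 3.5, 4.5)),
      left_x = ifelse(lv, runif(n, -50, 1400), NA_real_),
      left_y = ifelse(lv, runif(n, -50, 1100), NA_real_),
      right_x = ifelse(rv, runif(n, -50, 1400), NA_real_),
      right_y = ifelse(rv, runif(n, -50, 1100), NA_real_),
      left_valid = lv, right_valid = rv
    )
    tr <- gaze_trace(paste0("p", k), "grp", "stim", s, geometry = geom)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_gaze_log(tr, path)
    back <- read_gaze_log(path, geom)[[1]]
    expect_identical(back$samples$t, tr$samples$t)
    expect_identical(back$samples$left_x, tr$samples$left_x)
    expect_identical(back$samples$right_y, tr$samples$right_y)
    expect_identical(back$samples$left_valid, tr$samples$left_valid)
    expect_equal(back$participant_id, tr$participant_id)
  }
})
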