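test_that("a Movebank CSV round-trips through write and read", {
  ls <- uniform_landscape(n = 300)
  cfg <- sim_config(n_individuals = 2, n_fixes = 25, rng_seed = 2)
  fixes <- simulate_tracks(ls, cfg)$fixes
  path <- withr::local_tempfile(fileext = ".csv")
  write_movebank_csv(fixes, path)
  back <- read_tracks(path)
  expect_equal(nrow(back), nrow(fixes))
  expect_equal(back$x, fixes$x, tolerance = 1e-6)
  expect_equal(back$y, fixes$y, tolerance = 1e-6)
  expect_equal(back$timestamp, fixes$timestamp)
  expect_equal(sort(unique(back$individual_id)), c("sim_01", "sim_02"))
})

test_that("reader sorts out-of-order fixes and enforces structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_fixes(x = c(0, 10, 20), y = c(0, 0, 0))
  write_movebank_csv(df[c(2, 1, 3), ], path)
  back <- read_tracks(path)
  expect_equal(back$x, c(0, 10, 20))
  # missing column
  raw <- readr::read_csv(path, show_col_types = FALSE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw[, -1], path2)
  expect_error(read_tracks(path2), "individual-local-identifier")
  # duplicate timestamp
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_movebank_csv(dplyr::bind_rows(df, df[2, ]), path3)
  expect_error(read_tracks(path3), "duplicate timestamp")
  # unparseable timestamp
  raw$timestamp <- as.character(raw$timestamp)
  raw$timestamp[2] <- "not-a-time"
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path4)
  expect_error(read_tracks(path4), "timestamp")
})

test_that("geographic coordinates are projected to metre-true UTM", {
  skip_if_not_installed("geosphere")
  set.seed(1)
  lon <- -53.5 + cumsum(rnorm(50, 0, 0.001))
  lat <- -21.2 + cumsum(rnorm(50, 0, 0.001))
  xy <- project_utm(lon, lat)
  utm_d <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  geo_d <- geosphere::distGeo(cbind(lon, lat))[1:49]
  # transverse-Mercator scale distortion near the zone centre is < 0.1%
  expect_lt(max(abs(utm_d - geo_d) / geo_d), 1e-3)
})

test_that("steps are built with correct lengths, durations, and angles", {
  fx <- make_fixes(x = c(0, 300), y = c(0, 0))
  st <- build_steps(fx)
  expect_equal(nrow(st), 1)
  expect_equal(st$d_m, 300)
  expect_equal(st$t_min, 20)
  expect_true(is.na(st$theta))
  # collinear fixes: zero turning angle
  st <- build_steps(make_fixes(x = c(0, 10, 20), y = c(0, 0, 0)))
  expect_equal(st$theta[2], 0)
  # left turn is positive pi/2
  st <- build_steps(make_fixes(x = c(0, 1, 1), y = c(0, 0, 1)))
  expect_equal(st$theta[2], pi / 2)
  # right turn is negative
  st <- build_steps(make_fixes(x = c(0, 1, 1), y = c(0, 0, -1)))
  expect_equal(st$theta[2], -pi / 2)
  # N fixes -> N - 1 steps
  st <- build_steps(make_fixes(x = 1:7, y = rep(0, 7)))
  expect_equal(nrow(st), 6)
  # fewer than 2 fixes: empty table with a warning
  expect_warning(st0 <- build_steps(make_fixes(x = 0, y = 0)), "fewer than 2")
  expect_equal(nrow(st0), 0)
})

test_that("the top-1% rule removes exactly the longest steps", {
  set.seed(42)
  d <- sample(seq_len(1000)) # 1,000 distinct lengths
  st <- make_steps(d)
  out <- filter_speed_outliers(st)
  # sort-and-count oracle: lengths strictly above the type-7 99% quantile
  thr <- quantile(d, 0.99, type = 7)
  expect_equal(sum(out$removed_speed), sum(d > thr))
  expect_equal(sum(out$removed_speed), 10)
  expect_setequal(out$d_m[out$removed_speed], sort(d, decreasing = TRUE)[1:10])
})

test_that("tied step lengths are never removed by the quantile rule", {
  st <- make_steps(rep(50, 100))
  out <- filter_speed_outliers(st)
  expect_equal(sum(out$removed_speed), 0)
})

test_that("the speed threshold is computed per individual", {
  st <- dplyr::bind_rows(make_steps(1:100, id = "small"),
                         make_steps(1001:1100, id = "big"))
  out <- filter_speed_outliers(st)
  removed <- out[out$removed_speed, ]
  expect_setequal(unique(removed$individual_id), c("small", "big"))
  expect_equal(sum(removed$individual_id == "small"), 1)
  expect_equal(sum(removed$individual_id == "big"), 1)
})

test_that("gap filter removes strictly above 60 minutes and breaks the angle chain", {
  st <- make_steps(d = rep(10, 4), t = c(20, 60, 61, 20), theta = 0.5)
  out <- filter_long_gaps(st)
  expect_equal(out$removed_gap, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(is.na(out$theta[4])) # follows a removed step
  expect_equal(out$theta[2], 0.5)
})

test_that("a fixture with 37 injected 80-minute gaps yields exactly 37 removals", {
  ls <- uniform_landscape(n = 500)
  cfg <- sim_config(n_fixes = 2000, rng_seed = 6)
  tr <- simulate_trajectory(ls, cfg, 1)
  fixes <- tr$fixes
  # delete 3 consecutive fixes at 37 well-separated positions: each deletion
  # turns four 20-min steps into one 80-min step
  starts <- seq(10, by = 50, length.out = 37)
  drop <- unlist(lapply(starts, function(s) s:(s + 2)))
  fixes <- fixes[-drop, ]
  st <- filter_long_gaps(build_steps(fixes))
  expect_equal(sum(st$removed_gap), 37)
  expect_equal(sort(st$t_min[st$removed_gap]), rep(80, 37))
})

test_that("zero steps are floored to 1 m and flagged", {
  st <- make_steps(d = c(0, 5, 0, 12), theta = 0.1)
  out <- floor_zero_steps(st)
  expect_equal(out$d_m, c(1, 5, 1, 12))
  expect_equal(out$floored_zero, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(is.na(out$theta[out$floored_zero])))
  expect_equal(out$theta[2], 0.1)
  expect_error(floor_zero_steps(st, floor_m = 0), "floor_m")
})

test_that("filters are idempotent and retention is monotone", {
  ls <- uniform_landscape(n = 600)
  cfg <- sim_config(n_fixes = 1500, rng_seed = 8)
  st <- build_steps(simulate_trajectory(ls, cfg, 1)$fixes)
  once <- filter_speed_outliers(st)
  expect_identical(filter_speed_outliers(once), once)
  once_g <- filter_long_gaps(once)
  expect_identical(filter_long_gaps(once_g), once_g)
  # retained rows never increase through the chain
  n0 <- nrow(st)
  n1 <- nrow(retained_steps(once))
  n2 <- nrow(retained_steps(once_g))
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("artifact-free synthetic data retains about 99% of steps", {
  ls <- uniform_landscape(n = 900)
  cfg <- sim_config(n_fixes = 4000, rng_seed = 10)
  st <- build_steps(simulate_trajectory(ls, cfg, 1)$fixes) |>
    filter_speed_outliers() |>
    filter_long_gaps()
  retention <- nrow(retained_steps(st)) / nrow(st)
  expect_gt(retention, 0.985)
  expect_lte(retention, 0.9925)
  expect_equal(sum(st$removed_gap), 0) # only the top-1% rule bites
})
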