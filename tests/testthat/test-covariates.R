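grid_series <- function(x, y, delta_min = 15) {
  out <- data.frame(time = (seq_along(x) - 1) * delta_min * 60, x = x, y = y)
  attr(out, "delta_min") <- delta_min
  out
}

test_that("steps and angles follow the stated geometry", {
  # collinear equally spaced points: straight-line movement, angles 0
  s <- compute_steps_angles(grid_series(0:5 * 3, 0:5 * 4))
  expect_equal(s$step, c(rep(5, 5), NA))
  expect_equal(s$angle, c(NA, 0, 0, 0, 0, NA))
  # course reversal maps to +pi
  r <- compute_steps_angles(grid_series(c(0, 1, 0, 1), rep(0, 4)))
  expect_equal(r$angle[2:3], c(pi, pi))
  # square path: four right-angle turns of the same sign
  sq <- compute_steps_angles(grid_series(c(0, 1, 1, 0, 0, 1),
                                         c(0, 0, 1, 1, 0, 0)))
  expect_equal(sq$angle[2:5], rep(pi / 2, 4))
  sq2 <- compute_steps_angles(grid_series(c(0, 1, 1, 0, 0, 1),
                                          -c(0, 0, 1, 1, 0, 0)))
  expect_equal(sq2$angle[2:5], rep(-pi / 2, 4))
  # duplicate consecutive positions: zero step, undefined angle
  dup <- compute_steps_angles(grid_series(c(0, 1, 1, 2), c(0, 0, 0, 1)))
  expect_equal(dup$step[2], 0)
  expect_true(is.na(dup$angle[2]) && is.na(dup$angle[3]))
})

test_that("steps and angles are invariant under rigid motions", {
  set.seed(81)
  for (rep_ in 1:5) {
    x <- cumsum(rnorm(12)); y <- cumsum(rnorm(12))
    base <- compute_steps_angles(grid_series(x, y))
    th <- runif(1, 0, 2 * pi); dx <- rnorm(1, 0, 50); dy <- rnorm(1, 0, 50)
    rot <- compute_steps_angles(grid_series(
      cos(th) * x - sin(th) * y + dx, sin(th) * x + cos(th) * y + dy))
    expect_equal(rot$step, base$step, tolerance = 1e-10)
    expect_equal(rot$angle, base$angle, tolerance = 1e-8)
    # reflection flips angle signs
    ref <- compute_steps_angles(grid_series(x, -y))
    expect_equal(ref$angle, -base$angle, tolerance = 1e-10)
  }
})

test_that("acceleration aggregates by interval mean with missing propagation", {
  track <- data.frame(time = c(100, 500, 1000, 2000),
                      accel = c(0.5, 0.7, 0.2, NA))
  grid <- grid_series(1:4, 1:4, delta_min = 15)
  a <- aggregate_acceleration(track, grid)
  expect_equal(a[1], 0.6)          # transmissions at 100 and 500 s
  expect_equal(a[2], 0.2)          # 1000 s; the NA at 2000 s is ignored
  expect_true(all(is.na(a[3:4])))  # no transmissions in later intervals
  allna <- data.frame(time = c(100, 1000), accel = c(NA, NA))
  expect_true(all(is.na(aggregate_acceleration(allna, grid))))
})

test_that("tide covariates interpolate and difference as specified", {
  gt <- seq(3600, 6 * 3600, by = 900)
  # constant tide: zero difference
  flat <- data.frame(time = c(0, 1e5), height = c(1.2, 1.2))
  tc <- build_tide_covariates(flat, gt)
  expect_equal(tc$tide, rep(1.2, length(gt)))
  expect_equal(tc$dtide, rep(0, length(gt)))
  # linear 0.4 m/h rise: +0.1 m per 15 min everywhere
  lin <- data.frame(time = c(0, 1e5), height = c(0, 1e5 * 0.4 / 3600))
  tc2 <- build_tide_covariates(lin, gt)
  expect_equal(tc2$dtide, rep(0.1, length(gt)), tolerance = 1e-10)
  # sinusoid: difference tracks the analytic derivative (max near
  # mid-flood, ~0 at high water) and sums to ~0 over whole periods
  per <- 12.42 * 3600
  td <- simulate_tide(4 * per, amplitude = 1, period = per, datum_offset = 1,
                      sample_interval = 60)
  gt3 <- seq(900, 2 * per, by = 900)
  tc3 <- build_tide_covariates(td, gt3)
  deriv <- function(t) 2 * pi / per * cos(2 * pi * (t - 450) / per) * 900
  expect_equal(tc3$dtide, deriv(gt3), tolerance = 0.01)
  # the telescoping sum over ~2 periods leaves at most one grid step of
  # tidal slope (the 12.42 h period is not a multiple of the grid)
  expect_lt(abs(sum(tc3$dtide)), 2 * pi / per * 900 * 1.01)
  i_flood <- which.min(abs(gt3 - per))             # mid-flood
  i_high <- which.min(abs(gt3 - (per / 4 + 450)))  # dtide zero crossing
  expect_gt(tc3$dtide[i_flood], 10 * abs(tc3$dtide[i_high]))
  # outside the record: flagged missing
  tc4 <- build_tide_covariates(data.frame(time = c(2000, 4000),
                                          height = c(1, 1.1)),
                               c(500, 3000))
  expect_true(attr(tc4, "outside")[1])
  expect_true(is.na(tc4$tide[1]) || is.na(tc4$dtide[1]))
})

test_that("cyclic time covariates lie on the unit circle with 24 h period", {
  expect_equal(unlist(cyclic_time(0)), c(hour_cos = 1, hour_sin = 0))
  expect_equal(unlist(cyclic_time(6)), c(hour_cos = 0, hour_sin = 1),
               tolerance = 1e-12)
  t <- runif(200, -48, 72)
  ct <- cyclic_time(t)
  expect_equal(ct$hour_cos^2 + ct$hour_sin^2, rep(1, 200), tolerance = 1e-12)
  expect_equal(cyclic_time(t + 24), ct, tolerance = 1e-12)
})

test_that("habitat assignment respects the buffer, containment and priority", {
  seagrass <- list(category = "seagrass",
                   coords = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  mangrove <- list(category = "mangrove",
                   coords = cbind(c(8, 20, 20, 8), c(0, 0, 10, 10)))
  polys <- list(mangrove, seagrass)
  # 1.0 m outside a seagrass edge: captured by the 1.26 m buffer
  expect_equal(as.character(assign_habitat(11 - 1e-9, 5, list(seagrass))),
               "seagrass")
  expect_equal(as.character(assign_habitat(-1.0, 5, polys)), "seagrass")
  # 10 m away from everything: unvegetated
  expect_equal(as.character(assign_habitat(-10, 5, polys)), "unvegetated")
  # containment wins regardless of buffer
  expect_equal(as.character(assign_habitat(15, 5, polys)), "mangrove")
  # overlap region: seagrass outranks mangrove
  expect_equal(as.character(assign_habitat(9, 5, polys)), "seagrass")
  bad <- list(category = "saltmarsh", coords = cbind(c(0, 1), c(0, 1)))
  expect_error(assign_habitat(0, 0, list(bad)), "saltmarsh")
})

test_that("GeoJSON habitat layers round-trip into polygon lists", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(habitat = "seagrass"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(10, 0), list(10, 10), list(0, 10),
                list(0, 0)))))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  polys <- read_habitat_geojson(f)
  expect_length(polys, 1)
  expect_equal(polys[[1]]$category, "seagrass")
  expect_equal(as.character(assign_habitat(5, 5, polys)), "seagrass")
})
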