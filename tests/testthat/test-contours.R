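test_that("interpolation passes exactly through anchors and preserves shape", {
  ## constant and single-anchor contours are flat
  expect_equal(sample_contour(contour_spec(rbind(c(0, 100), c(1, 100))),
                              1, 5)$values, rep(100, 5))
  expect_equal(sample_contour(contour_spec(rbind(c(0.5, 200))),
                              1, 3)$values, rep(200, 3))
  ## multi-anchor contour reproduces anchor values at anchor times
  cs <- contour_spec(rbind(c(0, 100), c(0.5, 200), c(1, 100)))
  v <- sample_contour(cs, 1, 1001)$values
  expect_equal(v[c(1, 501, 1001)], c(100, 200, 100), tolerance = 1e-9)

  ## random anchor sets: exact at grid-hit anchor times, no overshoot
  ## between monotone anchors
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    tms <- sort(sample(seq(0, 1, by = 0.05), k))
    tms <- (tms - min(tms)) / (max(tms) - min(tms))  # span [0, 1]
    vals <- runif(k, 50, 500)
    cs <- contour_spec(cbind(tms, vals), scale = sample(c("linear", "log"), 1))
    sc <- sample_contour(cs, 1, 21)  # grid hits times that are multiples of .05
    grid_t <- seq(0, 1, length.out = 21)
    hit <- match(round(tms, 10), round(grid_t, 10))
    ok <- !is.na(hit)
    expect_equal(sc$values[hit[ok]], vals[ok], tolerance = 1e-6)
    ## within-segment values bounded by segment endpoints (monotone interp)
    dense <- sample_contour(cs, 1, 2000)$values
    expect_lte(max(dense), max(vals) + 1e-9 * max(vals))
    expect_gte(min(dense), min(vals) - 1e-9 * max(vals))
  }
})

test_that("resampling at >= 100 points/s recovers anchor values", {
  set.seed(7)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    tms <- seq(0, 1, length.out = k) +
      c(0, runif(max(k - 2, 0), -0.4, 0.4) / k, 0)  # jittered, well separated
    vals <- runif(k, 80, 800)
    cs <- contour_spec(cbind(tms, vals), scale = "log")
    sc <- sample_contour(cs, 2, 100)
    tt <- seq(0, 1, length.out = length(sc$values))
    read_back <- approx(tt, sc$values, xout = tms)$y
    expect_equal(read_back, vals, tolerance = 1e-3)
  }
})

test_that("invalid contour specifications are rejected", {
  expect_error(contour_spec(numeric(0)), "anchor")
  expect_error(contour_spec(rbind(c(0, -5)), scale = "log"), "positive")
  expect_error(contour_spec(rbind(c(0, 0.2), c(1, 1.5)), parameter = "mouth",
                            range = c(0, 1)), "mouth")
  expect_error(wiggle_contour(contour_spec(100), temperature = -1),
               "non-negative")
})

test_that("wiggle is a seeded perturbation with the configured SD", {
  cs <- contour_spec(100, parameter = "f0")
  ## zero temperature is the identity
  expect_identical(wiggle_contour(cs, 0), cs)
  ## seeded determinism
  expect_identical(wiggle_contour(cs, 0.1, seed = 42),
                   wiggle_contour(cs, 0.1, seed = 42))
  ## Monte-Carlo: SD of the perturbed anchor ~ temperature * (5% of value)
  temp <- 0.05
  vals <- vapply(1:10000, function(s)
    wiggle_contour(cs, temp, seed = s)$anchors$value, 0)
  expect_equal(sd(vals), temp * 0.05 * 100, tolerance = 0.05)
  ## higher temperature => strictly larger mean absolute perturbation
  d1 <- mean(abs(vapply(1:1000, function(s)
    wiggle_contour(cs, 0.05, seed = s)$anchors$value - 100, 0)))
  d2 <- mean(abs(vapply(1:1000, function(s)
    wiggle_contour(cs, 0.2, seed = s)$anchors$value - 100, 0)))
  expect_gt(d2, d1)
})
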