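test_that("linear volume fit equals the closed-form OLS solution", {
  set.seed(42)
  for (i in 1:5) {
    t <- sort(runif(12, 0, 3000))
    v <- 30 - 0.008 * t + rnorm(12, 0, 0.5)
    fit <- fit_linear_volume(t, v, window = NULL)
    # normal equations, independently
    sxx <- sum((t - mean(t))^2)
    slope <- sum((t - mean(t)) * (v - mean(v))) / sxx
    intercept <- mean(v) - slope * mean(t)
    expect_equal(fit$slope, slope, tolerance = 1e-12)
    expect_equal(fit$intercept, intercept, tolerance = 1e-12)
    r2 <- 1 - sum((v - intercept - slope * t)^2) / sum((v - mean(v))^2)
    expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  }
})

test_that("an exact line is recovered with R^2 = 1", {
  t <- seq(0, 3000, 300)
  fit <- fit_linear_volume(t, -0.01 * t + 29.9)
  expect_equal(fit$slope, -0.01)
  expect_equal(fit$intercept, 29.9)
  expect_equal(fit$r_squared, 1)
})

test_that("constant volumes give slope 0 and R^2 = 0 by convention", {
  fit <- fit_linear_volume(seq(0, 1000, 100), rep(20, 11))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("the default window drops points beyond 3000 s", {
  t <- seq(0, 3600, 300)
  v <- ifelse(t <= 3000, 29.9 - 0.01 * t, 29.9 - 0.01 * 3000)
  fit <- fit_linear_volume(t, v)  # late flat points excluded
  expect_equal(fit$slope, -0.01)
  fit_all <- fit_linear_volume(t, v, window = NULL)
  expect_gt(fit_all$slope, -0.01)
})

test_that("degenerate time vectors are rejected", {
  expect_error(fit_linear_volume(rep(5, 5), 1:5, window = NULL),
               "degenerate")
  expect_error(fit_linear_volume(1:2, 1:2, window = NULL), "3 points")
})

test_that("noisy synthetic series recover the slope within 5% (10-seed median)", {
  t <- seq(0, 3300, 300)
  errs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    v <- (35 - 0.0056 * t) * (1 + rnorm(length(t), 0, 0.02))
    abs(fit_linear_volume(t, v)$slope - (-0.0056)) / 0.0056
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("normalized trajectories start at 1 and track the generator modes", {
  ser <- gen_evaporation_series(35, -0.0056, 300, 3600, "pinned",
                                fluid = water, render = FALSE)
  times <- vapply(ser, function(f) f$time, 0)
  lens <- vapply(ser, function(f) f$truth$length, 0)
  hts <- vapply(ser, function(f) f$truth$height, 0)
  traj <- normalize_trajectories(times, lens, hts)
  expect_equal(traj$normalized_length[1], 1)
  expect_equal(traj$normalized_height[1], 1)
  expect_lt(max(abs(traj$normalized_length - 1)), 5e-3)
  expect_true(all(diff(traj$normalized_height) < 0))
})

test_that("depinning series show a strictly decreasing length after the threshold", {
  ser <- gen_evaporation_series(35, -0.008, 300, 3600, "depinning",
                                fluid = water, theta_pin = 30,
                                render = FALSE)
  lens <- vapply(ser, function(f) f$truth$length, 0)
  moving <- which(lens < lens[1] * 0.995)
  expect_gt(length(moving), 1)
  expect_true(all(diff(lens[moving]) < 0))
})

test_that("depinning detection fires within one frame of the generator onset", {
  ser <- gen_evaporation_series(35, -0.008, 300, 3600, "depinning",
                                fluid = water, theta_pin = 30,
                                render = FALSE)
  times <- vapply(ser, function(f) f$time, 0)
  el <- vapply(ser, function(f) f$truth$edge_left, 0)
  er <- vapply(ser, function(f) f$truth$edge_right, 0)
  lens <- er - el
  t_true <- times[which(lens < lens[1] * (1 - 0.02))[1]]
  t_det <- detect_depinning(times, el, er)
  expect_lte(abs(t_det - t_true), 300)
})

test_that("pinned series never trigger depinning detection", {
  ser <- gen_evaporation_series(35, -0.0056, 300, 3600, "pinned",
                                fluid = water, render = FALSE)
  times <- vapply(ser, function(f) f$time, 0)
  el <- vapply(ser, function(f) f$truth$edge_left, 0)
  er <- vapply(ser, function(f) f$truth$edge_right, 0)
  expect_true(is.na(detect_depinning(times, el, er)))
})

test_that("single-frame jitter below the persistence rule is ignored", {
  t <- 0:10
  el <- rep(0, 11); er <- rep(10, 11)
  el[5] <- 0.5  # one-frame 5% excursion
  expect_true(is.na(detect_depinning(t, el, er)))
  el[5:6] <- 0.5  # two frames: fires at the first of them
  expect_equal(detect_depinning(t, el, er), 4)
})

test_that("depinning detection is invariant to a uniform edge translation", {
  t <- 0:12
  el <- c(rep(0, 6), seq(0.15, 0.75, 0.1))
  er <- rep(10, 13)
  d0 <- detect_depinning(t, el, er)
  d1 <- detect_depinning(t, el + 3.7, er + 3.7)
  expect_equal(d0, d1)
  expect_false(is.na(d0))
})

test_that("evaporation_summary bundles fit, trajectories and depinning", {
  ser <- gen_evaporation_series(29.9, -0.01, 300, 2400, "pinned",
                                fluid = water, render = FALSE)
  times <- vapply(ser, function(f) f$time, 0)
  geom <- data.frame(
    volume = vapply(ser, function(f) f$truth$volume, 0),
    length = vapply(ser, function(f) f$truth$length, 0),
    height = vapply(ser, function(f) f$truth$height, 0),
    edge_left = vapply(ser, function(f) f$truth$edge_left, 0),
    edge_right = vapply(ser, function(f) f$truth$edge_right, 0))
  res <- evaporation_summary(times, geom)
  expect_s3_class(res, "evap_result")
  expect_equal(res$slope, -0.01, tolerance = 1e-9)
  expect_equal(res$intercept, 29.9, tolerance = 1e-9)
  expect_true(is.na(res$depin_time))
})
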