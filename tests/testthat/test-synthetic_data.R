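test_that("sessile generator records the requested geometry as ground truth", {
  g <- gen_sessile_image(35, 40, water)
  expect_equal(g$truth$volume, 35)
  expect_equal(g$truth$theta_left, 40)
  expect_equal(g$truth$length,
               g$truth$edge_right - g$truth$edge_left)
  expect_true(all(g$image >= 0 & g$image <= 1))
})

test_that("identical seed and parameters give bit-identical images", {
  sc <- synthetic_scene(noise_sd = 5 / 255, seed = 11)
  g1 <- gen_sessile_image(20, 35, water, sc)
  g2 <- gen_sessile_image(20, 35, water, sc)
  expect_identical(g1$image, g2$image)
  g3 <- gen_sessile_image(20, 35, water, synthetic_scene(noise_sd = 5 / 255,
                                                         seed = 12))
  expect_false(identical(g1$image, g3$image))
})

test_that("zero-gravity 90 degree drop renders a half disk of radius (3V/2pi)^(1/3)", {
  v <- 10
  R_mm <- (3 * v / (2 * pi))^(1 / 3)  # v in uL = mm^3
  g <- gen_sessile_image(v, 90, water, g = 0)
  expect_equal(g$truth$height, R_mm, tolerance = 1e-3)
  expect_equal(g$truth$length / 2, R_mm, tolerance = 1e-3)
  # silhouette area (px) * scale^2 matches the half-disk cross-section
  ps <- g$truth$pixel_scale
  dark <- sum(g$image < 0.5 & row(g$image) < g$truth$baseline_row)
  expect_equal(dark * ps^2, pi * R_mm^2 / 2, tolerance = 0.01)
})

test_that("rendered silhouette area matches the analytic cross-section", {
  g <- gen_sessile_image(35, 40, water)
  sh <- solve_for(35, 40, water)
  xs <- sh$x * 1e3; zs <- sh$z * 1e3
  area_mm2 <- 2 * sum((xs[-1] + xs[-length(xs)]) / 2 * diff(zs))
  ps <- g$truth$pixel_scale
  dark <- sum(g$image < 0.5 & row(g$image) < g$truth$baseline_row)
  # within 1 px-equivalent per boundary pixel
  boundary_px <- 2 * g$truth$height / ps + g$truth$length / ps
  expect_lt(abs(dark * ps^2 - area_mm2), boundary_px * ps^2)
})

test_that("evaporation series volumes are exactly affine in time", {
  ser <- gen_evaporation_series(29.9, -0.01, 300, 2400, "depinning",
                                fluid = water, render = FALSE)
  expect_length(ser, 9)
  vols <- vapply(ser, function(f) f$truth$volume, 0)
  times <- vapply(ser, function(f) f$time, 0)
  expect_equal(vols, 29.9 - 0.01 * times)
  expect_equal(vols[length(vols)], 5.9)
})

test_that("evaporation preconditions reject volumes falling below 5% of v0", {
  expect_error(gen_evaporation_series(29.9, -0.01, 300, 3000, "depinning",
                                      fluid = water, render = FALSE),
               "5%")
})

test_that("zero slope gives identical geometry in every frame", {
  ser <- gen_evaporation_series(35, 0, 300, 900, "pinned", fluid = water,
                                render = FALSE)
  lens <- vapply(ser, function(f) f$truth$length, 0)
  ths <- vapply(ser, function(f) f$truth$theta_left, 0)
  expect_equal(lens, rep(lens[1], length(lens)))
  expect_equal(ths, rep(ths[1], length(ths)))
})

test_that("pinned mode holds the contact-line length while theta falls", {
  ser <- gen_evaporation_series(35, -0.0056, 300, 3600, "pinned",
                                fluid = water, render = FALSE)
  lens <- vapply(ser, function(f) f$truth$length, 0)
  ths <- vapply(ser, function(f) f$truth$theta_left, 0)
  expect_lt(max(abs(lens - lens[1])) / lens[1], 2e-3)
  expect_true(all(diff(ths) < 0))
})

test_that("depinning mode pins theta at the threshold and shrinks the length", {
  ser <- gen_evaporation_series(35, -0.008, 300, 3600, "depinning",
                                fluid = water, theta_pin = 30,
                                render = FALSE)
  ths <- vapply(ser, function(f) f$truth$theta_left, 0)
  lens <- vapply(ser, function(f) f$truth$length, 0)
  after <- which(abs(ths - 30) < 0.01)
  expect_gt(length(after), 1)
  expect_true(all(diff(lens[after]) < 0))
  expect_true(all(ths >= 30 - 0.01))
})

test_that("rotation ramp arithmetic: one frame per rpm at 1 rpm/s", {
  rf <- gen_rotation_ramp(list(theta_adv = 53, rs_spread = 40,
                               theta_rec = 15, rs_slide = 50))
  expect_equal(nrow(rf), 101)
  expect_equal(rf$rs, 0:100)
  expect_equal(rf$a_T, rs_to_aT(0:100, 0.25))
})

test_that("ramp rear edge stays put below the sliding onset", {
  rf <- gen_rotation_ramp(list(theta_adv = 53, rs_spread = 40,
                               theta_rec = 15, rs_slide = 50))
  expect_true(all(rf$edge_rear[rf$rs < 50] == rf$edge_rear[1]))
  expect_true(all(diff(rf$edge_rear[rf$rs >= 50]) > 0))
  # angles hit their plateaus at the stated speeds
  expect_equal(rf$theta_front[rf$rs >= 40], rep(53, sum(rf$rs >= 40)))
  expect_equal(rf$theta_rear[rf$rs >= 50], rep(15, sum(rf$rs >= 50)))
})

test_that("pinned-rear ramp keeps the rear edge constant at every speed", {
  rf <- gen_rotation_ramp(list(theta_adv = 53, rs_spread = 55,
                               theta_rec = 15, rs_slide = NA, rs_rec = 65))
  expect_true(all(rf$edge_rear == rf$edge_rear[1]))
  expect_true(attr(rf, "pinned_rear"))
})

test_that("ramp generator rejects non-positive hysteresis", {
  expect_error(gen_rotation_ramp(list(theta_adv = 15, rs_spread = 40,
                                      theta_rec = 53, rs_slide = 50)),
               "hysteresis")
})

test_that("flow-curve generator follows the power law", {
  fc <- gen_flow_curve(K = 0.05, n = 1, noise_rel = 0)
  expect_equal(fc$viscosity, rep(0.05, nrow(fc)))
  fc <- gen_flow_curve(K = 0.05, n = 0.4, rate_range = c(10, 100))
  expect_equal(fc$viscosity[nrow(fc)] / fc$viscosity[1], 10^(-0.6),
               tolerance = 1e-10)
  f1 <- gen_flow_curve(0.05, 0.4, noise_rel = 0.05, seed = 4)
  f2 <- gen_flow_curve(0.05, 0.4, noise_rel = 0.05, seed = 4)
  expect_identical(f1, f2)
})

test_that("cell-field generator places the exact requested counts", {
  ci <- gen_cell_image(50, 20, seed = 2)
  expect_equal(ci$truth$n_green, 50)
  expect_equal(ci$truth$n_red, 20)
  expect_equal(sum(ci$truth$objects$channel == "green"), 50)
  expect_equal(nrow(ci$truth$objects), 70)
  expect_true(all(ci$truth$objects$area_px >= 10 &
                  ci$truth$objects$area_px <= 30))
  blank <- gen_cell_image(0, 0)
  expect_equal(sum(blank$green) + sum(blank$red), 0)
})

test_that("cell areas convert to physical units with the pixel scale", {
  ci <- gen_cell_image(10, 0, pixel_scale = 0.566, seed = 5)
  areas_um2 <- ci$truth$objects$area_px * 0.566^2
  expect_true(all(areas_um2 >= 10 * 0.566^2 & areas_um2 <= 30 * 0.566^2))
  # the default scale maps 10 px^2 to 3.2 um^2
  expect_equal(10 * 0.566^2, 3.2, tolerance = 0.02)
})

test_that("cell generator refuses fields over 30% covered", {
  expect_error(gen_cell_image(600, 600, field = c(100, 100)), "30%")
})

test_that("series writer produces PNG frames, JSON sidecars and a manifest", {
  d <- withr::local_tempdir()
  ser <- gen_evaporation_series(35, -0.01, 600, 1200, "pinned",
                                fluid = water,
                                scene = synthetic_scene(pixel_scale = 0.03))
  man <- write_series(ser, d)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(d, man$file))))
  img <- read_image(file.path(d, man$file[1]))
  expect_equal(dim(img), dim(ser[[1]]$image))
  expect_equal(max(abs(img - ser[[1]]$image)), 0, tolerance = 1 / 255)
})
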