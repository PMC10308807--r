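#' Describe a synthetic imaging scene
#'
#' Geometry and noise settings shared by all synthetic image
#' generators: the pixel scale of the (virtual) side-view camera, the
#' raster size, the row of the substrate surface, the grayscale noise
#' level and the RNG seed. The raster convention is origin top-left
#' with row index increasing downward; the droplet sits above
#' `baseline_row` and physical heights increase upward from the
#' baseline.
#'
#' @param pixel_scale physical length per pixel, mm/px.
#' @param image_size `c(rows, cols)` of the raster, or `NULL` to size
#'   the raster automatically around the rendered drop.
#' @param baseline_row row index of the first substrate row, or `NULL`
#'   to place the baseline automatically near the bottom of the raster.
#' @param noise_sd standard deviation of additive Gaussian intensity
#'   noise, on the 0-1 grayscale (e.g. `5/255`).
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical artifacts.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(pixel_scale = 0.01, image_size = NULL,
                            baseline_row = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(pixel_scale > 0, noise_sd >= 0)
  if (!is.null(image_size)) {
    stopifnot(length(image_size) == 2L, all(image_size >= 4))
    if (!is.null(baseline_row))
      stopifnot(baseline_row >= 2, baseline_row <= image_size[1])
  }
  structure(list(pixel_scale = pixel_scale, image_size = image_size,
                 baseline_row = baseline_row, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# grayscale levels of the rendering (dyed drop, dark on light background)
.render_levels <- list(bg = 0.9, drop = 0.1, substrate = 0.15)

# quantize to 8 bit, add seeded Gaussian noise, clip to [0, 1]
.finish_image <- function(img, scene) {
  if (scene$noise_sd > 0)
    img <- img + with_seed(scene$seed,
                           matrix(stats::rnorm(length(img), 0, scene$noise_sd),
                                  nrow = nrow(img)))
  img <- pmin(pmax(img, 0), 1)
  round(img * 255) / 255
}

# render the filled region {0 <= z <= ztop(r)} onto a scene raster with
# 4x4 supersampling; halfwidth_fun maps height above baseline (mm) to
# signed horizontal extents (mm) around r = 0
.render_region <- function(scene, height_mm, left_fun, right_fun,
                           extent_mm) {
  ps <- scene$pixel_scale
  if (is.null(scene$image_size)) {
    cols <- ceiling(2 * extent_mm / ps * 1.25)
    rows <- ceiling(height_mm / ps * 1.25) + max(12L, ceiling(0.12 * height_mm / ps))
    baseline <- rows - max(10L, round(0.12 * rows))
  } else {
    rows <- scene$image_size[1]; cols <- scene$image_size[2]
    baseline <- if (is.null(scene$baseline_row))
      rows - max(10L, round(0.12 * rows)) else scene$baseline_row
  }
  if ((baseline - 1) * ps < height_mm)
    stop("scene raster too small for the rendered drop height")
  lv <- .render_levels
  img <- matrix(lv$bg, nrow = rows, ncol = cols)
  img[baseline:rows, ] <- lv$substrate
  col_apex <- (cols + 1) / 2  # r = 0 at the raster centre column
  # bounding box in pixels
  r0 <- max(1L, floor(baseline - 1 - height_mm / ps) - 2L)
  off <- c(-0.375, -0.125, 0.125, 0.375)
  half_px <- ceiling(extent_mm / ps) + 2L
  c_lo <- max(1L, floor(col_apex - half_px))
  c_hi <- min(cols, ceiling(col_apex + half_px))
  rows_idx <- r0:(baseline - 1L)
  cols_idx <- c_lo:c_hi
  cov <- matrix(0, nrow = length(rows_idx), ncol = length(cols_idx))
  for (dy in off) {
    z <- (baseline - 0.5 - (rows_idx + dy)) * ps   # height above baseline, mm
    inz <- z >= 0 & z <= height_mm
    xl <- rep(NA_real_, length(z)); xr <- xl
    xl[inz] <- left_fun(z[inz]); xr[inz] <- right_fun(z[inz])
    for (dx in off) {
      xm <- (cols_idx + dx - col_apex) * ps        # signed mm from centre
      inside <- outer(seq_along(z), seq_along(xm), function(i, j)
        inz[i] & xm[j] >= xl[i] & xm[j] <= xr[i])
      inside[is.na(inside)] <- FALSE
      cov <- cov + inside
    }
  }
  cov <- cov / 16
  img[rows_idx, cols_idx] <- lv$bg + (lv$drop - lv$bg) * cov
  img[baseline:rows, ] <- lv$substrate
  list(image = img, baseline_row = baseline, col_apex = col_apex,
       rows = rows, cols = cols)
}

#' Render a synthetic side-view image of a sessile droplet
#'
#' Solves the axisymmetric Young-Laplace shape for the requested
#' volume and contact angle, and rasterizes its filled silhouette
#' (dark drop on a light background above a darker substrate) with
#' 4x4 supersampled anti-aliasing and optional additive Gaussian
#' noise. The returned ground truth records the exact rendered
#' geometry.
#'
#' @param volume drop volume, microlitres.
#' @param theta contact angle, degrees (5 to 175; silhouette rendering
#'   supports up to 90).
#' @param fluid a [fluid_properties()] object.
#' @param scene a [synthetic_scene()].
#' @param g gravitational acceleration, m/s^2 (0 gives the
#'   spherical-cap silhouette).
#' @return List with `image` (rows x cols matrix, grayscale 0-1),
#'   `truth` (volume, theta_left/right, length, height, edge
#'   positions in mm, baseline_row), and `scene`.
#' @export
gen_sessile_image <- function(volume, theta, fluid, scene = synthetic_scene(),
                              g = 9.81) {
  stopifnot(volume > 0, theta >= 5, theta <= 175)
  if (theta > 90)
    stop("silhouette rendering supports contact angles up to 90 degrees")
  sh <- solve_for(volume, theta, fluid, g = g)
  m <- attr(sh, "metrics")
  # height above baseline z -> halfwidth, via depth below apex
  zmm <- sh$z * 1e3; xmm <- sh$x * 1e3
  h <- m$height
  halfwidth <- function(z) stats::approx(zmm, xmm, pmin(pmax(h - z, 0), max(zmm)),
                                         rule = 2)$y
  r <- .render_region(scene, h, function(z) -halfwidth(z), halfwidth,
                      m$contact_radius)
  img <- .finish_image(r$image, scene)
  r_apex <- (r$col_apex - 1) * scene$pixel_scale
  truth <- list(volume = volume, theta_left = theta, theta_right = theta,
                length = 2 * m$contact_radius, height = h,
                edge_left = r_apex - m$contact_radius,
                edge_right = r_apex + m$contact_radius,
                apex_r = r_apex, baseline_row = r$baseline_row,
                pixel_scale = scene$pixel_scale)
  list(image = img, truth = truth, scene = scene)
}

# pinned-mode geometry: contact angle that holds contact radius a0 (mm)
# at the given volume; errors if the angle falls below min_theta
.theta_for_radius <- function(volume, a0, fluid, g, theta_guess,
                              min_theta = 2) {
  fn <- function(th) attr(solve_for(volume, th, fluid, g = g),
                          "metrics")$contact_radius - a0
  lo <- max(min_theta, 5); hi <- min(175, max(theta_guess + 10, 30))
  fhi <- fn(hi); flo <- fn(lo)
  # radius decreases with theta at fixed volume
  if (flo < 0)
    stop(sprintf("evaporation parameters drive theta below %g degrees", min_theta))
  if (fhi > 0) hi <- 175
  stats::uniroot(fn, c(lo, hi), tol = 1e-3)$root
}

#' Generate a synthetic evaporation image series
#'
#' Volumes decay exactly affinely, v(t) = v0 + slope t, sampled every
#' `dt` seconds over `duration`. In `pinned` mode the contact-line
#' length is held fixed and the contact angle falls; in `depinning`
#' mode the drop evaporates pinned until the angle reaches
#' `theta_pin`, after which the angle is held and the contact line
#' recedes.
#'
#' @param v0 initial volume, microlitres.
#' @param slope volume rate, microlitres per second (negative).
#' @param dt frame interval, seconds.
#' @param duration total duration, seconds; the volume must stay at or
#'   above 5% of `v0` throughout.
#' @param mode `"pinned"` or `"depinning"`.
#' @param scene a [synthetic_scene()].
#' @param fluid a [fluid_properties()] object.
#' @param theta0 initial contact angle, degrees.
#' @param theta_pin depinning threshold angle, degrees (depinning mode).
#' @param g gravitational acceleration, m/s^2.
#' @param render if `FALSE`, skip rasterization and return geometry
#'   ground truth only (fast).
#' @return List of frames, each with `time`, `image` (or `NULL`) and
#'   `truth` as in [gen_sessile_image()].
#' @export
gen_evaporation_series <- function(v0, slope, dt, duration,
                                   mode = c("pinned", "depinning"),
                                   scene = synthetic_scene(),
                                   fluid, theta0 = 40, theta_pin = 25,
                                   g = 9.81, render = TRUE) {
  mode <- match.arg(mode)
  stopifnot(v0 > 0, slope <= 0, dt > 0, duration >= 0)
  times <- seq(0, duration, by = dt)
  vols <- v0 + slope * times
  if (any(vols < 0.05 * v0))
    stop(sprintf("volume drops below 5%% of v0 within the duration (final %g uL)",
                 min(vols)))
  sh0 <- solve_for(v0, theta0, fluid, g = g)
  a0 <- attr(sh0, "metrics")$contact_radius
  # fix the raster across frames so the series is a consistent video
  scene_fixed <- scene
  if (is.null(scene$image_size)) {
    probe <- .render_region(scene, attr(sh0, "metrics")$height,
                            function(z) 0 * z, function(z) 0 * z, a0)
    scene_fixed$image_size <- c(probe$rows, probe$cols)
    scene_fixed$baseline_row <- probe$baseline_row
  }
  th_prev <- theta0
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    v <- vols[i]
    if (i > 1 && vols[i] == vols[i - 1]) {
      # unchanged volume: geometry is identical by construction
      th <- th_prev
    } else if (mode == "pinned") {
      th <- if (i == 1) theta0 else
        .theta_for_radius(v, a0, fluid, g, th_prev)
    } else {
      th <- if (i == 1) theta0 else
        tryCatch(.theta_for_radius(v, a0, fluid, g, th_prev,
                                   min_theta = theta_pin),
                 error = function(e) theta_pin)
    }
    if (th < 2) stop("evaporation parameters drive theta below 2 degrees")
    th_prev <- th
    if (render) {
      fr <- gen_sessile_image(v, th, fluid, scene_fixed, g = g)
    } else {
      m <- attr(solve_for(v, th, fluid, g = g), "metrics")
      fr <- list(image = NULL,
                 truth = list(volume = v, theta_left = th, theta_right = th,
                              length = 2 * m$contact_radius, height = m$height,
                              edge_left = -m$contact_radius,
                              edge_right = m$contact_radius,
                              pixel_scale = scene$pixel_scale),
                 scene = scene_fixed)
    }
    fr$time <- times[i]
    frames[[i]] <- fr
  }
  frames
}

#' Generate a synthetic centrifugal rotation-ramp series
#'
#' Emulates a forced-wetting run: rotation speed increases from 0 at
#' `ramp_rate` up to `rs_max`. The front contact angle rises linearly
#' from `theta0` to the advancing plateau `theta_adv` reached at
#' `rs_spread`; the rear angle falls to the receding plateau
#' `theta_rec` reached at `rs_slide` (or at `rs_rec` when the rear
#' stays permanently pinned). The front edge advances after the
#' spreading onset; the rear edge moves only after the sliding onset,
#' never in pinned-rear mode.
#'
#' @param targets list with `theta_adv`, `rs_spread`, `theta_rec`, and
#'   either `rs_slide` (rpm) or `rs_slide = NA` with `rs_rec` (rpm,
#'   speed at which the rear angle reaches its plateau) for a
#'   permanently pinned rear.
#' @param ramp_rate ramp, rpm per second (one frame per second).
#' @param rs_max final rotation speed, rpm.
#' @param theta0 initial (static) contact angle, degrees.
#' @param L0 initial droplet length, mm.
#' @param advance_rate front-edge speed after spreading onset,
#'   fraction of `L0` per rpm.
#' @param slide_rate rear-edge speed after sliding onset, fraction of
#'   `L0` per rpm.
#' @param r_radial radial distance of the droplet from the rotation
#'   axis, m (for the tangential acceleration of each frame).
#' @param scene a [synthetic_scene()] (used only when `render = TRUE`).
#' @param render if `TRUE`, rasterize each frame as an asymmetric
#'   silhouette (cubic profile honouring both contact angles).
#' @return Data frame of per-frame ground truth (class `ramp_frames`):
#'   `rs`, `a_T`, `theta_front`, `theta_rear`, `edge_front`,
#'   `edge_rear`, `length`, `height`; when `render = TRUE` the images
#'   are attached as attribute `images` (list of matrices).
#' @export
gen_rotation_ramp <- function(targets, ramp_rate = 1, rs_max = 100,
                              theta0 = 40, L0 = 6, advance_rate = 0.05,
                              slide_rate = 0.05, r_radial = 0.25,
                              scene = synthetic_scene(pixel_scale = 0.02),
                              render = FALSE) {
  ta <- targets$theta_adv; tr <- targets$theta_rec
  rs_sp <- targets$rs_spread; rs_sl <- targets$rs_slide
  pinned <- is.null(rs_sl) || is.na(rs_sl)
  rs_rec <- if (pinned) targets$rs_rec else rs_sl
  if (is.null(rs_rec) || is.na(rs_rec))
    stop("pinned-rear targets need rs_rec (speed at which the rear plateau is reached)")
  if (ta <= tr) stop("theta_adv must exceed theta_rec (hysteresis must be positive)")
  stopifnot(rs_sp > 0, ta >= theta0, tr <= theta0, rs_max > 0, ramp_rate > 0)
  if (!pinned) stopifnot(rs_sp < rs_sl, rs_sl <= rs_max)
  rs <- seq(0, rs_max, by = ramp_rate)
  theta_front <- theta0 + (ta - theta0) * pmin(rs / rs_sp, 1)
  theta_rear <- theta0 - (theta0 - tr) * pmin(rs / rs_rec, 1)
  edge_front <- L0 + advance_rate * L0 * pmax(rs - rs_sp, 0)
  edge_rear <- if (pinned) rep(0, length(rs)) else
    slide_rate * L0 * pmax(rs - rs_sl, 0)
  len <- edge_front - edge_rear
  # cubic silhouette height for the ground truth
  h <- vapply(seq_along(rs), function(i)
    .cubic_profile_height(len[i], theta_rear[i], theta_front[i]), 0)
  out <- data.frame(rs = rs, a_T = rs_to_aT(rs, r_radial),
                    theta_front = theta_front, theta_rear = theta_rear,
                    edge_front = edge_front, edge_rear = edge_rear,
                    length = len, height = h)
  if (render) {
    imgs <- lapply(seq_along(rs), function(i) {
      .render_asym_frame(scene, edge_rear[i], edge_front[i],
                         theta_rear[i], theta_front[i])
    })
    attr(out, "images") <- imgs
  }
  attr(out, "L0") <- L0
  attr(out, "r_radial") <- r_radial
  attr(out, "pinned_rear") <- pinned
  class(out) <- c("ramp_frames", "data.frame")
  out
}

# cubic drop profile z(u), u in [0,1] over length L, honouring the rear
# (left) and front (right) contact angles; returns coefficients
.cubic_profile_coef <- function(L, theta_rear, theta_front) {
  s0 <- L * tan(theta_rear * pi / 180)
  s1 <- -L * tan(theta_front * pi / 180)
  c(a3 = s0 + s1, a2 = -2 * s0 - s1, a1 = s0)
}
.cubic_profile_height <- function(L, theta_rear, theta_front) {
  cf <- .cubic_profile_coef(L, theta_rear, theta_front)
  u <- seq(0, 1, length.out = 400)
  max(cf["a3"] * u^3 + cf["a2"] * u^2 + cf["a1"] * u)
}
.render_asym_frame <- function(scene, edge_rear, edge_front,
                               theta_rear, theta_front) {
  L <- edge_front - edge_rear
  cf <- .cubic_profile_coef(L, theta_rear, theta_front)
  u <- seq(0, 1, length.out = 2000)
  zc <- cf["a3"] * u^3 + cf["a2"] * u^2 + cf["a1"] * u
  h <- max(zc)
  mid <- (edge_rear + edge_front) / 2
  # invert z(u) on each monotone branch for left/right extents
  iapex <- which.max(zc)
  left_fun <- function(z) stats::approx(zc[1:iapex], u[1:iapex] * L + edge_rear - mid,
                                        pmin(z, h), rule = 2)$y
  right_fun <- function(z) stats::approx(rev(zc[iapex:length(zc)]),
                                         rev(u[iapex:length(zc)] * L + edge_rear - mid),
                                         pmin(z, h), rule = 2)$y
  r <- .render_region(scene, h, left_fun, right_fun, L / 2 + abs(mid) * 0)
  .finish_image(r$image, scene)
}

#' Generate a synthetic power-law flow curve
#'
#' Viscosity eta(gamma_dot) = K gamma_dot^(n-1), optionally with
#' multiplicative Gaussian noise, at log-spaced shear rates.
#'
#' @param K consistency index, Pa.s^n.
#' @param n flow behaviour index (0 < n <= 1.5).
#' @param rate_range shear-rate range, 1/s (pair).
#' @param points number of log-spaced shear rates.
#' @param noise_rel relative noise level (fraction).
#' @param seed integer RNG seed.
#' @param temperature metadata, degrees C.
#' @return A `flow_curve`: data frame with `shear_rate` (1/s) and
#'   `viscosity` (Pa.s), attribute `temperature`.
#' @export
gen_flow_curve <- function(K, n, rate_range = c(10, 100), points = 10,
                           noise_rel = 0, seed = 1L, temperature = 25) {
  stopifnot(K > 0, n > 0, n <= 1.5, all(rate_range > 0), points >= 2)
  rates <- exp(seq(log(rate_range[1]), log(rate_range[2]),
                   length.out = points))
  eta <- K * rates^(n - 1)
  if (noise_rel > 0)
    eta <- eta * (1 + with_seed(seed, stats::rnorm(points, 0, noise_rel)))
  out <- data.frame(shear_rate = rates, viscosity = eta)
  attr(out, "temperature") <- temperature
  class(out) <- c("flow_curve", "data.frame")
  out
}

#' Generate a synthetic two-channel live/dead cell field
#'
#' Places rod-like cells (ellipses of 3:1 aspect ratio) uniformly at
#' random in each channel, with rasterized areas constrained to the
#' requested range and non-overlapping placement, and records the
#' exact per-channel counts, centroids and areas as ground truth.
#' Green encodes live (membrane-intact) cells, red dead cells.
#'
#' @param n_green,n_red number of cells per channel.
#' @param area_range_px cell area range, px^2.
#' @param field `c(rows, cols)` of the field, px.
#' @param pixel_scale edge length of a pixel, micrometres (default
#'   0.566 so that 10 px^2 = 3.2 um^2).
#' @param seed integer RNG seed.
#' @param min_gap minimum empty margin between cells, px.
#' @return List with `green` and `red` intensity matrices (0-1) and
#'   `truth` (counts and an object table with channel, centroid and
#'   rendered pixel area).
#' @export
gen_cell_image <- function(n_green, n_red, area_range_px = c(10, 30),
                           field = c(256, 256), pixel_scale = 0.566,
                           seed = 1L, min_gap = 2) {
  stopifnot(n_green >= 0, n_red >= 0, area_range_px[1] < area_range_px[2])
  mean_area <- mean(area_range_px)
  if ((n_green + n_red) * mean_area >= 0.3 * prod(field))
    stop("total requested cell area exceeds 30% of the field")
  with_seed(seed, {
    occ <- matrix(FALSE, field[1], field[2])
    chans <- list(green = matrix(0, field[1], field[2]),
                  red = matrix(0, field[1], field[2]))
    objs <- list()
    for (ch in c("green", "red")) {
      ntarget <- if (ch == "green") n_green else n_red
      placed <- 0; attempts <- 0
      while (placed < ntarget) {
        attempts <- attempts + 1
        if (attempts > 500 * max(ntarget, 1))
          stop("could not place all cells without overlap")
        area <- stats::runif(1, area_range_px[1], area_range_px[2])
        bb <- sqrt(area / (3 * pi)); aa <- 3 * bb   # 3:1 rod
        ang <- stats::runif(1, 0, pi)
        r0 <- stats::runif(1, aa + min_gap + 1, field[1] - aa - min_gap - 1)
        c0 <- stats::runif(1, aa + min_gap + 1, field[2] - aa - min_gap - 1)
        rr <- floor(r0 - aa - min_gap):ceiling(r0 + aa + min_gap)
        cc <- floor(c0 - aa - min_gap):ceiling(c0 + aa + min_gap)
        dx <- outer(rr - r0, rep(1, length(cc)))
        dy <- outer(rep(1, length(rr)), cc - c0)
        xr <- dx * cos(ang) + dy * sin(ang)
        yr <- -dx * sin(ang) + dy * cos(ang)
        inside <- (xr / aa)^2 + (yr / bb)^2 <= 1
        npix <- sum(inside)
        if (npix < area_range_px[1] || npix > area_range_px[2]) next
        # keep-out: same ellipse dilated by the gap
        guard <- (xr / (aa + min_gap))^2 + (yr / (bb + min_gap))^2 <= 1
        if (any(occ[rr, cc][guard])) next
        occ[rr, cc][guard] <- TRUE
        m <- chans[[ch]][rr, cc]
        m[inside] <- 1
        chans[[ch]][rr, cc] <- m
        placed <- placed + 1
        objs[[length(objs) + 1]] <-
          data.frame(channel = ch, row = r0, col = c0, area_px = npix)
      }
    }
    truth <- list(n_green = n_green, n_red = n_red,
                  objects = if (length(objs)) do.call(rbind, objs) else
                    data.frame(channel = character(), row = numeric(),
                               col = numeric(), area_px = numeric()),
                  field = field, pixel_scale = pixel_scale)
    list(green = chans$green, red = chans$red, truth = truth)
  })
}

#' Render a synthetic top-view droplet footprint
#'
#' Dark elliptical footprint on a light background, for testing
#' top-view contour extraction.
#'
#' @param semi_axes_mm `c(a, b)` semi-axes of the footprint, mm.
#' @param scene a [synthetic_scene()]; `image_size` must be given or
#'   is sized automatically.
#' @return List with `image` and `truth` (semi-axes, centre, area and
#'   perimeter in mm; perimeter by Ramanujan's approximation).
#' @export
gen_footprint_image <- function(semi_axes_mm, scene = synthetic_scene(pixel_scale = 0.02)) {
  stopifnot(length(semi_axes_mm) == 2L, all(semi_axes_mm > 0))
  ps <- scene$pixel_scale
  a <- semi_axes_mm[1]; b <- semi_axes_mm[2]
  if (is.null(scene$image_size)) {
    rows <- ceiling(2 * b / ps * 1.4); cols <- ceiling(2 * a / ps * 1.4)
  } else {
    rows <- scene$image_size[1]; cols <- scene$image_size[2]
  }
  r0 <- (rows + 1) / 2; c0 <- (cols + 1) / 2
  off <- c(-0.375, -0.125, 0.125, 0.375)
  cov <- matrix(0, rows, cols)
  for (dy in off) for (dx in off) {
    yy <- ((seq_len(rows) + dy) - r0) * ps
    xx <- ((seq_len(cols) + dx) - c0) * ps
    cov <- cov + outer(yy, xx, function(y, x) (x / a)^2 + (y / b)^2 <= 1)
  }
  cov <- cov / 16
  lv <- .render_levels
  img <- .finish_image(lv$bg + (lv$drop - lv$bg) * cov, scene)
  hsum <- (a - b)^2 / (a + b)^2
  perim <- pi * (a + b) * (1 + 3 * hsum / (10 + sqrt(4 - 3 * hsum)))
  list(image = img,
       truth = list(semi_axes = semi_axes_mm, centre_px = c(r0, c0),
                    area = pi * a * b, perimeter = perim,
                    pixel_scale = ps))
}
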