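#' Integrate the axisymmetric Young-Laplace sessile-drop shape
#'
#' Solves the Bashforth-Adams arc-length system for an axisymmetric
#' sessile drop,
#'   dx/ds = cos(phi), dz/ds = sin(phi),
#'   dphi/ds = 2 b + c z - sin(phi) / x,
#' with the apex limit dphi/ds -> b as x -> 0. `x` is the radial
#' coordinate, `z` the depth below the apex, and `phi` the tangent
#' angle. The integration is carried out with `phi` as the independent
#' variable, which is valid while `phi` is strictly increasing (always
#' the case for sessile shapes up to 180 degrees) and makes truncation
#' at a target contact angle exact.
#'
#' @param b apex curvature, 1/m.
#' @param c capillary parameter rho * g / sigma, 1/m^2 (0 for the
#'   zero-gravity spherical-cap limit).
#' @param phi_max tangent angle at which to stop, radians.
#' @param n number of output samples along the arc.
#' @param rtol,atol relative/absolute tolerances passed to the ODE solver.
#' @return An object of class `yl_shape`: a data frame with columns
#'   `s`, `x`, `z`, `phi` (SI units, apex at the first row) and
#'   attributes `b` and `c`.
#' @examples
#' sh <- integrate_shape(b = 500, c = 0, phi_max = pi / 2)
#' max(abs(sh$x - sin(sh$phi) / 500))  # circular arc of radius 1/b
#' @export
integrate_shape <- function(b, c = 0, phi_max = pi / 2, n = 400,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(b > 0, c >= 0, phi_max > 0, phi_max < pi)
  phi0 <- min(1e-5, phi_max / 50)
  # series start on the osculating sphere of radius 1/b
  y0 <- c(x = sin(phi0) / b, z = (1 - cos(phi0)) / b, s = phi0 / b)
  rhs <- function(phi, y, parms) {
    f <- 2 * b + c * y[["z"]] - sin(phi) / y[["x"]]
    if (!is.finite(f) || f <= 0) f <- NA_real_
    list(c(cos(phi) / f, sin(phi) / f, 1 / f))
  }
  phis <- seq(phi0, phi_max, length.out = n)
  sol <- deSolve::ode(y = y0, times = phis, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  names(sol) <- c("phi", "x", "z", "s")
  if (anyNA(sol) || nrow(sol) < n) {
    bad <- if (anyNA(sol$x)) sol$phi[which(is.na(sol$x))[1]] else max(sol$phi)
    stop(sprintf(paste0("Young-Laplace integration failed: phi stops being ",
                        "monotone near phi = %.3f rad (re-entrant shape for ",
                        "b = %g 1/m, c = %g 1/m^2)"), bad, b, c))
  }
  out <- rbind(data.frame(s = 0, x = 0, z = 0, phi = 0),
               sol[, c("s", "x", "z", "phi")])
  attr(out, "b") <- b
  attr(out, "c") <- c
  class(out) <- c("yl_shape", "data.frame")
  out
}

#' Geometric metrics of a Young-Laplace shape truncated at a contact angle
#'
#' Truncates an integrated sessile shape at tangent angle `theta`
#' (the contact angle, measured through the liquid) and reports the
#' volume of the solid of revolution, the contact-line radius, and the
#' drop height.
#'
#' @param shape a `yl_shape` from [integrate_shape()].
#' @param theta contact angle at which to truncate, degrees; must lie
#'   within the integrated `phi` range.
#' @return List with `volume` (microlitres), `contact_radius` (mm) and
#'   `height` (mm).
#' @examples
#' sh <- integrate_shape(b = 1000, c = 0, phi_max = pi / 2)
#' shape_metrics(sh, 90)$volume  # hemisphere of radius 1 mm: (2/3) pi
#' @export
shape_metrics <- function(shape, theta) {
  stopifnot(inherits(shape, "yl_shape"), theta > 0)
  th <- theta * pi / 180
  if (th > max(shape$phi) + 1e-12)
    stop(sprintf("theta = %g deg exceeds the integrated phi range (%g deg)",
                 theta, max(shape$phi) * 180 / pi))
  keep <- shape$phi <= th
  xs <- shape$x[keep]; zs <- shape$z[keep]
  xt <- stats::approx(shape$phi, shape$x, th)$y
  zt <- stats::approx(shape$phi, shape$z, th)$y
  if (abs(zt - zs[length(zs)]) > 0) {
    xs <- c(xs, xt); zs <- c(zs, zt)
  }
  # solid of revolution: V = int pi x^2 dz (trapezoid on the arc samples)
  v <- sum(pi * (xs[-1]^2 + xs[-length(xs)]^2) / 2 * diff(zs))
  list(volume = v * 1e9, contact_radius = xt * 1e3, height = zt * 1e3)
}

# zero-gravity spherical-cap closed forms (apex curvature b in 1/m)
cap_volume_m3 <- function(b, theta_rad) {
  pi / (3 * b^3) * (1 - cos(theta_rad))^2 * (2 + cos(theta_rad))
}
cap_b_from_volume <- function(volume_m3, theta_rad) {
  (pi * (1 - cos(theta_rad))^2 * (2 + cos(theta_rad)) / (3 * volume_m3))^(1 / 3)
}

#' Solve the inverse drop-shape problem: apex curvature from volume and angle
#'
#' Finds the apex curvature `b` such that the axisymmetric
#' Young-Laplace shape truncated at contact angle `theta` encloses the
#' requested volume, by bracketed root search started from the
#' spherical-cap inverse. The capillary parameter is
#' c = rho g / sigma from the fluid properties.
#'
#' @param volume target drop volume, microlitres.
#' @param theta contact angle, degrees (5 to 175).
#' @param fluid a [fluid_properties()] object (density, surface tension).
#' @param g gravitational acceleration, m/s^2; set 0 for the
#'   spherical-cap limit.
#' @param tol_rel relative volume tolerance of the root search.
#' @param n samples along the arc passed to [integrate_shape()].
#' @return A `yl_shape` truncated at `theta`, with attributes `b`,
#'   `c`, `theta` and `metrics` (the [shape_metrics()] of the solution).
#' @examples
#' w <- fluid_properties(997, 0.072)
#' sh <- solve_for(35, 40, w)
#' attr(sh, "metrics")$volume  # 35 within 0.1%
#' @export
solve_for <- function(volume, theta, fluid, g = 9.81, tol_rel = 1e-6,
                      n = 400) {
  stopifnot(volume > 0, theta >= 5, theta <= 175,
            inherits(fluid, "fluid_properties"))
  cc <- fluid$density * g / fluid$surface_tension
  th <- theta * pi / 180
  v_m3 <- volume * 1e-9
  b0 <- cap_b_from_volume(v_m3, th)
  fn <- function(b) {
    sh <- integrate_shape(b, cc, phi_max = th, n = n)
    shape_metrics(sh, theta)$volume - volume
  }
  lo <- b0 / 2; hi <- 2 * b0
  flo <- fn(lo); fhi <- fn(hi); tries <- 0
  while (sign(flo) == sign(fhi) && tries < 8) {
    lo <- lo / 2; hi <- hi * 2
    flo <- tryCatch(fn(lo), error = function(e) NA_real_)
    fhi <- tryCatch(fn(hi), error = function(e) NA_real_)
    if (is.na(flo) || is.na(fhi))
      stop(sprintf("no curvature bracket found for volume = %g uL, theta = %g deg (scanned b in [%g, %g] 1/m)",
                   volume, theta, lo, hi))
    tries <- tries + 1
  }
  if (sign(flo) == sign(fhi))
    stop(sprintf("no curvature bracket found for volume = %g uL, theta = %g deg (scanned b in [%g, %g] 1/m)",
                 volume, theta, lo, hi))
  root <- stats::uniroot(fn, c(lo, hi), tol = b0 * tol_rel)$root
  sh <- integrate_shape(root, cc, phi_max = th, n = n)
  attr(sh, "theta") <- theta
  attr(sh, "metrics") <- shape_metrics(sh, theta)
  sh
}

#' Export a shape as CSV
#'
#' Writes the arc samples (s, x, z, phi) of a `yl_shape` to a CSV file.
#'
#' @param shape a `yl_shape`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_csv <- function(shape, path) {
  stopifnot(inherits(shape, "yl_shape"))
  utils::write.csv(as.data.frame(shape)[, c("s", "x", "z", "phi")],
                   path, row.names = FALSE)
  invisible(path)
}
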