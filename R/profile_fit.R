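#' Estimate droplet volume by Young-Laplace profile fitting
#'
#' Fits a measured side profile to the numerical solution of the
#' axisymmetric Young-Laplace equation, with the drop volume as the
#' fitting parameter. The profile is first symmetrized about the
#' midpoint of its contact points (average of the two flanks); the
#' apex curvature `b` is then searched by deterministic
#' golden-section minimization of the root-mean-square horizontal
#' distance between the measured flank and the model flank truncated
#' at the measured height. The search bracket is initialized from the
#' spherical-cap inverse of the measured length and height and
#' expanded by a fixed rule if the optimum lands on its edge.
#'
#' @param profile a `drop_profile` (mm units).
#' @param fluid a [fluid_properties()] object (density and surface
#'   tension set the capillary parameter).
#' @param g gravitational acceleration, m/s^2.
#' @param residual_ceiling warn-level ceiling on the rms residual,
#'   as a fraction of the drop height; above it the result is flagged
#'   non-axisymmetric.
#' @param n_grid number of height samples of the fitting grid.
#' @param tol_rel relative bracket width at which the golden-section
#'   search stops.
#' @return A `volume_fit` list: `volume` (uL), `b` (1/m),
#'   `rms_residual` (mm), `theta_implied` (degrees, the tangent angle
#'   at the truncation height) and `nonaxisymmetric` flag.
#' @export
fit_volume <- function(profile, fluid, g = 9.81, residual_ceiling = 0.05,
                       n_grid = 60, tol_rel = 1e-5) {
  stopifnot(inherits(profile, "drop_profile"),
            inherits(fluid, "fluid_properties"))
  edges <- attr(profile, "edges")
  mid <- mean(edges)
  L <- diff(edges)
  h <- max(profile$z)
  stopifnot(L > 0, h > 0)
  left <- profile[profile$r <= mid, ]
  right <- profile[profile$r >= mid, ]
  hc <- 0.995 * min(max(left$z), max(right$z))
  zg <- seq(0, hc, length.out = n_grid)
  # single-valued flanks: keep the outermost sample at each height
  xl <- stats::approx(left$z, mid - left$r, zg, rule = 2, ties = max)$y
  xr <- stats::approx(right$z, right$r - mid, zg, rule = 2, ties = max)$y
  xbar <- (xl + xr) / 2                       # symmetrized halfwidth, mm
  cc <- fluid$density * g / fluid$surface_tension
  model_flank <- function(b) {
    sh <- tryCatch(integrate_shape(b, cc, phi_max = 174 * pi / 180, n = 300),
                   error = function(e) NULL)
    if (is.null(sh)) return(NULL)
    zmm <- sh$z * 1e3; xmm <- sh$x * 1e3
    if (max(zmm) < h) return(NULL)            # shape shorter than the drop
    list(sh = sh, zmm = zmm, xmm = xmm)
  }
  objective <- function(b) {
    mf <- model_flank(b)
    if (is.null(mf)) return(1e6)
    xm <- stats::approx(mf$zmm, mf$xmm, h - zg)$y
    sqrt(mean((xm - xbar)^2))
  }
  # bracket from the spherical-cap inverse of (L, h)
  a <- L / 2
  b0 <- 2 * h / (h^2 + a^2) * 1e3             # 1/m
  lo <- b0 / 4; hi <- b0 * 4
  golden <- function(lo, hi) {
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- objective(x1); f2 <- objective(x2)
    while ((hi - lo) > tol_rel * b0) {
      if (f1 < f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- objective(x1)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- objective(x2)
      }
    }
    (lo + hi) / 2
  }
  for (expand in 1:4) {
    b_best <- golden(lo, hi)
    at_edge <- (b_best - lo) < 0.02 * (hi - lo) ||
               (hi - b_best) < 0.02 * (hi - lo)
    if (!at_edge) break
    lo <- lo / 4; hi <- hi * 4
  }
  mf <- model_flank(b_best)
  if (is.null(mf))
    stop("no apex-curvature bracket found for the measured profile")
  # truncate at the measured height and integrate the volume
  phi_h <- stats::approx(mf$zmm, mf$sh$phi, h)$y
  m <- shape_metrics(mf$sh, phi_h * 180 / pi)
  rms <- objective(b_best)
  flag <- rms > residual_ceiling * h
  if (flag)
    warning(sprintf("rms residual %.3g mm exceeds %g%% of the drop height; profile flagged non-axisymmetric",
                    rms, 100 * residual_ceiling))
  structure(list(volume = m$volume, b = b_best, rms_residual = rms,
                 theta_implied = phi_h * 180 / pi,
                 nonaxisymmetric = flag),
            class = "volume_fit")
}

#' @export
print.volume_fit <- function(x, ...) {
  cat(sprintf("<volume_fit> V = %.3f uL, b = %.1f 1/m, theta = %.1f deg, rms = %.4f mm%s\n",
              x$volume, x$b, x$theta_implied, x$rms_residual,
              if (x$nonaxisymmetric) " [non-axisymmetric]" else ""))
  invisible(x)
}
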