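#' Rig configuration for centrifugal forced-wetting runs
#'
#' Geometry and ramp settings of the rotating stage: droplets sit at
#' radial distance `r_radial` from the rotation axis and the speed is
#' ramped at `ramp_rate` up to `rs_max`. `char_length_Bo` is the
#' characteristic length used in the tangential Bond number (1 mm by
#' convention for drops of this size).
#'
#' @param r_radial radial distance of the droplet from the axis, m.
#' @param ramp_rate rotation-speed ramp, rpm/s.
#' @param rs_max maximum rotation speed, rpm.
#' @param char_length_Bo characteristic length for the Bond number, m.
#' @return An object of class `rig_config`.
#' @export
rig_config <- function(r_radial = 0.25, ramp_rate = 1, rs_max = 100,
                       char_length_Bo = 0.001) {
  stopifnot(r_radial > 0, ramp_rate > 0, rs_max > 0, char_length_Bo > 0)
  structure(list(r_radial = r_radial, ramp_rate = ramp_rate,
                 rs_max = rs_max, char_length_Bo = char_length_Bo),
            class = "rig_config")
}

#' Tangential acceleration from rotation speed
#'
#' a_T = omega^2 r with omega = 2 pi RS / 60.
#'
#' @param rs rotation speed, rpm (vectorized).
#' @param r_radial radial distance from the rotation axis, m.
#' @return Tangential acceleration, m/s^2.
#' @examples
#' rs_to_aT(100, 0.25)  # 27.4 m/s^2
#' @export
rs_to_aT <- function(rs, r_radial = 0.25) {
  stopifnot(all(rs >= 0), r_radial > 0)
  (2 * pi * rs / 60)^2 * r_radial
}

#' Tangential Bond number
#'
#' Bo_T = rho L^2 a_T / sigma: the ratio of the tangential body force
#' to the surface-tension force on the droplet. (With the
#' characteristic length squared the group is dimensionless.)
#'
#' @param fluid a [fluid_properties()] object.
#' @param L characteristic length, m (1 mm by convention).
#' @param a_T tangential acceleration, m/s^2.
#' @return Dimensionless tangential Bond number.
#' @examples
#' bond_number(fluid_properties(1000, 0.072), 0.001, 27.4)
#' @export
bond_number <- function(fluid, L, a_T) {
  stopifnot(inherits(fluid, "fluid_properties"), L > 0, all(a_T >= 0))
  fluid$density * L^2 * a_T / fluid$surface_tension
}

#' Sliding retention force from the critical tangential acceleration
#'
#' F_s = rho V a_T: the droplet mass times the critical tangential
#' acceleration at the onset of sliding equals the retention
#' (adhesion) force.
#'
#' @param fluid a [fluid_properties()] object.
#' @param volume droplet volume at the time of the test, microlitres.
#' @param aT_crit critical tangential acceleration, m/s^2.
#' @return Retention force, N.
#' @export
retention_force <- function(fluid, volume, aT_crit) {
  stopifnot(inherits(fluid, "fluid_properties"), volume > 0,
            all(aT_crit >= 0))
  fluid$density * volume * 1e-9 * aT_crit
}

#' Furmidge retention factor
#'
#' Inverts Furmidge's relation F_s = k R sigma (cos theta_r -
#' cos theta_a) for the retention factor k, given a characteristic
#' length R. cos(theta_r) - cos(theta_a) is the contact-angle
#' hysteresis.
#'
#' @param F_s retention force, N.
#' @param R characteristic length, m (initial or sliding droplet
#'   length).
#' @param sigma surface tension, N/m.
#' @param theta_adv advancing contact angle, degrees.
#' @param theta_rec receding contact angle, degrees; must be strictly
#'   below `theta_adv`.
#' @return Dimensionless retention factor k.
#' @examples
#' furmidge_k(2.4e-4, 6.1e-3, 0.072, 53, 15)
#' @export
furmidge_k <- function(F_s, R, sigma, theta_adv, theta_rec) {
  stopifnot(F_s >= 0, R > 0, sigma > 0)
  if (theta_adv <= theta_rec)
    stop("theta_adv must exceed theta_rec: zero or negative hysteresis")
  hyst <- cos(theta_rec * pi / 180) - cos(theta_adv * pi / 180)
  F_s / (R * sigma * hyst)
}

# rolling OLS slope of y against x over a centred window
.rolling_slope <- function(x, y, window = 5L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    xs <- x[lo:hi]; ys <- y[lo:hi]
    sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  }, 0)
}

# earliest x at the start of a persistent run of `moved`
.onset <- function(x, moved, persistence) {
  run <- 0L
  for (i in seq_along(moved)) {
    run <- if (moved[i]) run + 1L else 0L
    if (run >= persistence) return(x[i - persistence + 1L])
  }
  NA_real_
}

#' Detect spreading and sliding events in a rotation-ramp series
#'
#' From a rotation-speed-ordered series of per-frame geometry,
#' detects the spreading onset (first persistent advance of the front
#' edge), the sliding onset (first persistent motion of the rear
#' edge), and the advancing/receding contact-angle plateaus
#' (sliding-window slope below `plateau_tol`). A rear edge that never
#' moves is the permanently pinned regime: `rs_slide` is `NA` and the
#' receding angle is taken from the final rear-angle plateau. When
#' the pinned drop is squeezed out of the field of view, pass the
#' disappearance speed as `rs_disappear`; it is then used as the
#' sliding onset for the retention quantities.
#'
#' The force points toward increasing edge coordinates (front edge at
#' the larger coordinate).
#'
#' @param frames data frame with columns `rs` (rpm, increasing),
#'   `theta_front`, `theta_rear` (degrees), `edge_front`, `edge_rear`
#'   (mm); e.g. from [gen_rotation_ramp()] or measured frames.
#' @param plateau_tol plateau slope threshold, degrees per rpm.
#' @param motion_threshold edge-motion threshold, fraction of the
#'   initial length.
#' @param persistence consecutive frames the motion must persist.
#' @param window frames in the sliding window of the plateau slope.
#' @param fluid optional [fluid_properties()]; with `volume` enables
#'   the retention quantities.
#' @param volume droplet volume at the start of the ramp, microlitres.
#' @param rig a [rig_config()].
#' @param rs_disappear optional speed (rpm) at which a pinned-rear
#'   drop left the field of view, used as the critical speed.
#' @return A `wetting_events` list: `theta_adv`, `theta_rec`,
#'   `rs_spread`, `rs_slide`, `static`, `pinned_rear`, `L_initial`,
#'   `L_sliding` (mm), and, when fluid and volume are supplied,
#'   `aT_crit` (m/s^2), `Bo_T`, `F_s` (N), `k1`, `k2`.
#' @export
detect_events <- function(frames, plateau_tol = 0.1,
                          motion_threshold = 0.02, persistence = 2L,
                          window = 5L, fluid = NULL, volume = NULL,
                          rig = rig_config(), rs_disappear = NA_real_) {
  stopifnot(is.data.frame(frames), nrow(frames) >= 10,
            !is.unsorted(frames$rs))
  rs <- frames$rs
  L0 <- frames$edge_front[1] - frames$edge_rear[1]
  stopifnot(L0 > 0)
  disp_f <- frames$edge_front - frames$edge_front[1]
  disp_r <- frames$edge_rear - frames$edge_rear[1]
  rs_spread <- .onset(rs, disp_f > motion_threshold * L0, persistence)
  rs_slide <- .onset(rs, abs(disp_r) > motion_threshold * L0, persistence)
  static <- is.na(rs_spread)
  pinned_rear <- is.na(rs_slide)

  slope_f <- .rolling_slope(rs, frames$theta_front, window)
  slope_r <- .rolling_slope(rs, frames$theta_rear, window)
  plateau_f <- abs(slope_f) < plateau_tol
  plateau_r <- abs(slope_r) < plateau_tol

  theta_adv <- NA_real_
  if (!static) {
    sel <- plateau_f & rs >= rs_spread
    if (!any(sel)) stop("no advancing-angle plateau found after the spreading onset")
    theta_adv <- mean(frames$theta_front[sel])
  }
  if (pinned_rear) {
    # last contiguous plateau run of the rear angle
    runs <- rle(plateau_r)
    if (!any(runs$values)) stop("no receding-angle plateau found (pinned rear)")
    ends <- cumsum(runs$lengths)
    i_run <- max(which(runs$values))
    sel <- (ends[i_run] - runs$lengths[i_run] + 1L):ends[i_run]
    theta_rec <- mean(frames$theta_rear[sel])
  } else {
    sel <- plateau_r & rs >= rs_slide
    if (!any(sel)) stop("no receding-angle plateau found after the sliding onset")
    theta_rec <- mean(frames$theta_rear[sel])
  }

  rs_crit <- if (!pinned_rear) rs_slide else rs_disappear
  L_initial <- L0
  L_sliding <- if (!pinned_rear) {
    i <- which(rs >= rs_slide)[1]
    frames$edge_front[i] - frames$edge_rear[i]
  } else {
    frames$edge_front[nrow(frames)] - frames$edge_rear[nrow(frames)]
  }

  ev <- list(theta_adv = theta_adv, theta_rec = theta_rec,
             rs_spread = rs_spread, rs_slide = rs_slide,
             static = static, pinned_rear = pinned_rear,
             L_initial = L_initial, L_sliding = L_sliding)
  if (!is.null(fluid) && !is.null(volume) && !is.na(rs_crit) &&
      !is.na(theta_adv)) {
    aT <- rs_to_aT(rs_crit, rig$r_radial)
    ev$aT_crit <- aT
    ev$Bo_T <- bond_number(fluid, rig$char_length_Bo, aT)
    ev$F_s <- retention_force(fluid, volume, aT)
    ev$k1 <- furmidge_k(ev$F_s, L_initial * 1e-3, fluid$surface_tension,
                        theta_adv, theta_rec)
    ev$k2 <- furmidge_k(ev$F_s, L_sliding * 1e-3, fluid$surface_tension,
                        theta_adv, theta_rec)
  }
  structure(ev, class = "wetting_events")
}

#' @export
print.wetting_events <- function(x, ...) {
  cat("<wetting_events>\n")
  cat(sprintf("  theta_adv = %.1f deg, theta_rec = %.1f deg\n",
              x$theta_adv, x$theta_rec))
  cat(sprintf("  spreading at %s rpm, sliding at %s rpm%s\n",
              format(x$rs_spread), format(x$rs_slide),
              if (isTRUE(x$pinned_rear)) " (rear pinned)" else ""))
  if (!is.null(x$F_s))
    cat(sprintf("  aT = %.3g m/s^2, Bo_T = %.3g, F_s = %.3g N, k1 = %.2f, k2 = %.2f\n",
                x$aT_crit, x$Bo_T, x$F_s, x$k1, x$k2))
  invisible(x)
}
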