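#' Linear fit of droplet volume against evaporation time
#'
#' Ordinary least squares of volume on time over an optional time
#' window. By default the window is restricted to 0-3000 s: beyond
#' 50 minutes the little liquid left makes the volume readings flat
#' and noisy, so the linear regime ends there; pass `window = NULL`
#' to use every point.
#'
#' @param times sample times, seconds.
#' @param volumes fitted droplet volumes, microlitres.
#' @param window `c(min, max)` time range to fit, seconds, or `NULL`
#'   for all points.
#' @return List with `slope` (uL/s), `intercept` (uL) and
#'   `r_squared`. A zero-variance response has `r_squared = 0` by
#'   convention.
#' @examples
#' t <- seq(0, 3000, 300)
#' fit_linear_volume(t, 29.9 - 0.01 * t)
#' @export
fit_linear_volume <- function(times, volumes, window = c(0, 3000)) {
  stopifnot(length(times) == length(volumes))
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; volumes <- volumes[keep]
  }
  if (length(times) < 3) stop("need at least 3 points in the fit window")
  if (stats::var(times) == 0) stop("degenerate fit: all times are equal")
  fit <- stats::lm(volumes ~ times)
  cf <- stats::coef(fit)
  sst <- sum((volumes - mean(volumes))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = cf[["times"]], intercept = cf[["(Intercept)"]],
       r_squared = r2)
}

#' Normalize droplet length and height trajectories
#'
#' Divides each series by its first (t = 0) value, the form in which
#' contact-line pinning is read off: a pinned contact line keeps the
#' normalized length at 1 while the height falls.
#'
#' @param times sample times, seconds.
#' @param lengths droplet lengths, mm.
#' @param heights droplet heights, mm.
#' @return Data frame with `time`, `normalized_length`,
#'   `normalized_height`.
#' @export
normalize_trajectories <- function(times, lengths, heights) {
  stopifnot(length(times) == length(lengths),
            length(times) == length(heights))
  if (lengths[1] <= 0 || heights[1] <= 0)
    stop("first frame must have positive length and height")
  data.frame(time = times,
             normalized_length = lengths / lengths[1],
             normalized_height = heights / heights[1])
}

#' Detect contact-line depinning in an evaporation series
#'
#' The contact line is declared depinned at the earliest time at
#' which either edge has moved inward by more than
#' `rel_threshold` times the initial length and stays moved for at
#' least `persistence` consecutive frames. Single-frame jitter below
#' the persistence requirement is ignored. The detection is invariant
#' to a uniform translation of all edge positions.
#'
#' @param times frame times, seconds.
#' @param edge_left,edge_right edge positions, mm (left < right).
#' @param rel_threshold inward displacement threshold as a fraction
#'   of the initial length (default 0.02).
#' @param persistence number of consecutive frames the displacement
#'   must persist (default 2).
#' @return Depinning time in seconds, or `NA_real_` if the contact
#'   line never depins.
#' @export
detect_depinning <- function(times, edge_left, edge_right,
                             rel_threshold = 0.02, persistence = 2L) {
  n <- length(times)
  stopifnot(length(edge_left) == n, length(edge_right) == n,
            n >= persistence + 1)
  L0 <- edge_right[1] - edge_left[1]
  stopifnot(L0 > 0)
  inward <- pmax(edge_left - edge_left[1], edge_right[1] - edge_right)
  moved <- inward > rel_threshold * L0
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (moved[i]) run + 1L else 0L
    if (run >= persistence) return(times[i - persistence + 1L])
  }
  NA_real_
}

#' Summarize an evaporation series
#'
#' Bundles the linear volume fit, the normalized trajectories and the
#' depinning detection for a measured series of per-frame geometry.
#'
#' @param times frame times, seconds.
#' @param geometry data frame with columns `volume`, `length`,
#'   `height`, `edge_left`, `edge_right` (uL / mm).
#' @param window fit window passed to [fit_linear_volume()].
#' @param rel_threshold,persistence passed to [detect_depinning()].
#' @return List (class `evap_result`) with `slope`, `intercept`,
#'   `r_squared`, `trajectories` and `depin_time`.
#' @export
evaporation_summary <- function(times, geometry, window = c(0, 3000),
                                rel_threshold = 0.02, persistence = 2L) {
  fit <- fit_linear_volume(times, geometry$volume, window)
  traj <- normalize_trajectories(times, geometry$length, geometry$height)
  depin <- detect_depinning(times, geometry$edge_left, geometry$edge_right,
                            rel_threshold, persistence)
  structure(c(fit, list(trajectories = traj, depin_time = depin)),
            class = "evap_result")
}

#' @export
print.evap_result <- function(x, ...) {
  cat(sprintf("<evap_result> dV/dt = %.4g uL/s, V0 = %.3g uL, R^2 = %.3f, depinning at %s\n",
              x$slope, x$intercept, x$r_squared,
              if (is.na(x$depin_time)) "never" else
                sprintf("%g s", x$depin_time)))
  invisible(x)
}
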