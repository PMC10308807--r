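#' Read a grayscale image from PNG or TIFF
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix with intensities in 0-1 (first channel of
#'   multi-channel files).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a grayscale matrix as 8-bit PNG
#'
#' @param image numeric matrix, intensities in 0-1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Detect the substrate baseline in a side-view image
#'
#' Returns the row with the strongest horizontally-integrated vertical
#' intensity gradient, i.e. the first substrate row. Ties break to the
#' bottom-most row.
#'
#' @param image grayscale matrix (0-1), origin top-left.
#' @param prominence required ratio of the peak gradient to the median
#'   gradient; below it the detection fails and a manual baseline is
#'   needed.
#' @return Integer row index of the first substrate row.
#' @export
detect_baseline <- function(image, prominence = 5) {
  stopifnot(is.matrix(image), nrow(image) >= 3)
  g <- rowSums(abs(image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE]))
  peak <- max(g)
  if (peak <= 0 || peak < prominence * (stats::median(g) + 1e-9))
    stop(sprintf("no baseline gradient peak above prominence %g; supply the baseline manually",
                 prominence))
  idx <- which(g == peak)
  idx[length(idx)] + 1L
}

#' Extract the droplet side profile from an image
#'
#' Thresholds the region above the baseline with an automatic global
#' (Otsu) threshold, keeps the largest dark connected component
#' touching the baseline, traces its upper boundary column by column,
#' refines each boundary sample to subpixel precision by linear
#' interpolation of the intensity crossing, and converts to
#' millimetres with z = 0 at the baseline.
#'
#' @param image grayscale matrix (0-1).
#' @param baseline first substrate row (e.g. from [detect_baseline()]).
#' @param pixel_scale mm per pixel.
#' @param min_area minimum component area (px) to count as a droplet
#'   candidate.
#' @param source_frame optional frame identifier carried through.
#' @return A `drop_profile`: data frame with `r` and `z` (mm), one
#'   point per image column under the drop, with attributes
#'   `pixel_scale`, `edges` (left/right contact-point r, mm),
#'   `baseline_row` and `source_frame`.
#' @export
extract_profile <- function(image, baseline, pixel_scale,
                            min_area = 20, source_frame = NA) {
  stopifnot(is.matrix(image), baseline > 2, baseline <= nrow(image))
  region <- image[seq_len(baseline - 1L), , drop = FALSE]
  if (diff(range(region)) < 0.05)
    stop("expected exactly one droplet region touching the baseline, found 0 (no contrast above the baseline)")
  thr <- EBImage::otsu(EBImage::Image(region))
  mask <- region < thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  areas <- tabulate(labels[labels > 0])
  touching <- unique(labels[nrow(labels), ])
  touching <- touching[touching > 0]
  touching <- touching[areas[touching] >= min_area]
  if (length(touching) != 1L)
    stop(sprintf("expected exactly one droplet region touching the baseline, found %d",
                 length(touching)))
  comp <- labels == touching
  cols <- which(colSums(comp) > 0)
  y_cross <- vapply(cols, function(ci) {
    t_c <- which(comp[, ci])[1]
    if (t_c <= 1) return(t_c - 0.5)
    i_above <- region[t_c - 1L, ci]; i_at <- region[t_c, ci]
    frac <- if (i_above > i_at) (i_above - thr) / (i_above - i_at) else 0.5
    (t_c - 1) + min(max(frac, 0), 1)
  }, 0)
  z <- (baseline - 0.5 - y_cross) * pixel_scale
  r <- (cols - 1) * pixel_scale
  # subpixel edge positions from the bottom-most drop row
  bot <- nrow(region)
  brow <- region[bot, ]
  bcols <- which(comp[bot, ])
  edge_sub <- function(c_edge, dir) {
    c_out <- c_edge - dir
    if (c_out < 1 || c_out > length(brow) || brow[c_out] <= thr)
      return(c_edge - dir * 0.5)
    frac <- (brow[c_out] - thr) / (brow[c_out] - brow[c_edge])
    c_out + dir * min(max(frac, 0), 1)
  }
  edges <- c((edge_sub(bcols[1], 1L) - 1) * pixel_scale,
             (edge_sub(bcols[length(bcols)], -1L) - 1) * pixel_scale)
  out <- data.frame(r = r, z = pmax(z, 0))
  attr(out, "pixel_scale") <- pixel_scale
  attr(out, "edges") <- edges
  attr(out, "baseline_row") <- baseline
  attr(out, "source_frame") <- source_frame
  class(out) <- c("drop_profile", "data.frame")
  out
}

#' Construct a drop profile from coordinates
#'
#' Builds a `drop_profile` directly from ordered contour points in
#' physical units (e.g. digitized or analytic profiles).
#'
#' @param r,z coordinates in mm, left to right, `z >= 0` above the
#'   baseline.
#' @param pixel_scale mm per pixel of the source imagery (used by
#'   consumers to express pixel-equivalent tolerances).
#' @param edges optional left/right contact-point positions, mm;
#'   defaults to the endpoints.
#' @return A `drop_profile`.
#' @export
drop_profile <- function(r, z, pixel_scale = NA_real_, edges = NULL) {
  stopifnot(length(r) == length(z), all(z >= 0))
  out <- data.frame(r = r, z = z)
  attr(out, "pixel_scale") <- pixel_scale
  attr(out, "edges") <- if (is.null(edges)) c(r[1], r[length(r)]) else edges
  class(out) <- c("drop_profile", "data.frame")
  out
}

#' Contact angles from a drop profile
#'
#' Fits a quadratic to each flank over the points within
#' `fit_height_frac` of the drop height and reports the tangent angle
#' at the baseline (z = 0), measured through the liquid. The fit is of
#' r on z, so near-vertical flanks (angles near 90 degrees) remain
#' well conditioned.
#'
#' @param profile a `drop_profile`.
#' @param fit_height_frac fraction of the drop height used for the
#'   flank fits (default 0.15).
#' @param min_points minimum points required per flank.
#' @return Named numeric vector `c(theta_left, theta_right)` in
#'   degrees.
#' @export
contact_angles <- function(profile, fit_height_frac = 0.15,
                           min_points = 10L) {
  stopifnot(inherits(profile, "drop_profile"))
  h <- max(profile$z)
  r_apex <- profile$r[which.max(profile$z)]
  one_flank <- function(side) {
    pts <- if (side == "left") profile[profile$r <= r_apex, ]
           else profile[profile$r >= r_apex, ]
    pts <- pts[pts$z <= fit_height_frac * h, ]
    if (nrow(pts) < min_points)
      stop(sprintf("too few near-baseline points on the %s flank (%d < %d)",
                   side, nrow(pts), min_points))
    fit <- stats::lm(r ~ z + I(z^2), data = pts)
    drdz <- stats::coef(fit)[["z"]]
    if (side == "left") atan2(1, drdz) * 180 / pi
    else atan2(1, -drdz) * 180 / pi
  }
  c(theta_left = one_flank("left"), theta_right = one_flank("right"))
}

#' Closed contour, perimeter and area from a top-view image
#'
#' Extracts the boundary of the largest dark region at subpixel
#' precision (bilinear level crossing of the automatic threshold),
#' and reports the polygon perimeter and the shoelace area in
#' physical units.
#'
#' @param image grayscale matrix (0-1), dark footprint on light
#'   background.
#' @param pixel_scale mm per pixel.
#' @return List with `contour` (data frame `x`, `y` in mm, closed),
#'   `perimeter` (mm) and `area` (mm^2).
#' @export
top_contour <- function(image, pixel_scale) {
  stopifnot(is.matrix(image))
  if (diff(range(image)) < 0.05)
    stop("no footprint found: image contrast too low")
  thr <- EBImage::otsu(EBImage::Image(image))
  cl <- grDevices::contourLines(x = seq_len(nrow(image)),
                                y = seq_len(ncol(image)),
                                z = image, levels = thr)
  if (length(cl) == 0L) stop("no footprint found at the threshold level")
  sho <- function(p) {
    x <- p$x; y <- p$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  best <- cl[[which.max(vapply(cl, sho, 0))]]
  x <- best$x * pixel_scale; y <- best$y * pixel_scale
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  perim <- sum(sqrt(diff(x)^2 + diff(y)^2))
  area <- abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
  list(contour = data.frame(x = x, y = y), perimeter = perim, area = area)
}

#' Per-frame droplet geometry from a side-view image
#'
#' Convenience wrapper: baseline detection (unless given), profile
#' extraction and contact-angle measurement for one frame.
#'
#' @param image grayscale matrix.
#' @param pixel_scale mm per pixel.
#' @param baseline `"auto"` or an integer row.
#' @param fit_height_frac passed to [contact_angles()].
#' @return A list (class `drop_geometry`): `theta_left`,
#'   `theta_right`, `length`, `height`, `edge_left`, `edge_right`
#'   (mm/degrees) plus the `profile`.
#' @export
measure_frame <- function(image, pixel_scale, baseline = "auto",
                          fit_height_frac = 0.15) {
  bl <- if (identical(baseline, "auto")) detect_baseline(image)
        else as.integer(baseline)
  prof <- extract_profile(image, bl, pixel_scale)
  ang <- contact_angles(prof, fit_height_frac)
  edges <- attr(prof, "edges")
  structure(list(theta_left = ang[["theta_left"]],
                 theta_right = ang[["theta_right"]],
                 length = edges[2] - edges[1],
                 height = max(prof$z),
                 edge_left = edges[1], edge_right = edges[2],
                 profile = prof),
            class = "drop_geometry")
}
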