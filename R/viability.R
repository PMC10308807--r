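#' Segment cells in a single fluorescence channel
#'
#' Automatic global (Otsu) threshold and connected components; any
#' component too large to be a single cell (area above the filter
#' maximum, i.e. a merged cluster) is split by a watershed on its
#' distance transform; finally a size filter keeps objects whose
#' area lies in `area_range_px`. The procedure contains no
#' randomness and is invariant to image translation.
#'
#' @param image single-channel intensity matrix (0-1), bright cells
#'   on dark background.
#' @param area_range_px `c(min, max)` retained object area, px^2.
#' @param watershed_tolerance minimum object-height separation for
#'   the watershed split (px, in distance-map units).
#' @return Data frame with one row per retained object: `row`, `col`
#'   (centroid, px) and `area_px`. Empty images give an empty table,
#'   not an error.
#' @export
segment_channel <- function(image, area_range_px = c(10, 30),
                            watershed_tolerance = 0.5) {
  stopifnot(is.matrix(image), area_range_px[1] < area_range_px[2])
  empty <- data.frame(row = numeric(), col = numeric(),
                      area_px = numeric())
  if (diff(range(image)) < 1e-6) return(empty)
  thr <- EBImage::otsu(EBImage::Image(image))
  mask <- image > thr
  if (!any(mask)) return(empty)
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  areas <- tabulate(comp[comp > 0])
  labels <- comp
  oversized <- comp > 0
  oversized[oversized] <- areas[comp[oversized]] > area_range_px[2]
  labels[oversized] <- 0L
  # watershed-split oversized components (merged cell clusters)
  nxt <- max(labels)
  for (id in which(areas > area_range_px[2])) {
    sub <- comp == id
    dm <- EBImage::distmap(EBImage::Image(sub))
    ws <- EBImage::imageData(EBImage::watershed(dm,
                                                tolerance = watershed_tolerance,
                                                ext = 1))
    labels[ws > 0] <- nxt + ws[ws > 0]
    nxt <- max(labels)
  }
  ids <- sort(unique(labels[labels > 0]))
  out <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    data.frame(row = mean(px[, 1]), col = mean(px[, 2]),
               area_px = nrow(px))
  })
  out <- do.call(rbind, out)
  out <- out[out$area_px >= area_range_px[1] &
             out$area_px <= area_range_px[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-area live/dead cell densities
#'
#' Normalizes per-channel counts by the field area so that fields of
#' different sizes are comparable (cells per square micrometre).
#'
#' @param objects_green,objects_red object tables from
#'   [segment_channel()] for the green (live) and red (dead) channel.
#' @param field `c(rows, cols)` of the field, px.
#' @param pixel_scale pixel edge length, micrometres (default 0.566,
#'   i.e. 10 px^2 = 3.2 um^2).
#' @return A `cell_counts` list: `n_green`, `n_red`,
#'   `density_green`, `density_red` (cells/um^2), `field_area`
#'   (um^2) and the combined `objects` table.
#' @export
count_densities <- function(objects_green, objects_red, field,
                            pixel_scale = 0.566) {
  stopifnot(length(field) == 2L, all(field > 0), pixel_scale > 0)
  area_um2 <- prod(field) * pixel_scale^2
  obj <- rbind(
    if (nrow(objects_green)) cbind(channel = "green", objects_green),
    if (nrow(objects_red)) cbind(channel = "red", objects_red))
  structure(list(n_green = nrow(objects_green),
                 n_red = nrow(objects_red),
                 density_green = nrow(objects_green) / area_um2,
                 density_red = nrow(objects_red) / area_um2,
                 field_area = area_um2,
                 objects = obj),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d live (%.3g/um^2), %d dead (%.3g/um^2) in %.4g um^2\n",
              x$n_green, x$density_green, x$n_red, x$density_red,
              x$field_area))
  invisible(x)
}

#' Compare cell densities between two conditions
#'
#' One-tailed unpaired two-sample Student's t-test with pooled
#' variance (Welch's correction available behind `welch`).
#' Significance is declared at p < 0.005.
#'
#' @param a,b replicate measurements (e.g. densities) for the two
#'   conditions; at least 3 each.
#' @param alternative `"greater"` tests mean(a) > mean(b);
#'   `"less"` the reverse.
#' @param alpha significance level (default 0.005).
#' @param welch use Welch's unequal-variance t-test instead of the
#'   pooled-variance form.
#' @return List with `t_statistic`, `p_value`, `significant`.
#' @examples
#' compare_conditions(c(5, 6, 7), c(1, 1.2, 0.9))
#' @export
compare_conditions <- function(a, b, alternative = c("greater", "less"),
                               alpha = 0.005, welch = FALSE) {
  alternative <- match.arg(alternative)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 replicates per condition")
  tt <- stats::t.test(a, b, alternative = alternative,
                      var.equal = !welch)
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       significant = tt$p.value < alpha)
}
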