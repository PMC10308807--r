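#' Write a drop profile as CSV
#'
#' @param profile a `drop_profile`.
#' @param path output path; columns `r_mm`, `z_mm`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "drop_profile"))
  utils::write.csv(data.frame(r_mm = profile$r, z_mm = profile$z),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a drop profile from CSV
#'
#' @param path CSV with columns `r_mm`, `z_mm`.
#' @param pixel_scale optional mm/px of the source imagery.
#' @return A `drop_profile`.
#' @export
read_profile <- function(path, pixel_scale = NA_real_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("r_mm", "z_mm") %in% names(d)))
  drop_profile(d$r_mm, d$z_mm, pixel_scale = pixel_scale)
}

#' Write a synthetic series to disk
#'
#' Writes each frame of a generated series as an 8-bit grayscale PNG
#' with a JSON ground-truth sidecar, plus a CSV manifest
#' (`frame_id`, `time_s` or `rs_rpm`, `file`).
#'
#' @param frames list of frames from [gen_sessile_image()] /
#'   [gen_evaporation_series()] (each with `image`, `truth`, and
#'   optionally `time`).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return The manifest data frame, invisibly.
#' @export
write_series <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    base <- sprintf("%s_%03d", prefix, i)
    if (!is.null(fr$image))
      write_image_png(fr$image, file.path(dir, paste0(base, ".png")))
    jsonlite::write_json(fr$truth, file.path(dir, paste0(base, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(frame_id = base,
               time_s = if (is.null(fr$time)) NA_real_ else fr$time,
               file = paste0(base, ".png"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write wetting events as JSON
#'
#' @param events a `wetting_events` list from [detect_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  stopifnot(inherits(events, "wetting_events"))
  jsonlite::write_json(unclass(events), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
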