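#' Pixel and frame calibration
#'
#' Records the physical size of a pixel and the time between frames, so that
#' image-space quantities (object areas, structuring-element radii) can be
#' expressed in micrometres and time courses in hours or seconds.
#'
#' @param pixel_size Physical length of one pixel side (> 0), in `space_unit`.
#' @param frame_interval Time between consecutive frames (> 0), in `time_unit`.
#' @param space_unit One of `"um"`, `"nm"`.
#' @param time_unit One of `"h"`, `"min"`, `"s"`.
#' @return A `pixel_calibration` object.
#' @examples
#' cal <- pixel_calibration(1, 0.5)          # 1 um/px, frames every 0.5 h
#' @export
pixel_calibration <- function(pixel_size, frame_interval,
                              space_unit = c("um", "nm"),
                              time_unit = c("h", "min", "s")) {
  space_unit <- match.arg(space_unit)
  time_unit <- match.arg(time_unit)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a single finite value > 0")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single finite value > 0")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 space_unit = space_unit, time_unit = time_unit),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("pixel calibration: %g %s/px, frame every %g %s\n",
              x$pixel_size, x$space_unit, x$frame_interval, x$time_unit))
  invisible(x)
}

# pixel size in micrometres regardless of declared unit
pixel_size_um <- function(calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  if (calibration$space_unit == "nm") calibration$pixel_size / 1000
  else calibration$pixel_size
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with defaults
#' taken from the acquisition protocol the pipeline reproduces: top-hat radii
#' 10 um (green) and 100 um (red), colour threshold 0.7 on normalized top-hat
#' output, SMLM density radius = 5 x mean nearest-neighbour distance and local
#' density threshold 40, a minimum of 100 localizations per aggregate.
#'
#' @return Nested list of parameters.
#' @seealso [read_config()], [write_config()]
#' @export
default_config <- function() {
  list(
    segmentation = list(
      tophat_radius_um = list(green = 10, red = 100),
      colour_threshold = 0.7,
      min_area_px = 5
    ),
    kinetics = list(
      log_floor_frac = 1e-3
    ),
    smlm = list(
      density_radius_multiplier = 5,
      density_threshold = 40,
      min_localizations = 100,
      max_localizations = Inf,
      min_members = 3,
      render_pixel_nm = 20
    ),
    seed = 1L
  )
}

#' Read / write pipeline configuration
#'
#' Configuration round-trips losslessly through YAML text. Keys absent from
#' the file take their [default_config()] values; unknown keys error.
#'
#' @param path Path of a YAML configuration file.
#' @param config A configuration list as returned by [default_config()].
#' @return `read_config` returns the merged configuration list;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(user[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    else
      base[[key]] <- user[[key]]
  }
  base
}
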