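#' Segmentation parameters for puncta detection
#'
#' Defaults follow the automated acquisition protocol this pipeline
#' reproduces: structuring-element radii of 10 um for the green channel and
#' 100 um for the red channel, a colour threshold of 0.7 applied to the
#' min-max-normalized top-hat output, and a minimum object area filter.
#'
#' @param tophat_radius_um Named list with per-channel top-hat disc radii in
#'   micrometres (`green`, `red`); radii must be > 0.
#' @param colour_threshold Threshold in (0, 1) on the normalized top-hat
#'   response.
#' @param min_area_px Minimum object area in pixels (>= 1); smaller connected
#'   components are discarded.
#' @param smooth_sigma_px Gaussian denoising s.d. (px) applied to the
#'   top-hat response before normalization and thresholding; 0 disables it.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(tophat_radius_um = list(green = 10, red = 100),
                                colour_threshold = 0.7,
                                min_area_px = 3,
                                smooth_sigma_px = 0.7) {
  stopifnot(all(unlist(tophat_radius_um) > 0),
            colour_threshold > 0, colour_threshold < 1,
            min_area_px >= 1, smooth_sigma_px >= 0)
  structure(list(tophat_radius_um = tophat_radius_um,
                 colour_threshold = colour_threshold,
                 min_area_px = min_area_px,
                 smooth_sigma_px = smooth_sigma_px),
            class = "segmentation_params")
}

# White top-hat with a disc structuring element. The image is rescaled to
# [0, 1] for EBImage (whose grayscale morphology clamps to that range) and
# the result mapped back to raw intensity units — morphology is equivariant
# under positive affine maps, and the top-hat removes the offset itself.
# Padding by edge replication keeps image borders free of artifacts from the
# finite support.
disc_tophat <- function(img, radius_px) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(matrix(0, nrow(img), ncol(img)))
  img01 <- (img - rng[1]) / (rng[2] - rng[1])
  p <- 2L * radius_px + 1L
  ri <- pmin(pmax(seq_len(nrow(img) + 2L * p) - p, 1L), nrow(img))
  ci <- pmin(pmax(seq_len(ncol(img) + 2L * p) - p, 1L), ncol(img))
  th <- EBImage::whiteTopHat(img01[ri, ci],
                             EBImage::makeBrush(2L * radius_px + 1L, "disc"))
  th[p + seq_len(nrow(img)), p + seq_len(ncol(img)), drop = FALSE] *
    (rng[2] - rng[1])
}

#' Top-hat segmentation of fluorescent puncta
#'
#' Applies a white top-hat transform (image minus its morphological opening)
#' with a disc structuring element of the channel's configured radius,
#' lightly denoises the response with a Gaussian filter
#' (`smooth_sigma_px`), min-max-normalizes it to `[0, 1]`, thresholds it at
#' the colour threshold and removes objects smaller than `min_area_px`. The
#' top-hat suppresses background structure larger than the disc, so flat
#' images and smooth gradients yield empty masks, and the result is
#' invariant to adding a constant to the image.
#'
#' @param image 2-D numeric matrix.
#' @param params A [segmentation_params()].
#' @param calibration A [pixel_calibration()] used to convert the radius from
#'   micrometres to pixels (rounded up to >= 1 px; radii below half a pixel
#'   raise an error suggesting a calibration check).
#' @param channel `"green"` or `"red"`: selects the per-channel radius.
#' @return Logical matrix mask, `TRUE` on puncta pixels.
#' @export
tophat_segment <- function(image, params = segmentation_params(),
                           calibration, channel = c("green", "red")) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(image), inherits(params, "segmentation_params"))
  r_um <- params$tophat_radius_um[[channel]]
  if (is.null(r_um)) stop("no top-hat radius configured for channel ", channel)
  r_px_real <- r_um / pixel_size_um(calibration)
  if (r_px_real < 0.5)
    stop(sprintf(paste0("top-hat radius %g um converts to %.3f px; ",
                        "check the pixel calibration"), r_um, r_px_real))
  r_px <- as.integer(ceiling(r_px_real - 1e-9))
  th <- disc_tophat(image, r_px)
  if (params$smooth_sigma_px > 0 && max(th) > 0)
    th <- EBImage::gblur(th, sigma = params$smooth_sigma_px)
  mx <- max(th)
  if (mx <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  mask <- (th / mx) > params$colour_threshold
  drop_small_objects(mask, params$min_area_px)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged through connected components of the label graph.
label_mask <- function(mask) {
  lb <- EBImage::bwlabel(mask)
  nlab <- max(lb)
  if (nlab <= 1) return(lb)
  nr <- nrow(lb); nc <- ncol(lb)
  a <- lb[-nr, -nc]; b <- lb[-1, -1]       # down-right diagonal pairs
  c1 <- lb[-nr, -1]; d <- lb[-1, -nc]      # down-left diagonal pairs
  e1 <- cbind(as.vector(a), as.vector(b))
  e2 <- cbind(as.vector(c1), as.vector(d))
  edges <- rbind(e1[e1[, 1] > 0 & e1[, 2] > 0 & e1[, 1] != e1[, 2], ,
                    drop = FALSE],
                 e2[e2[, 1] > 0 & e2[, 2] > 0 & e2[, 1] != e2[, 2], ,
                    drop = FALSE])
  if (nrow(edges) == 0) return(lb)
  g <- igraph::graph_from_edgelist(matrix(as.character(t(edges)), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(nlab)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(nlab)
  map[as.integer(names(comp))] <- comp
  out <- lb
  out[lb > 0] <- map[lb[lb > 0]]
  # compact to 1..k
  used <- sort(unique(out[out > 0]))
  relab <- integer(max(used)); relab[used] <- seq_along(used)
  out[out > 0] <- relab[out[out > 0]]
  out
}

drop_small_objects <- function(mask, min_area_px) {
  if (!any(mask) || min_area_px <= 1) return(mask)
  lb <- label_mask(mask)
  sizes <- tabulate(lb[lb > 0])
  keep <- which(sizes >= min_area_px)
  array(lb %in% keep, dim = dim(mask))
}

#' Detect puncta as connected components of a mask
#'
#' Labels the mask with 8-connectivity and measures each object's centroid
#' (0-based pixel-centre coordinates), pixel area, calibrated area and mean
#' intensity over the underlying image.
#'
#' @param mask Logical matrix from [tophat_segment()].
#' @param intensity_image Matrix of the same shape supplying intensities.
#' @param frame_index Frame number recorded with every object.
#' @param calibration Optional [pixel_calibration()]; when given, areas are
#'   also reported in um^2.
#' @param channel Channel class recorded with every object
#'   (`"green"`, `"red"` or `"white"`).
#' @return A `puncta_set` data frame: `frame`, `label`, `x_px`, `y_px`,
#'   `area_px`, `area_um2`, `mean_intensity`, `channel`.
#' @export
detect_puncta <- function(mask, intensity_image, frame_index = 1L,
                          calibration = NULL, channel = NA_character_) {
  if (!identical(dim(mask), dim(intensity_image)))
    stop("mask and intensity image differ in shape")
  lb <- label_mask(mask)
  nlab <- max(lb)
  px_um2 <- if (is.null(calibration)) NA_real_ else pixel_size_um(calibration)^2
  if (nlab == 0) {
    out <- data.frame(frame = integer(0), label = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), channel = character(0))
  } else {
    idx <- which(lb > 0)
    lab <- lb[idx]
    rows <- (idx - 1) %% nrow(lb) + 1
    cols <- (idx - 1) %/% nrow(lb) + 1
    area <- tabulate(lab, nlab)
    out <- data.frame(
      frame = frame_index,
      label = seq_len(nlab),
      x_px = as.numeric(tapply(cols - 1, lab, mean)),
      y_px = as.numeric(tapply(rows - 1, lab, mean)),
      area_px = area,
      area_um2 = area * px_um2,
      mean_intensity = as.numeric(tapply(intensity_image[idx], lab, mean)),
      channel = channel)
  }
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Overlap ("white") area between green and red masks
#'
#' The white mask is the pixelwise intersection of the green and red masks;
#' the white area fraction divides the overlap area by the red (magenta)
#' area. An empty red mask yields fraction 0 with a warning.
#'
#' @param green_mask,red_mask Logical matrices of identical shape.
#' @return List with `mask` (logical matrix) and `fraction` in `[0, 1]`.
#' @export
white_overlap <- function(green_mask, red_mask) {
  if (!identical(dim(green_mask), dim(red_mask)))
    stop("green and red masks differ in shape")
  white <- green_mask & red_mask
  red_area <- sum(red_mask)
  if (red_area == 0) {
    warning("red mask is empty; white area fraction reported as 0")
    return(list(mask = white, fraction = 0))
  }
  list(mask = white, fraction = sum(white) / red_area)
}

#' Classify red puncta as white or red-only
#'
#' Object-level companion to the area-based [white_overlap()]: a red object
#' is classed `"white"` when at least half of its pixels are green-positive,
#' `"red"` otherwise.
#'
#' @param red_mask,green_mask Logical matrices of identical shape.
#' @return Data frame with `label`, `green_fraction`, `channel`.
#' @export
classify_puncta_colour <- function(red_mask, green_mask) {
  if (!identical(dim(red_mask), dim(green_mask)))
    stop("masks differ in shape")
  lb <- label_mask(red_mask)
  nlab <- max(lb)
  if (nlab == 0)
    return(data.frame(label = integer(0), green_fraction = numeric(0),
                      channel = character(0)))
  idx <- which(lb > 0)
  lab <- lb[idx]
  gf <- as.numeric(tapply(green_mask[idx], lab, mean))
  data.frame(label = seq_len(nlab), green_fraction = gf,
             channel = ifelse(gf >= 0.5, "white", "red"))
}

#' Mean puncta size per frame
#'
#' Arithmetic mean of object areas (um^2 when calibrated, else px) per frame;
#' frames without objects report `NA`, not 0.
#'
#' @param puncta_sets List of [detect_puncta()] results, one per frame.
#' @return Data frame with `frame` and `mean_area_um2` (or `mean_area_px`
#'   when areas are uncalibrated).
#' @export
average_object_size <- function(puncta_sets) {
  stopifnot(is.list(puncta_sets))
  frames <- vapply(seq_along(puncta_sets), function(i) {
    fr <- unique(puncta_sets[[i]]$frame)
    if (length(fr) == 1) as.integer(fr) else i
  }, integer(1))
  use_um <- all(vapply(puncta_sets,
                       function(p) nrow(p) == 0 || all(is.finite(p$area_um2)),
                       logical(1)))
  mean_area <- vapply(puncta_sets, function(p) {
    if (nrow(p) == 0) return(NA_real_)
    if (use_um) mean(p$area_um2) else mean(p$area_px)
  }, numeric(1))
  out <- data.frame(frame = frames, mean_area = mean_area)
  names(out)[2] <- if (use_um) "mean_area_um2" else "mean_area_px"
  out
}

#' Fraction of puncta colocalizing with a marker
#'
#' An object colocalizes when its centroid falls on a `TRUE` pixel of the
#' marker mask (object-based colocalization).
#'
#' @param puncta A [detect_puncta()] result.
#' @param marker_mask Logical matrix in the same coordinate frame.
#' @return Fraction in `[0, 1]`; `NA` when there are no puncta.
#' @export
colocalize_puncta <- function(puncta, marker_mask) {
  if (nrow(puncta) == 0) return(NA_real_)
  rows <- pmin(pmax(round(puncta$y_px) + 1, 1), nrow(marker_mask))
  cols <- pmin(pmax(round(puncta$x_px) + 1, 1), ncol(marker_mask))
  mean(marker_mask[cbind(rows, cols)])
}

#' ROI signal intensity and fold change across conditions
#'
#' Reproduces the confocal quantification in which the reporter (mCherry)
#' channel defines aggregate ROIs and the mean intensity of a measured
#' protein channel within each ROI is compared across conditions as fold
#' change relative to a reference condition.
#'
#' @param images_by_condition Named list (one entry per condition) of lists
#'   of images; each image is a list with elements `roi` (ROI-defining
#'   channel matrix) and `measured` (measured channel matrix).
#' @param params A [segmentation_params()]; the ROI channel is segmented with
#'   [tophat_segment()] using the `"red"` radius.
#' @param calibration A [pixel_calibration()].
#' @param reference_condition Name of the condition all fold changes are
#'   relative to.
#' @return List with `per_roi` (condition, image, roi label, mean intensity)
#'   and `fold_change` (condition means and fold change; the reference's fold
#'   change is exactly 1).
#' @export
roi_intensity_foldchange <- function(images_by_condition,
                                     params = segmentation_params(),
                                     calibration,
                                     reference_condition) {
  if (!reference_condition %in% names(images_by_condition))
    stop("reference condition '", reference_condition, "' absent")
  per_roi <- do.call(rbind, lapply(names(images_by_condition), function(cond) {
    imgs <- images_by_condition[[cond]]
    do.call(rbind, lapply(seq_along(imgs), function(i) {
      roi_mask <- tophat_segment(imgs[[i]]$roi, params, calibration, "red")
      ps <- detect_puncta(roi_mask, imgs[[i]]$measured, frame_index = i,
                          calibration = calibration)
      if (nrow(ps) == 0) return(NULL)
      data.frame(condition = cond, image = i, roi = ps$label,
                 mean_intensity = ps$mean_intensity)
    }))
  }))
  if (is.null(per_roi) || nrow(per_roi) == 0)
    stop("no ROIs detected in any condition")
  cond_mean <- tapply(per_roi$mean_intensity, per_roi$condition, mean)
  ref <- cond_mean[[reference_condition]]
  fc <- data.frame(condition = names(cond_mean),
                   mean_intensity = as.numeric(cond_mean),
                   fold_change = as.numeric(cond_mean) / ref)
  rownames(fc) <- NULL
  list(per_roi = per_roi, fold_change = fc)
}

#' Fraction of the cell area covered by green signal
#'
#' Divides the green-positive area inside the cell by the total cell area
#' (the readout used for stabilized-GFP degradation reporters).
#'
#' @param green_mask,cell_mask Logical matrices of identical shape;
#'   `cell_mask` must be non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
gfp_area_fraction <- function(green_mask, cell_mask) {
  if (!identical(dim(green_mask), dim(cell_mask)))
    stop("masks differ in shape")
  cell <- sum(cell_mask)
  if (cell == 0) stop("cell mask is empty")
  sum(green_mask & cell_mask) / cell
}

#' Quantify one two-channel frame
#'
#' Convenience wrapper running the full per-frame pipeline: segment both
#' channels, compute the white overlap and return per-channel puncta tables.
#'
#' @param green,red 2-D matrices of the two channels.
#' @param params A [segmentation_params()].
#' @param calibration A [pixel_calibration()].
#' @param frame_index Frame number recorded in the puncta tables.
#' @return List: `green_mask`, `red_mask`, `white_mask`,
#'   `white_fraction`, `green_puncta`, `red_puncta`.
#' @export
quantify_frame <- function(green, red, params = segmentation_params(),
                           calibration, frame_index = 1L) {
  gm <- tophat_segment(green, params, calibration, "green")
  rm_ <- tophat_segment(red, params, calibration, "red")
  ov <- white_overlap(gm, rm_)
  list(green_mask = gm, red_mask = rm_, white_mask = ov$mask,
       white_fraction = ov$fraction,
       green_puncta = detect_puncta(gm, green, frame_index, calibration,
                                    "green"),
       red_puncta = detect_puncta(rm_, red, frame_index, calibration, "red"))
}

#' White-fraction time course of a two-channel movie
#'
#' Runs [quantify_frame()] over every frame of a green/red stack pair and
#' returns the white area fraction as a [time_series()].
#'
#' @param green_stack,red_stack [frame_stack()] objects of equal length.
#' @param params A [segmentation_params()].
#' @return A [time_series()] of white area fraction vs time.
#' @export
white_fraction_timeseries <- function(green_stack, red_stack,
                                      params = segmentation_params()) {
  stopifnot(n_frames(green_stack) == n_frames(red_stack))
  cal <- green_stack$calibration
  fr <- vapply(seq_len(n_frames(green_stack)), function(i) {
    suppressWarnings(
      quantify_frame(get_frame(green_stack, i), get_frame(red_stack, i),
                     params, cal, i)$white_fraction)
  }, numeric(1))
  time_series(frame_times(green_stack), fr, unit = cal$time_unit,
              label = "white area fraction")
}
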