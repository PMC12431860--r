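#' Disc-shaped aggregate ROI label mask
#'
#' Convenience constructor for synthetic SMLM experiments: one or more discs
#' on a pixel grid, returned as an integer label matrix (0 = background,
#' k = aggregate k) plus its pixel size.
#'
#' @param diameter_nm Disc diameter(s), nm (one per aggregate).
#' @param pixel_size_nm Mask pixel size, nm.
#' @param spacing_nm Centre-to-centre spacing when several discs are laid out
#'   in a row; defaults to twice the largest diameter.
#' @return List with `mask` (integer matrix) and `pixel_size_nm`.
#' @export
disc_roi_mask <- function(diameter_nm = 1000, pixel_size_nm = 10,
                          spacing_nm = NULL) {
  k <- length(diameter_nm)
  if (is.null(spacing_nm)) spacing_nm <- 2 * max(diameter_nm)
  r_px <- diameter_nm / 2 / pixel_size_nm
  width <- ceiling(spacing_nm / pixel_size_nm * (k - 1) + 2 * max(r_px) + 4)
  height <- ceiling(2 * max(r_px) + 4)
  mask <- matrix(0L, height, width)
  cy <- height / 2
  for (i in seq_len(k)) {
    cx <- max(r_px) + 2 + (i - 1) * spacing_nm / pixel_size_nm
    d2 <- outer((seq_len(height) - 0.5 - cy)^2,
                (seq_len(width) - 0.5 - cx)^2, "+")
    mask[d2 <= r_px[i]^2] <- i
  }
  list(mask = mask, pixel_size_nm = pixel_size_nm)
}

# uniform positions (nm) on the TRUE/positive pixels of a mask; pixel
# [r, c] covers [(c-1), c) x [(r-1), r) * pixel_size_nm
sample_on_mask <- function(mask, pixel_size_nm, n) {
  idx <- which(mask > 0)
  if (length(idx) == 0) stop("mask is empty")
  pick <- sample(idx, n, replace = TRUE)
  rows <- (pick - 1) %% nrow(mask) + 1
  cols <- (pick - 1) %/% nrow(mask) + 1
  cbind(x = (cols - 1 + stats::runif(n)) * pixel_size_nm,
        y = (rows - 1 + stats::runif(n)) * pixel_size_nm)
}

point_in_mask <- function(mask, pixel_size_nm, x, y, value = NULL) {
  cols <- floor(x / pixel_size_nm) + 1
  rows <- floor(y / pixel_size_nm) + 1
  ok <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
  out <- rep(0L, length(x))
  out[ok] <- mask[cbind(rows[ok], cols[ok])]
  if (is.null(value)) out > 0 else out == value
}

#' Simulate receptor localizations on aggregate footprints
#'
#' Generates an SMLM localization table with known ground truth: per
#' aggregate, `round(clustered_fraction * n_per_aggregate)` molecules are
#' drawn from isotropic Gaussian clusters (centres placed inside the
#' aggregate with a minimum mutual separation, membership multinomial) and
#' the remainder uniformly over the aggregate footprint. Every coordinate is
#' jittered by Gaussian localization error, truncated at 4 sigma so no
#' localization leaves the footprint by more than 4x the error.
#'
#' @param roi A list with `mask` (integer label matrix, 0 = background) and
#'   `pixel_size_nm`, as from [disc_roi_mask()].
#' @param n_per_aggregate Localizations per aggregate.
#' @param clustered_fraction Fraction of molecules in clusters, in `[0, 1]`.
#' @param n_clusters Clusters per aggregate (>= 0).
#' @param cluster_sigma_nm Cluster radial s.d., nm (> 0 when clusters exist).
#' @param localization_error_nm Localization error sigma, nm.
#' @param cluster_allocation `"multinomial"` (each clustered molecule picks
#'   its cluster uniformly at random) or `"equal"` (clustered molecules are
#'   divided as evenly as possible across clusters).
#' @param min_cluster_sep_nm Minimum distance between cluster centres;
#'   default `16 * cluster_sigma_nm`, i.e. well separated relative to both
#'   the cluster spread and the density-linking radius of the analysis
#'   (clusters closer than that radius merge by construction).
#' @param seed Integer seed.
#' @return List: `localizations` (a [localization_table()]) and `truth`
#'   (per-molecule `aggregate` id and `cluster` label, -1 = background;
#'   cluster centres; the generating parameters).
#' @export
simulate_smlm_localizations <- function(roi,
                                        n_per_aggregate = 250,
                                        clustered_fraction = 0.6,
                                        n_clusters = 3,
                                        cluster_sigma_nm = 20,
                                        localization_error_nm = 10,
                                        min_cluster_sep_nm = NULL,
                                        cluster_allocation = c("multinomial",
                                                               "equal"),
                                        seed) {
  cluster_allocation <- match.arg(cluster_allocation)
  if (missing(seed)) stop("seed must be given")
  stopifnot(clustered_fraction >= 0, clustered_fraction <= 1, n_clusters >= 0)
  if (n_clusters > 0 && cluster_sigma_nm <= 0)
    stop("cluster_sigma_nm must be > 0 when n_clusters > 0")
  if (is.null(min_cluster_sep_nm)) min_cluster_sep_nm <- 16 * cluster_sigma_nm
  set.seed(seed)
  mask <- roi$mask; px <- roi$pixel_size_nm
  agg_ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  if (length(agg_ids) == 0) stop("ROI mask has no aggregates")

  xs <- ys <- numeric(0); agg_col <- lab_col <- integer(0)
  centres <- NULL
  for (a in agg_ids) {
    amask <- mask == a
    n_clu <- if (n_clusters > 0) round(clustered_fraction * n_per_aggregate)
             else 0L
    n_bg <- n_per_aggregate - n_clu
    if (n_clu > 0) {
      # cluster centres: rejection-sample for minimum separation
      ctr <- sample_on_mask(amask, px, 1)
      tries <- 0
      while (nrow(ctr) < n_clusters && tries < 2000) {
        cand <- sample_on_mask(amask, px, 1)
        d <- sqrt((ctr[, 1] - cand[1])^2 + (ctr[, 2] - cand[2])^2)
        if (all(d >= min_cluster_sep_nm)) ctr <- rbind(ctr, cand)
        tries <- tries + 1
      }
      if (nrow(ctr) < n_clusters)
        stop("could not place ", n_clusters, " cluster centres at ",
             min_cluster_sep_nm, " nm separation; enlarge the ROI")
      member <- if (cluster_allocation == "multinomial")
        sample.int(n_clusters, n_clu, replace = TRUE)
      else rep_len(seq_len(n_clusters), n_clu)
      cx <- cy <- numeric(n_clu)
      for (i in seq_len(n_clu)) {
        repeat {                       # keep cluster points on the footprint
          p <- ctr[member[i], ] + stats::rnorm(2, 0, cluster_sigma_nm)
          if (point_in_mask(amask, px, p[1], p[2])) break
        }
        cx[i] <- p[1]; cy[i] <- p[2]
      }
      xs <- c(xs, cx); ys <- c(ys, cy)
      agg_col <- c(agg_col, rep(a, n_clu)); lab_col <- c(lab_col, member)
      centres <- rbind(centres,
                       data.frame(aggregate = a,
                                  cluster = seq_len(n_clusters),
                                  x_nm = ctr[, 1], y_nm = ctr[, 2]))
    }
    if (n_bg > 0) {
      bg <- sample_on_mask(amask, px, n_bg)
      xs <- c(xs, bg[, 1]); ys <- c(ys, bg[, 2])
      agg_col <- c(agg_col, rep(a, n_bg)); lab_col <- c(lab_col, rep(-1L, n_bg))
    }
  }

  n <- length(xs)
  if (n > 0 && localization_error_nm > 0) {
    jit <- matrix(stats::rnorm(2 * n, 0, localization_error_nm), ncol = 2)
    over <- sqrt(rowSums(jit^2)) > 4 * localization_error_nm
    while (any(over)) {                # truncate jitter at 4 sigma
      jit[over, ] <- stats::rnorm(2 * sum(over), 0, localization_error_nm)
      over <- sqrt(rowSums(jit^2)) > 4 * localization_error_nm
    }
    xs <- xs + jit[, 1]; ys <- ys + jit[, 2]
  }
  locs <- localization_table(xs, ys, frame = seq_len(max(n, 0)),
                             sigma_nm = rep(max(localization_error_nm, 1e-3),
                                            max(n, 0)))
  list(localizations = locs,
       truth = list(aggregate = agg_col, cluster = lab_col,
                    centres = centres,
                    clustered_fraction = clustered_fraction,
                    n_clusters = n_clusters,
                    cluster_sigma_nm = cluster_sigma_nm,
                    localization_error_nm = localization_error_nm))
}

#' Simulate raw SMLM camera frames from ground-truth molecule positions
#'
#' Each molecule blinks on in a sparse Bernoulli subset of frames and is
#' rendered as a Gaussian PSF spot on a smooth additive background that may
#' drift in amplitude over time; frames carry Poisson noise. A global
#' stage-drift step between the two movie halves can be injected and is
#' recorded in the returned truth.
#'
#' @param positions_nm Two-column matrix of molecule positions (nm).
#' @param image_shape `c(rows, cols)` of the camera frame, px.
#' @param pixel_size_nm Camera pixel size, nm.
#' @param n_frames Number of frames.
#' @param blink_rate Per-frame emission probability of each molecule.
#' @param photons Photons emitted per blink (spot amplitude scale).
#' @param background Mean background photons/pixel.
#' @param background_drift Fractional linear change of the background level
#'   from first to last frame (0 = static).
#' @param psf_sigma_px PSF standard deviation, px (> 0).
#' @param drift_px `c(dx, dy)` pixel shift applied to all molecules from the
#'   movie midpoint on (step drift); `c(0, 0)` for none.
#' @param seed Integer seed.
#' @return List: `stack` (a [frame_stack()] of integer counts), `truth`
#'   (emission table `frame`/`molecule`, the injected `drift_px`, and the
#'   frame index at which it starts).
#' @export
simulate_raw_smlm_frames <- function(positions_nm,
                                     image_shape = c(64, 64),
                                     pixel_size_nm = 100,
                                     n_frames = 200,
                                     blink_rate = 0.01,
                                     photons = 500,
                                     background = 10,
                                     background_drift = 0,
                                     psf_sigma_px = 1.3,
                                     drift_px = c(0, 0),
                                     seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(psf_sigma_px > 0, blink_rate >= 0, blink_rate <= 1)
  set.seed(seed)
  positions_nm <- as.matrix(positions_nm)
  n_mol <- nrow(positions_nm)
  xpx <- positions_nm[, 1] / pixel_size_nm
  ypx <- positions_nm[, 2] / pixel_size_nm
  half <- floor(n_frames / 2) + 1L
  # smooth background: plane with a gentle diagonal ramp
  ramp <- outer(seq(0, 0.2, length.out = image_shape[1]),
                seq(0, 0.2, length.out = image_shape[2]), "+")
  arr <- array(0, dim = c(n_frames, image_shape[1], image_shape[2]))
  emissions <- NULL
  amp <- photons / (2 * pi * psf_sigma_px^2)
  cal <- pixel_calibration(pixel_size_nm, 1, space_unit = "nm",
                           time_unit = "s")
  for (f in seq_len(n_frames)) {
    lev <- background *
      (1 + background_drift * (f - 1) / max(n_frames - 1, 1))
    img <- matrix(lev, image_shape[1], image_shape[2]) + lev * ramp
    on <- if (n_mol > 0 && blink_rate > 0)
      which(stats::runif(n_mol) < blink_rate) else integer(0)
    if (length(on) > 0) {
      dx <- if (f >= half) drift_px[1] else 0
      dy <- if (f >= half) drift_px[2] else 0
      img <- render_blobs(img, xpx[on] + dx, ypx[on] + dy,
                          rep(psf_sigma_px, length(on)),
                          rep(amp, length(on)))
      emissions <- rbind(emissions, data.frame(frame = f, molecule = on))
    }
    arr[f, , ] <- matrix(pmin(stats::rpois(length(img), img), 65535),
                         image_shape[1], image_shape[2])
  }
  list(stack = frame_stack(arr, cal),
       truth = list(emissions = emissions, drift_px = drift_px,
                    drift_start_frame = half, psf_sigma_px = psf_sigma_px,
                    positions_nm = positions_nm))
}
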