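#' Camera noise model for synthetic movies
#'
#' Standard sCMOS/CCD model: Poisson shot noise on (background + signal)
#' photons plus additive Gaussian read noise, rounded to integer counts.
#'
#' @param background Mean background level (photons/pixel).
#' @param peak_photons Peak signal of one aggregate blob (photons).
#' @param read_sd Read noise standard deviation (counts).
#' @return A `noise_model` list; pass `NULL` for noiseless rendering.
#' @export
noise_model <- function(background = 20, peak_photons = 300, read_sd = 3) {
  stopifnot(background >= 0, peak_photons > 0, read_sd >= 0)
  structure(list(background = background, peak_photons = peak_photons,
                 read_sd = read_sd), class = "noise_model")
}

# add Gaussian blobs (amp * exp(-d^2 / (2 sigma^2))) to an image in place,
# rendering only a +/- 3 sigma patch per blob
render_blobs <- function(img, x, y, sigma_px, amp) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(x)) {
    h <- ceiling(3 * sigma_px[i])
    r0 <- max(1, round(y[i]) + 1 - h); r1 <- min(nr, round(y[i]) + 1 + h)
    c0 <- max(1, round(x[i]) + 1 - h); c1 <- min(nc, round(x[i]) + 1 + h)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dy2 <- ((rr - 1) - y[i])^2
    dx2 <- ((cc - 1) - x[i])^2
    img[rr, cc] <- img[rr, cc] +
      amp[i] * exp(-(outer(dy2, dx2, "+")) / (2 * sigma_px[i]^2))
  }
  img
}

#' Simulate a two-channel aggrephagy reporter time-lapse
#'
#' Emulates the tandem-fluorophore reporter logic: each aggregate is visible
#' in the red channel throughout, and in the green channel only while in the
#' `dual` state; quenching of the green fluorophore on lysosomal delivery is
#' modelled as a one-way `dual -> red_only` transition with an exponential
#' waiting time at rate `k_deg`. Aggregates may split symmetrically at rate
#' `k_frag` (children conserve the parent's area and inherit its quenching
#' clock). Aggregates are distinct objects: initial centres are placed with
#' a hard-core minimum separation of twice the largest radius, and all blobs
#' share the same peak brightness (uniform reporter labelling). Images carry
#' Poisson-Gaussian camera noise unless `noise = NULL`.
#'
#' The ground-truth white area fraction at each frame is the ratio of summed
#' noiseless disc footprint areas of dual-state aggregates to that of all
#' aggregates, so with `k_frag = 0` its expectation is exactly
#' `exp(-k_deg * t)`.
#'
#' @param n_aggregates Number of aggregates present at time 0.
#' @param k_deg Quenching (lysosomal delivery) rate, per time unit (>= 0).
#' @param k_frag Fragmentation rate, per aggregate per time unit (>= 0).
#' @param duration Total simulated time.
#' @param frame_interval Time between frames.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param calibration A [pixel_calibration()]; its `frame_interval` should
#'   match `frame_interval`.
#' @param noise A [noise_model()] or `NULL` for noiseless images.
#' @param radius_range_um Aggregate radii are drawn uniformly from this range.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param render If `FALSE`, skip image synthesis and return ground truth
#'   only (used for large-n checks of the decay law).
#' @return List: `green`, `red` ([frame_stack()]s, `NULL` when
#'   `render = FALSE`) and `truth` (frame times, white area fraction,
#'   per-aggregate event table, `k_deg`, `k_frag`).
#' @export
simulate_aggrephagy_timelapse <- function(n_aggregates = 200,
                                          k_deg = 0.1,
                                          k_frag = 0,
                                          duration = 24,
                                          frame_interval = 0.5,
                                          image_shape = c(200, 200),
                                          calibration = pixel_calibration(
                                            1, frame_interval),
                                          noise = noise_model(),
                                          radius_range_um = c(2.5, 3.5),
                                          seed,
                                          render = TRUE) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(k_deg >= 0, k_frag >= 0, duration > 0, frame_interval > 0,
            all(image_shape >= 8))
  set.seed(seed)
  px_um <- pixel_size_um(calibration)
  margin <- ceiling(max(radius_range_um) * 2 / px_um)
  if (render && (image_shape[1] <= 2 * margin || image_shape[2] <= 2 * margin))
    stop("image too small for the aggregate radius range")

  # hard-core placement: puncta are distinct objects, so centres keep a
  # minimum separation of twice the largest radius (only relevant when the
  # cohort is rendered; truth-only runs at large n skip it)
  min_sep_px <- 2 * max(radius_range_um) / px_um
  xs <- stats::runif(1, margin, image_shape[2] - 1 - margin)
  ys <- stats::runif(1, margin, image_shape[1] - 1 - margin)
  if (render) {
    tries <- 0L
    while (length(xs) < n_aggregates) {
      cx <- stats::runif(1, margin, image_shape[2] - 1 - margin)
      cy <- stats::runif(1, margin, image_shape[1] - 1 - margin)
      if (min((xs - cx)^2 + (ys - cy)^2) >= min_sep_px^2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
      tries <- tries + 1L
      if (tries > 2000L * n_aggregates)
        stop("cannot place ", n_aggregates, " aggregates at ",
             round(min_sep_px, 1), " px separation; enlarge image_shape")
    }
  } else {
    xs <- c(xs, stats::runif(n_aggregates - 1, margin,
                             image_shape[2] - 1 - margin))
    ys <- c(ys, stats::runif(n_aggregates - 1, margin,
                             image_shape[1] - 1 - margin))
  }

  # initial cohort; fragments appended as events are processed
  agg <- data.frame(
    id = seq_len(n_aggregates),
    parent_id = NA_integer_,
    birth = 0,
    death = Inf,                        # split time, Inf if never splits
    x = xs,
    y = ys,
    radius_um = stats::runif(n_aggregates, radius_range_um[1],
                             radius_range_um[2]),
    t_conv = if (k_deg > 0) stats::rexp(n_aggregates, k_deg) else
      rep(Inf, n_aggregates))

  if (k_frag > 0) {
    queue <- seq_len(n_aggregates)
    max_total <- 20L * n_aggregates     # guard against runaway branching
    while (length(queue) > 0 && nrow(agg) < max_total) {
      i <- queue[1]; queue <- queue[-1]
      t_split <- agg$birth[i] + stats::rexp(1, k_frag)
      if (t_split >= duration) next
      agg$death[i] <- t_split
      ang <- stats::runif(1, 0, 2 * pi)
      r_child <- agg$radius_um[i] / sqrt(2)   # area conserved across split
      off <- agg$radius_um[i] / px_um
      for (s in c(-1, 1)) {
        child <- data.frame(
          id = nrow(agg) + 1L, parent_id = agg$id[i],
          birth = t_split, death = Inf,
          x = min(max(agg$x[i] + s * off * cos(ang), margin),
                  image_shape[2] - 1 - margin),
          y = min(max(agg$y[i] + s * off * sin(ang), margin),
                  image_shape[1] - 1 - margin),
          radius_um = r_child,
          t_conv = agg$t_conv[i])       # same material, same quenching clock
        agg <- rbind(agg, child)
        queue <- c(queue, nrow(agg))
      }
    }
  }

  times <- seq(0, duration, by = frame_interval)
  area <- pi * agg$radius_um^2
  white_fraction <- vapply(times, function(t) {
    alive <- agg$birth <= t & t < agg$death
    if (!any(alive)) return(NA_real_)
    sum(area[alive & agg$t_conv > t]) / sum(area[alive])
  }, numeric(1))

  green <- red <- NULL
  if (render) {
    amp <- if (is.null(noise)) 1 else noise$peak_photons
    g_arr <- array(0, dim = c(length(times), image_shape[1], image_shape[2]))
    r_arr <- g_arr
    zero <- matrix(0, image_shape[1], image_shape[2])
    for (f in seq_along(times)) {
      t <- times[f]
      alive <- which(agg$birth <= t & t < agg$death)
      dual <- alive[agg$t_conv[alive] > t]
      sig_px <- agg$radius_um / px_um / 2  # blob sd = half the disc radius
      r_img <- render_blobs(zero, agg$x[alive], agg$y[alive],
                            sig_px[alive], rep(amp, length(alive)))
      g_img <- render_blobs(zero, agg$x[dual], agg$y[dual],
                            sig_px[dual], rep(amp, length(dual)))
      if (!is.null(noise)) {
        add_noise <- function(img) {
          counts <- stats::rpois(length(img), lambda = img + noise$background)
          counts <- counts + round(stats::rnorm(length(img), 0,
                                                noise$read_sd))
          matrix(pmin(pmax(counts, 0), 65535), nrow(img), ncol(img))
        }
        r_img <- add_noise(r_img); g_img <- add_noise(g_img)
      }
      r_arr[f, , ] <- r_img
      g_arr[f, , ] <- g_img
    }
    green <- frame_stack(g_arr, calibration)
    red <- frame_stack(r_arr, calibration)
  }

  list(green = green, red = red,
       truth = list(times = times, white_fraction = white_fraction,
                    aggregates = agg, k_deg = k_deg, k_frag = k_frag))
}
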