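#' Grey-value cross-section profile
#'
#' @param positions Strictly increasing sample positions (px or nm).
#' @param values Non-negative, finite grey values; at least 10 samples.
#' @param aggregate Aggregate identifier.
#' @param condition Condition label.
#' @return A `profile_trace` data frame (`position`, `value`) with
#'   attributes `aggregate` and `condition`.
#' @export
profile_trace <- function(positions, values, aggregate = 1L,
                          condition = "unlabelled") {
  stopifnot(length(positions) == length(values))
  if (length(values) < 10) stop("a profile needs at least 10 samples")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("grey values must be finite and non-negative")
  structure(data.frame(position = positions, value = values),
            aggregate = aggregate, condition = condition,
            class = c("profile_trace", "data.frame"))
}

# bilinear interpolation at 0-based pixel-centre coordinates (x, y)
bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(x), 0), nc - 2); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(y), 0), nr - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  v00 <- image[cbind(y0 + 1, x0 + 1)]; v01 <- image[cbind(y0 + 1, x1 + 1)]
  v10 <- image[cbind(y1 + 1, x0 + 1)]; v11 <- image[cbind(y1 + 1, x1 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Extract a grey-value profile along a line segment
#'
#' Samples the image by bilinear interpolation at `n_samples` equally spaced
#' points along the segment. Exact on affine images (constants and linear
#' ramps reproduce exactly).
#'
#' @param image 2-D numeric matrix.
#' @param line_endpoints 2x2 matrix `rbind(c(x0, y0), c(x1, y1))` in 0-based
#'   pixel-centre coordinates; both endpoints must lie inside the image.
#' @param n_samples Number of samples (>= 10).
#' @param aggregate,condition Labels recorded on the trace.
#' @return A [profile_trace()]; positions are distances along the segment in
#'   pixels.
#' @export
extract_profile <- function(image, line_endpoints, n_samples = 100,
                            aggregate = 1L, condition = "unlabelled") {
  stopifnot(is.matrix(image), n_samples >= 10)
  ep <- as.matrix(line_endpoints)
  stopifnot(identical(dim(ep), c(2L, 2L)))
  if (any(ep[, 1] < 0) || any(ep[, 1] > ncol(image) - 1) ||
      any(ep[, 2] < 0) || any(ep[, 2] > nrow(image) - 1))
    stop("line endpoints fall outside the image")
  t <- seq(0, 1, length.out = n_samples)
  x <- ep[1, 1] + t * (ep[2, 1] - ep[1, 1])
  y <- ep[1, 2] + t * (ep[2, 2] - ep[1, 2])
  len <- sqrt(sum((ep[2, ] - ep[1, ])^2))
  v <- bilinear(image, x, y)
  # positions must be strictly increasing even for a degenerate segment
  pos <- if (len > 0) t * len else seq_along(t) - 1
  profile_trace(pos, pmax(v, 0), aggregate = aggregate,
                condition = condition)
}

#' Random cross-section chord within a mask
#'
#' Seeds a uniform random chord through the masked region: a random interior
#' point and direction, extended to the mask boundary on both sides. Used
#' when no manually placed cross-section is supplied.
#'
#' @param mask Logical matrix marking the aggregate footprint.
#' @param seed Integer seed.
#' @return 2x2 endpoint matrix in 0-based pixel-centre coordinates, usable
#'   with [extract_profile()].
#' @export
random_chord <- function(mask, seed) {
  if (missing(seed)) stop("seed must be given")
  set.seed(seed)
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty")
  pick <- sample(idx, 1)
  py <- (pick - 1) %% nrow(mask)
  px <- (pick - 1) %/% nrow(mask)
  ang <- stats::runif(1, 0, pi)
  dir <- c(cos(ang), sin(ang))
  extend <- function(s) {
    t <- 0
    repeat {
      x <- px + (t + s) * dir[1]; y <- py + (t + s) * dir[2]
      r <- round(y) + 1; c <- round(x) + 1
      if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) ||
          !mask[r, c]) break
      t <- t + s
    }
    t
  }
  t_pos <- extend(0.5); t_neg <- extend(-0.5)
  rbind(c(px + t_neg * dir[1], py + t_neg * dir[2]),
        c(px + t_pos * dir[1], py + t_pos * dir[2]))
}

#' Mean grey value of a profile
#'
#' The per-aggregate mean line drawn through cross-section plots, and the
#' normalizer used by [normalized_spread()].
#'
#' @param trace A [profile_trace()].
#' @return Arithmetic mean of the grey values.
#' @export
profile_mean_line <- function(trace) {
  stopifnot(inherits(trace, "profile_trace"))
  mean(trace$value)
}

#' Normalized grey-value spread per condition
#'
#' Normalizes every sample of each cross-section against its aggregate's
#' mean grey value (so each aggregate's normalized values average 1),
#' pools the normalized values per condition, bins them into a histogram
#' with equal-width bins over a range shared across conditions, and reports
#' the standard deviation of the normalized values as the spread statistic.
#' A broad spread indicates loose aggregate packing, a narrow one a compact
#' aggregate. Per-aggregate normalization makes the result invariant to
#' rescaling any single trace.
#'
#' @param traces List of [profile_trace()] objects (each carries its
#'   aggregate id and condition label).
#' @param n_bins Number of equal-width histogram bins (shared range
#'   `[0, max normalized value]` across conditions).
#' @return A `spread_result` list: `per_condition` data frame (condition,
#'   n_samples, n_aggregates, spread = SD of normalized values),
#'   `histograms` (per condition: breaks and counts summing to the sample
#'   count), `normalized` (long data frame of normalized values).
#' @export
normalized_spread <- function(traces, n_bins = 20) {
  stopifnot(is.list(traces), length(traces) > 0, n_bins >= 2)
  long <- do.call(rbind, lapply(traces, function(tr) {
    stopifnot(inherits(tr, "profile_trace"))
    m <- profile_mean_line(tr)
    if (m <= 0) stop("aggregate ", attr(tr, "aggregate"),
                     " has a non-positive mean grey value")
    data.frame(condition = attr(tr, "condition"),
               aggregate = attr(tr, "aggregate"),
               normalized = tr$value / m)
  }))
  breaks <- seq(0, max(long$normalized), length.out = n_bins + 1)
  conds <- unique(long$condition)
  histograms <- lapply(conds, function(cd) {
    v <- long$normalized[long$condition == cd]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(histograms) <- conds
  per_condition <- do.call(rbind, lapply(conds, function(cd) {
    v <- long$normalized[long$condition == cd]
    data.frame(condition = cd, n_samples = length(v),
               n_aggregates = length(unique(
                 long$aggregate[long$condition == cd])),
               spread = stats::sd(v))
  }))
  structure(list(per_condition = per_condition, histograms = histograms,
                 normalized = long),
            class = "spread_result")
}
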