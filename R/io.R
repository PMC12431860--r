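#' @importFrom utils read.csv write.csv head
NULL

# message() wrapper used by every filtering step so record flow is auditable
log_filter <- function(stage, n_before, n_after, what = "records") {
  message(sprintf("[%s] %d -> %d %s (%d dropped)",
                  stage, n_before, n_after, what, n_before - n_after))
}

#' Write a frame stack to a multi-page 16-bit TIFF
#'
#' Pixel values must be integer-valued counts in `[0, 65535]`; they are stored
#' as 16-bit samples so that [read_stack()] recovers them bit-exactly.
#'
#' @param stack A [frame_stack()], or a named list of them (one per channel);
#'   multi-channel stacks are stored with one sample per channel per page
#'   (TIFF samples-per-pixel), one page per frame.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "frame_stack")) stack <- list(stack)
  stopifnot(all(vapply(stack, inherits, logical(1), "frame_stack")))
  nf <- unique(vapply(stack, n_frames, integer(1)))
  if (length(nf) != 1) stop("all channels must have the same frame count")
  pages <- lapply(seq_len(nf), function(i) {
    chans <- lapply(stack, function(s) get_frame(s, i))
    bad <- vapply(chans, function(m)
      any(m < 0 | m > 65535 | abs(m - round(m)) > 1e-6), logical(1))
    if (any(bad))
      stop("pixel values must be integers in [0, 65535] for 16-bit storage")
    if (length(chans) == 1) return(round(chans[[1]]) / 65535)
    a <- array(0, dim = c(dim(chans[[1]]), length(chans)))
    for (k in seq_along(chans)) a[, , k] <- round(chans[[k]])
    a / 65535
  })
  suppressWarnings(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE))
  invisible(path)
}

#' Read a TIFF image stack
#'
#' Accepts 2-D single images, multi-page `(t, y, x)` single-channel stacks
#' and multi-sample pages `(t, c, y, x)` (samples interpreted as channels);
#' the axis order is normalized to `(t, y, x)` and one [frame_stack()] is
#' returned per channel. Integer intensities written by [write_stack()] are
#' recovered bit-exactly (sample values normalized to `[0, 1]` by the TIFF
#' reader are rescaled by the file's declared bit depth).
#'
#' @param path TIFF file path.
#' @param calibration A [pixel_calibration()] attached to every channel.
#' @return Named list of [frame_stack()] objects (`channel1`, `channel2`, ...).
#' @export
read_stack <- function(path, calibration) {
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                    info = TRUE)),
    error = function(e) stop("unreadable TIFF '", path, "': ",
                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("pages of '", path, "' differ in shape; assumed layout is ",
         "(t, y, x) or (t, c, y, x) multi-sample pages of constant geometry")
  d <- dims[[1]]
  n_chan <- if (length(d) == 3) d[3] else 1L
  # multi-sample pages come back normalized to [0, 1] even with as.is
  rescale <- vapply(pages, function(p) max(p) <= 1 && !is.integer(p),
                    logical(1))
  bits <- attr(pages[[1]], "bits.per.sample")
  scale <- if (is.null(bits)) 65535 else 2^bits - 1
  channels <- lapply(seq_len(n_chan), function(k) {
    a <- array(0, dim = c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) {
      pg <- if (length(d) == 2) pages[[i]] else pages[[i]][, , k]
      a[i, , ] <- if (rescale[i]) round(pg * scale) else pg
    }
    frame_stack(a, calibration)
  })
  names(channels) <- paste0("channel", seq_len(n_chan))
  channels
}

#' Localization table constructor
#'
#' @param x_nm,y_nm Molecule coordinates in nm (finite).
#' @param frame Acquisition frame index of each localization.
#' @param sigma_nm Localization error (nm, > 0).
#' @return A `localization_table` data frame with columns
#'   `x_nm`, `y_nm`, `frame`, `sigma_nm`.
#' @export
localization_table <- function(x_nm, y_nm, frame, sigma_nm) {
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   frame = as.integer(frame), sigma_nm = as.numeric(sigma_nm))
  if (nrow(df) > 0) {
    stopifnot(all(is.finite(df$x_nm)), all(is.finite(df$y_nm)),
              all(df$sigma_nm > 0))
  }
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Read an SMLM localization table from CSV
#'
#' Requires columns `x`, `y` (or `x_nm`, `y_nm`; values in nm) and `frame`;
#' an optional uncertainty column (`sigma_nm`, `sigma` or `uncertainty_nm`)
#' is carried as the localization error, defaulting to `default_sigma_nm`
#' when absent. Rows with non-finite coordinates are dropped with a logged
#' count.
#'
#' @param path CSV file path.
#' @param default_sigma_nm Localization error assigned when the file has no
#'   uncertainty column (nm).
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, default_sigma_nm = 10) {
  df <- read.csv(path, check.names = FALSE)
  pick <- function(cands) {
    hit <- cands[cands %in% names(df)]
    if (length(hit)) df[[hit[1]]] else NULL
  }
  x <- pick(c("x_nm", "x")); y <- pick(c("y_nm", "y"))
  fr <- pick(c("frame"))
  for (nm in c("x", "y", "frame")[c(is.null(x), is.null(y), is.null(fr))])
    stop("missing required column '", nm, "' in '", path, "'")
  sg <- pick(c("sigma_nm", "sigma", "uncertainty_nm", "uncertainty"))
  if (is.null(sg)) sg <- rep(default_sigma_nm, nrow(df))
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) log_filter("read_localizations", length(keep), sum(keep))
  localization_table(x[keep], y[keep], fr[keep], sg[keep])
}

#' Write an SMLM localization table to CSV
#'
#' Column order is fixed (`x_nm`, `y_nm`, `frame`, `sigma_nm`) and units are
#' part of the header names; [read_localizations()] round-trips the values
#' within float formatting precision.
#'
#' @param locs A [localization_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(inherits(locs, "localization_table"))
  write_table(locs[, c("x_nm", "y_nm", "frame", "sigma_nm")], path)
}

#' Write any tabular result to CSV
#'
#' Used for puncta tables, cluster summaries and time series; columns are
#' written in their existing (stable) order, without row names. An empty
#' table produces a header-only file.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
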