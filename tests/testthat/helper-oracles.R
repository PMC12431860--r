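# Independent brute-force oracles used across tests. These stay deliberately
# naive (double loops, queue-based flood fill) so they share no code path
# with the implementation they check.

oracle_mean_nn <- function(points) {
  n <- nrow(points)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((points[i, 1] - points[j, 1])^2 +
                (points[i, 2] - points[j, 2])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}

oracle_local_density <- function(points, radius) {
  n <- nrow(points)
  out <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((points[i, 1] - points[j, 1])^2 +
                (points[i, 2] - points[j, 2])^2)
      if (d <= radius) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

# 8-connected component labelling by breadth-first flood fill
oracle_label <- function(mask) {
  lb <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lb[r0, c0] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lb[r0, c0] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) next
        if (mask[r, c] && lb[r, c] == 0) {
          lb[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lb
}

# image of Gaussian blobs at 0-based centres, used as a segmentation fixture
blob_image <- function(shape, centres, sigma, amp = 100, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centres)))
    img <- img + amp * exp(-(outer(((seq_len(shape[1]) - 1) -
                                      centres[i, 2])^2,
                                   ((seq_len(shape[2]) - 1) -
                                      centres[i, 1])^2, "+")) /
                             (2 * sigma^2))
  img
}
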