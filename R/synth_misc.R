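# moments of a normal(mu, sigma) truncated at zero
trunc_norm_moments <- function(mu, sigma) {
  alpha <- -mu / sigma
  z <- 1 - stats::pnorm(alpha)
  lambda <- stats::dnorm(alpha) / z
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent (mu, sigma) so the zero-truncated distribution has the target
# mean and sd; negligible adjustment when cv is small
solve_trunc_norm <- function(target_mean, target_sd) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(p) {
    mo <- trunc_norm_moments(p[1], exp(p[2]))
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Simulate a grey-value cross-section profile
#'
#' Positive grey values drawn from a zero-truncated Gaussian whose parent
#' parameters are moment-matched so the *truncated* distribution has mean
#' `mean_level` and coefficient of variation `cv` — the generator for
#' compact (low CV) versus loose (high CV) aggregate cross-sections.
#'
#' @param length Number of samples (>= 10).
#' @param mean_level Target mean grey value (> 0).
#' @param cv Target coefficient of variation (>= 0); `cv = 0` gives a
#'   constant profile.
#' @param aggregate Aggregate identifier recorded on the trace.
#' @param condition Condition label recorded on the trace.
#' @param seed Integer seed.
#' @return A `profile_trace` data frame (`position`, `value`) with
#'   attributes `aggregate` and `condition`.
#' @export
simulate_profile <- function(length = 200, mean_level = 100, cv = 0.2,
                             aggregate = 1L, condition = "synthetic", seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(length >= 10, mean_level > 0, cv >= 0)
  set.seed(seed)
  if (cv == 0) {
    v <- rep(mean_level, length)
  } else {
    par <- solve_trunc_norm(mean_level, cv * mean_level)
    v <- stats::rnorm(length, par["mu"], par["sigma"])
    while (any(v <= 0))
      v[v <= 0] <- stats::rnorm(sum(v <= 0), par["mu"], par["sigma"])
  }
  profile_trace(seq_len(length) - 1, v, aggregate = aggregate,
                condition = condition)
}

#' Simulate a FRAP recovery trace
#'
#' `n_prebleach` frames at the pre-bleach intensity, then single-exponential
#' recovery `I(t) = i_post + mobile_fraction * (i_pre - i_post) *
#' (1 - exp(-k_rec * t))` with `t` counted from the first post-bleach frame,
#' plus optional Gaussian noise. Defaults mirror a typical confocal FRAP
#' protocol of 80 frames sampled every 10 s with two pre-bleach frames.
#'
#' @param i_pre Pre-bleach intensity (> `i_post`).
#' @param i_post Intensity immediately after the bleach.
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param k_rec Recovery rate constant (per second, >= 0).
#' @param n_frames Total frames (> `n_prebleach`).
#' @param dt Frame interval, seconds.
#' @param n_prebleach Frames acquired before the bleach.
#' @param noise_sd Gaussian noise s.d. added to every frame (0 = noiseless).
#' @param seed Integer seed (only needed when `noise_sd > 0`).
#' @return A [time_series()] in seconds.
#' @export
simulate_frap <- function(i_pre = 1000, i_post = 300, mobile_fraction = 0.7,
                          k_rec = 0.02, n_frames = 80, dt = 10,
                          n_prebleach = 2, noise_sd = 0, seed = 1L) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, i_post < i_pre,
            k_rec >= 0, dt > 0)
  if (n_prebleach >= n_frames)
    stop("n_prebleach must be smaller than n_frames")
  set.seed(seed)
  t_abs <- (seq_len(n_frames) - 1) * dt
  tau <- (seq_len(n_frames) - n_prebleach - 1) * dt   # 0 at first post frame
  v <- ifelse(seq_len(n_frames) <= n_prebleach, i_pre,
              i_post + mobile_fraction * (i_pre - i_post) *
                (1 - exp(-k_rec * tau)))
  if (noise_sd > 0) v <- v + stats::rnorm(n_frames, 0, noise_sd)
  time_series(t_abs, v, unit = "s", label = "FRAP intensity")
}
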