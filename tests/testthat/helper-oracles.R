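# Independent oracles used across the suite.

# Exhaustive two-sided Mann-Whitney p-value: enumerate every assignment of
# the pooled ranks to group x, build the exact U distribution, and apply
# the standard two-sided rule (double the smaller tail, capped at 1).
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) {
    xs <- pooled[ii]; ys <- pooled[-ii]
    sum(outer(xs, ys, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p_lower <- mean(us <= u_obs)
  p_upper <- mean(us >= u_obs)
  if (u_obs > nx * ny / 2) min(2 * p_upper, 1) else min(2 * p_lower, 1)
}

# Textbook pooled-variance two-sample t-test.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, p_value = 2 * pt(-abs(t), df))
}

# Dominant frequency (Hz) of a uniformly sampled series, by FFT peak.
fft_peak_hz <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  sp <- Mod(fft(v))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  freqs[which.max(sp[-1]) + 1]
}

# Small moving-blob video for tracking tests: a bright square moving
# linearly from (x0, y0) to (x1, y1) in px on a dark background.
make_blob_stack <- function(n_frames = 40, size = 64, from = c(10, 10),
                            to = c(50, 50), half = 2, fps = 20,
                            pixel_size = NULL) {
  frames <- array(0, dim = c(size, size, n_frames))
  xs <- seq(from[1], to[1], length.out = n_frames)
  ys <- seq(from[2], to[2], length.out = n_frames)
  for (k in seq_len(n_frames)) {
    cx <- round(xs[k]); cy <- round(ys[k])
    frames[(cy - half):(cy + half), (cx - half):(cx + half), k] <- 1
  }
  frame_stack(frames, fps = fps, pixel_size = pixel_size)
}
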