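# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Direct discrete Gaussian convolution with clamped (edge-replicated)
# indices.
oracle_gaussian_blur <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  g <- dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      s <- s + k[di + r + 1, dj + r + 1] * x[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# Explicit per-pixel scan count of intensities strictly above a threshold.
oracle_scan_count <- function(x, threshold) {
  n <- 0L
  v <- as.vector(x)
  for (i in seq_along(v)) if (v[i] > threshold) n <- n + 1L
  n
}

# Per-pixel clipped difference, by loop.
oracle_subtract_invert <- function(img, bg) {
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    d <- bg[i, j] - img[i, j]
    out[i, j] <- min(max(d, 0), 255)
  }
  out
}

# Quadratic least squares by hand-coded normal equations.
oracle_quadratic_fit <- function(p, y) {
  X <- cbind(1, p, p^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(c = beta[1], b = beta[2], a = beta[3])
}

# Build a one-well trace from per-phase levels under a schedule.
make_trace <- function(ocr_by_phase, ecar_by_phase = NULL,
                       schedule = injection_schedule(), well = "A01",
                       ocr_noise_sd = 0, ecar_noise_sd = 0) {
  phases <- schedule_phases(schedule)
  n <- schedule$n_cycles
  if (is.null(ecar_by_phase))
    ecar_by_phase <- setNames(rep(10, length(unique(phases))), unique(phases))
  data.frame(
    plate_id = "t", well = well, cycle = seq_len(n),
    time_min = seq_len(n) * 5,
    ocr = unname(ocr_by_phase[phases]) + rnorm(n, sd = ocr_noise_sd),
    ecar = unname(ecar_by_phase[phases]) + rnorm(n, sd = ecar_noise_sd),
    phase = phases, stringsAsFactors = FALSE)
}
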