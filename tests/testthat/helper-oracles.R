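# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's vectorised code paths.

# Population/sample variance of the dB-scaled sequence, plain double loop.
brute_liv <- function(x_linear, db_floor = 1e-12, divisor = c("N", "N-1")) {
  divisor <- match.arg(divisor)
  x <- 10 * log10(x_linear + db_floor)
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v / n
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  ss / (if (divisor == "N") n else n - 1)
}

# Lag-k Pearson autocorrelation with global mean/variance normalisation and
# pair averaging over the N - k available pairs, plain double loop.
brute_lag_correlation <- function(x, k) {
  n <- length(x)
  mu <- mean(x)
  den <- 0
  for (v in x) den <- den + (v - mu)^2 / n
  num <- 0
  for (t in seq_len(n - k)) num <- num + (x[t] - mu) * (x[t + k] - mu) / (n - k)
  num / den
}

# Welch statistic from the textbook formulas.
brute_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t_stat), dof)
  c(t = t_stat, dof = dof, p = p)
}

# Negated OLS slope of a curve y over x, via lm().
brute_negated_slope <- function(x, y) -unname(coef(lm(y ~ x))[2])

# Tiny protocol: one block, `n_loc` locations, small frames.
tiny_protocol <- function(n_loc = 2, n_repeats = 8, depth = 4, lateral = 5,
                          frame_interval = 204.8) {
  scan_protocol(n_blocks = 1, locations_per_block = n_loc,
                n_repeats = n_repeats, frame_interval = frame_interval,
                fov_lateral = c(lateral * 0.01, n_loc * 0.01),
                a_lines_per_frame = lateral, n_depth_pixels = depth,
                depth_pixel_size = 10)
}

# Series with a caller-supplied per-voxel generator `fun(loc, d, w)` that
# returns the n_repeats intensity samples of that voxel.
make_series <- function(protocol, fun, provenance = "test") {
  p <- protocol
  arr <- array(0, dim = c(p$n_locations, p$n_repeats, p$n_depth_pixels,
                          p$a_lines_per_frame))
  for (i in seq_len(p$n_locations)) {
    for (d in seq_len(p$n_depth_pixels)) {
      for (w in seq_len(p$a_lines_per_frame)) {
        arr[i, , d, w] <- fun(i, d, w)
      }
    }
  }
  frame_timeseries(arr, p, provenance)
}

# Simulated uniform-region series (no PSF, optional noise).
simulate_uniform <- function(protocol, m, tau_c, seed, noise_floor = 0) {
  ph <- uniform_label_volume(protocol, region_dynamics(m, tau_c),
                             noise_floor = noise_floor, seed = seed)
  simulate_timeseries(ph, protocol, seed = seed)
}
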