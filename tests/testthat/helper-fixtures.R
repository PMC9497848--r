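# Shared fixture builders (all generated in code, seeded).

noise_dyad <- function(L = 600, seed = 1, sd = 1, fps = 25) {
  set.seed(seed)
  dyad_ts(pmin(pmax(10 + rnorm(L, 0, sd), 0), 100),
          pmin(pmax(10 + rnorm(L, 0, sd), 0), 100),
          fps = fps, id = sprintf("noise%d", seed))
}

# dyad whose B is a lagged noiseless copy of A inside [start, end); the
# member series themselves carry noise so every window has variance
copy_dyad <- function(L = 1500, start = 400, end = 900, lag = 10, seed = 2,
                      fps = 25, noise_sd = 1) {
  cfg <- dyad_config(length_frames = L, noise_sd = noise_sd, baseline = 2,
                     burst_rate = 6, burst_duration_frames = 80,
                     burst_amplitude = 30, fps = fps)
  generate_coupled_dyad(cfg, coupling_interval(start, end, lag, 1, 1),
                        seed = seed, id = "copy", coupling_noise_sd = 0)
}

# noise-driven dyad (no bursts) with a noiseless lagged copy injected:
# the cleanest fixture for interval-recovery checks
noise_copy_dyad <- function(L = 2000, start = 600, end = 1200, lag = 30,
                            seed = 2, fps = 25) {
  cfg <- dyad_config(length_frames = L, burst_rate = 0, noise_sd = 3,
                     baseline = 10, fps = fps)
  generate_coupled_dyad(cfg, coupling_interval(start, end, lag, 1, 1),
                        seed = seed, id = "noise_copy", coupling_noise_sd = 0)
}

# small cohort of independent-noise dyads for calibration checks
noise_cohort <- function(n = 6, L = 600, seed = 1) {
  lapply(seq_len(n), function(i) noise_dyad(L = L, seed = seed + i))
}

# planted factor data: p variables, loadings `load` on `k` orthogonal factors
planted_factor_data <- function(n = 200, k = 2, p_per = 4, load = 0.8,
                                seed = 1) {
  set.seed(seed)
  p <- k * p_per
  F <- matrix(rnorm(n * k), n, k)
  Lam <- matrix(0, p, k)
  for (f in seq_len(k)) Lam[((f - 1) * p_per + 1):(f * p_per), f] <- load
  X <- F %*% t(Lam) + matrix(rnorm(n * p, 0, sqrt(1 - load^2)), n, p)
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(p))
  df
}
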