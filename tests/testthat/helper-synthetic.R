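# builders shared across test files; all fixtures are generated in code

# single-region oscillating stack, flat background so expectations are
# closed-form
make_sin_stack <- function(f_hz, fps = 500, n = 1000, h = 16, w = 16,
                           amplitude = 20, background = 100,
                           noise_sigma = 0, bit_depth = NULL, seed = 1,
                           wavelength_px = Inf, drift = NULL) {
  cfg <- sim_config(
    fps = fps, n_frames = n, height = h, width = w,
    regions = list(sim_region("rect", cbf_hz = f_hz,
                              amplitude = amplitude, x0 = 0, y0 = 0,
                              width = w, height = h,
                              wavelength_px = wavelength_px)),
    background = background, noise_sigma = noise_sigma,
    drift = drift, bit_depth = bit_depth, seed = seed)
  simulate_cilia_stack(cfg)
}

# textured-background stack with a centered oscillating disk:
# the registration test bed
make_patch_stack <- function(f_hz = 10, fps = 500, n = 80, h = 40, w = 40,
                             amplitude = 15, noise_sigma = 0,
                             bit_depth = 8, seed = 5, drift = NULL) {
  cfg <- sim_config(
    fps = fps, n_frames = n, height = h, width = w,
    regions = list(sim_region("disk", cbf_hz = f_hz,
                              amplitude = amplitude,
                              cx = floor((w - 1) / 2),
                              cy = floor((h - 1) / 2),
                              radius = floor(min(h, w) / 5))),
    noise_sigma = noise_sigma, drift = drift,
    bit_depth = bit_depth, seed = seed)
  simulate_cilia_stack(cfg)
}

make_sin_trace <- function(f_hz, fps = 500, n = 1000, amplitude = 20,
                           offset = 100, noise_sigma = 0, seed = 1) {
  t0 <- (seq_len(n) - 1) / fps
  v <- offset + amplitude * sin(2 * pi * f_hz * t0)
  if (noise_sigma > 0) {
    v <- v + withr::with_seed(seed, rnorm(n, 0, noise_sigma))
  }
  beat_trace(v, fps)
}

# cohort table whose per-method group medians are exact by
# construction: symmetric offsets around the target median
make_median_fixture <- function(medians = list(
                                  manual = c(PCD = 9.2, HC = 11.1),
                                  mean_psd = c(PCD = 8.8, HC = 10.7),
                                  histogram = c(PCD = 8.7, HC = 10.8)),
                                n_pcd = 115, n_hc = 60) {
  offsets <- function(n) {
    k <- stats::qnorm(stats::ppoints(n))
    0.6 * (k - (k[n] + k[1]) / 2)   # symmetric: median lands exactly
  }
  rows <- list()
  for (m in names(medians)) {
    for (g in c("PCD", "HC")) {
      n <- if (g == "PCD") n_pcd else n_hc
      vals <- medians[[m]][[g]] + offsets(n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = sprintf("%s_s%03d", g, seq_len(n)),
        group = g,
        recording = sprintf("%s_r%03d", g, seq_len(n)),
        method = m,
        cbf_hz = vals)
    }
  }
  dplyr::bind_rows(rows)
}
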