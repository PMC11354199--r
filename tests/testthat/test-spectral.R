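# dense zero-padded DFT band power of one centered series: the
# independent oracle for leakage bookkeeping
dense_band_power <- function(x, fps, band, pad = 16L) {
  n <- length(x)
  xc <- x - mean(x)
  np <- n * pad
  X <- fft(c(xc, rep(0, np - n)))
  k <- 0:(np - 1)
  f <- k * fps / np
  one_sided <- f <= fps / 2
  mult <- ifelse(f == 0 | abs(f - fps / 2) < 1e-12, 1, 2)
  # |X|^2 / (n * pad): spreads the length-n energy over pad-times
  # denser bins so the one-sided sum still equals n * var
  p <- Mod(X)^2 / np * mult
  sum(p[one_sided & f >= band[1] & f <= band[2]])
}

test_that("static stacks carry no spectral power", {
  stk <- frame_stack(array(37, dim = c(64, 4, 4)), fps = 500)
  sp <- pixel_power_spectra(stk, band = c(1, 30))
  expect_true(all(sp$psd == 0))
  expect_error(mean_psd_cbf(sp), "no spectral power")
})

test_that("an on-grid sinusoid concentrates all power in its bin", {
  sim <- make_sin_stack(10, fps = 500, n = 1000, h = 3, w = 3,
                        bit_depth = NULL)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.5)
  px <- sp$psd[, 5]
  on_bin <- which(sp$freqs == 10)
  expect_gt(px[on_bin], 0)
  expect_lt(max(px[-on_bin]), 1e-15 * px[on_bin])
})

test_that("off-grid frequencies land in an adjacent bin and conserve band power", {
  sim <- make_sin_stack(10.2, fps = 500, n = 1000, h = 2, w = 2,
                        bit_depth = NULL)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  est <- mean_psd_cbf(sp)
  expect_true(est$value_hz %in% c(10.0, 10.5))

  x <- sim$stack$frames[, 1, 1]
  ours <- sum(sp$psd[ciliafreq:::band_index(sp), 1])
  oracle <- dense_band_power(x, 500, c(1, 30))
  expect_lt(abs(ours - oracle) / oracle, 0.01)
})

test_that("Parseval holds per pixel under the one-sided normalization", {
  set.seed(21)
  arr <- array(rnorm(256 * 5 * 5, 100, 12), dim = c(256, 5, 5))
  stk <- frame_stack(arr, fps = 500)
  sp <- pixel_power_spectra(stk, band = c(1, 30))
  for (j in c(1L, 7L, 25L)) {
    v <- arr[, (j - 1) %% 5 + 1, (j - 1) %/% 5 + 1]
    expect_equal(sum(sp$psd[, j]), 256 * mean((v - mean(v))^2),
                 tolerance = 1e-9)
  }
  # odd frame count exercises the no-Nyquist-bin branch
  sp_odd <- pixel_power_spectra(
    frame_stack(arr[1:255, , , drop = FALSE], fps = 500), band = c(1, 30))
  v <- arr[1:255, 1, 1]
  expect_equal(sum(sp_odd$psd[, 1]), 255 * mean((v - mean(v))^2),
               tolerance = 1e-9)
})

test_that("the mean-PSD equals the average of per-pixel periodograms", {
  set.seed(33)
  arr <- array(rnorm(64 * 4 * 4, 0, 5), dim = c(64, 4, 4))
  stk <- frame_stack(arr, fps = 500)
  sp <- pixel_power_spectra(stk, band = c(1, 30))
  # brute-force loop oracle
  acc <- numeric(33)
  for (y in 1:4) for (x in 1:4) {
    v <- arr[, y, x] - mean(arr[, y, x])
    P <- Mod(fft(v)[1:33])^2 / 64
    P[2:32] <- 2 * P[2:32]
    acc <- acc + P
  }
  expect_equal(rowMeans(sp$psd), acc / 16, tolerance = 1e-12)
})

test_that("the mean-PSD peak weights regions by squared amplitude", {
  # equal areas; 8 Hz at amplitude 20 dominates 12 Hz at amplitude 10
  cfg <- sim_config(
    fps = 500, n_frames = 500, height = 8, width = 16,
    regions = list(
      sim_region("rect", cbf_hz = 8, amplitude = 20, x0 = 0, y0 = 0,
                 width = 8, height = 8),
      sim_region("rect", cbf_hz = 12, amplitude = 10, x0 = 8, y0 = 0,
                 width = 8, height = 8)),
    background = 100, noise_sigma = 0, bit_depth = NULL, seed = 2)
  sim <- simulate_cilia_stack(cfg)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  expect_equal(mean_psd_cbf(sp)$value_hz, 8.0)
})

test_that("the dominant-frequency map matches the simulator ground truth", {
  cfg <- sim_config(
    fps = 500, n_frames = 500, height = 10, width = 20,
    regions = list(
      sim_region("rect", cbf_hz = 8, amplitude = 15, x0 = 0, y0 = 0,
                 width = 12, height = 10),
      sim_region("rect", cbf_hz = 12, amplitude = 15, x0 = 12, y0 = 0,
                 width = 8, height = 10)),
    background = 50, noise_sigma = 0, bit_depth = NULL, seed = 4)
  sim <- simulate_cilia_stack(cfg)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  fm <- dominant_frequency_map(sp)
  expect_identical(fm$map, sim$truth$frequency_map)
})

test_that("oscillation-free background pixels are undefined in the map", {
  sim <- make_patch_stack(n = 64, noise_sigma = 0)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  fm <- dominant_frequency_map(sp)
  expect_true(all(is.na(fm$map[is.na(sim$truth$frequency_map)])))
  expect_true(all(!is.na(fm$map[!is.na(sim$truth$frequency_map)])))
})

test_that("histograms report counts, percentages and the modal bin", {
  sim <- make_sin_stack(10, fps = 500, n = 500, h = 6, w = 6,
                        bit_depth = NULL)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  h <- cbf_histogram(dominant_frequency_map(sp))
  occupied <- h$distribution[h$distribution$count > 0, ]
  expect_equal(nrow(occupied), 1L)
  expect_equal(occupied$bin_center_hz, 10)
  expect_equal(occupied$percentage, 100)
  expect_equal(h$estimate$value_hz, 10)
  expect_equal(h$estimate$method, "histogram_mode")
})

test_that("a 60/40 area split yields 60/40 percentages and the lower mode", {
  cfg <- sim_config(
    fps = 500, n_frames = 500, height = 10, width = 10,
    regions = list(
      sim_region("rect", cbf_hz = 8, amplitude = 15, x0 = 0, y0 = 0,
                 width = 6, height = 10),
      sim_region("rect", cbf_hz = 12, amplitude = 15, x0 = 6, y0 = 0,
                 width = 4, height = 10)),
    background = 50, noise_sigma = 0, bit_depth = NULL, seed = 4)
  sim <- simulate_cilia_stack(cfg)
  sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
  h <- cbf_histogram(dominant_frequency_map(sp))
  d <- h$distribution
  expect_equal(d$percentage[d$bin_center_hz == 8], 60)
  expect_equal(d$percentage[d$bin_center_hz == 12], 40)
  expect_equal(h$estimate$value_hz, 8)
})

test_that("percentages always sum to 100 over seeded random maps", {
  for (s in 1:5) {
    sim <- make_patch_stack(f_hz = 6 + s, n = 64, noise_sigma = 2,
                            seed = s)
    sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
    h <- cbf_histogram(dominant_frequency_map(sp))
    expect_equal(sum(h$distribution$percentage), 100, tolerance = 1e-9)
  }
})

test_that("halving the frame count doubles the grid spacing", {
  sim <- make_sin_stack(10, fps = 500, n = 1000, h = 2, w = 2,
                        bit_depth = NULL)
  sp1000 <- pixel_power_spectra(sim$stack, n_frames = 1000,
                                band = c(1, 30))
  sp500 <- pixel_power_spectra(sim$stack, n_frames = 500,
                               band = c(1, 30))
  expect_equal(diff(sp1000$freqs[1:2]), 0.5)
  expect_equal(diff(sp500$freqs[1:2]), 1.0)
})

test_that("on-grid recovery survives sensor noise at SNR >= 10", {
  # amplitude 20, sigma 4 -> SNR = A^2 / (2 sigma^2) = 12.5
  hits <- 0L
  for (s in 1:100) {
    sim <- make_sin_stack(10, fps = 250, n = 250, h = 12, w = 12,
                          amplitude = 20, noise_sigma = 4,
                          bit_depth = 8, seed = 1000 + s)
    sp <- pixel_power_spectra(sim$stack, band = c(1, 30))
    if (mean_psd_cbf(sp)$value_hz == 10) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("band validation rejects empty and out-of-range bands", {
  sim <- make_sin_stack(10, n = 100, h = 2, w = 2)
  expect_error(pixel_power_spectra(sim$stack, band = c(0, 30)), "band")
  expect_error(pixel_power_spectra(sim$stack, band = c(1, 400)), "band")
  expect_error(pixel_power_spectra(sim$stack, n_frames = 2000), "exceeds")
})
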