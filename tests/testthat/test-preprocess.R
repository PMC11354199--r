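rot90_oracle <- function(m) t(m)[ncol(m):1, , drop = FALSE]

test_that("quarter-turn rotations are exact index permutations", {
  sim <- make_patch_stack(n = 6, h = 10, w = 14)
  stk <- sim$stack

  expect_identical(rotate_frames(stk, 0)$frames, stk$frames)
  expect_identical(rotate_frames(stk, 360)$frames, stk$frames)

  r90 <- rotate_frames(stk, 90)
  expect_equal(dim(r90$frames), c(6, 14, 10))
  for (t in c(1L, 4L)) {
    expect_equal(r90$frames[t, , ], rot90_oracle(stk$frames[t, , ]))
  }

  r180_once <- rotate_frames(stk, 180)
  r90_twice <- rotate_frames(r90, 90)
  expect_identical(r90_twice$frames, r180_once$frames)

  r360 <- rotate_frames(rotate_frames(r180_once, 90), 90)
  expect_identical(r360$frames, stk$frames)
})

test_that("arbitrary-angle rotation resamples bilinearly with zero fill", {
  arr <- array(7, dim = c(3, 21, 21))
  stk <- frame_stack(arr, fps = 100)
  rot <- rotate_frames(stk, 30)
  # constant image stays constant wherever the source frame covers
  # the target; corners fall outside and are zero-filled
  center_patch <- rot$frames[1, 9:13, 9:13]
  expect_true(all(abs(center_patch - 7) < 1e-9))
  expect_equal(rot$frames[1, 1, 1], 0)
  expect_equal(dim(rot$frames), dim(stk$frames))
})

test_that("crop_roi follows the half-open convention", {
  sim <- make_patch_stack(n = 6, h = 12, w = 10)
  stk <- sim$stack

  expect_identical(crop_roi(stk, full_roi(stk))$frames, stk$frames)

  one <- crop_roi(stk, rect_roi(3, 5, 1, 1))
  expect_equal(dim(one$frames), c(6, 1, 1))
  expect_equal(one$frames[, 1, 1], stk$frames[, 6, 4])

  expect_error(crop_roi(stk, rect_roi(8, 0, 3, 3)), "past")
  expect_error(crop_roi(stk, rect_roi(0, 10, 3, 3)), "past")
})

test_that("crops compose: cropping twice equals one offset crop", {
  sim <- make_patch_stack(n = 5, h = 20, w = 20)
  a <- rect_roi(2, 3, 14, 12)
  b <- rect_roi(4, 1, 6, 8)
  nested <- crop_roi(crop_roi(sim$stack, a), b)
  composed <- crop_roi(sim$stack, rect_roi(a$x0 + b$x0, a$y0 + b$y0,
                                           b$width, b$height))
  expect_identical(nested$frames, composed$frames)
})

test_that("stabilization is a no-op on drift-free stacks", {
  sim <- make_patch_stack(n = 24, noise_sigma = 0)
  st <- stabilize(sim$stack)
  expect_true(all(st$shifts$dx == 0L))
  expect_true(all(st$shifts$dy == 0L))
  expect_identical(st$stack$frames, sim$stack$frames)
})

test_that("known integer drift is estimated exactly and undone", {
  drift <- list(kind = "linear", dx_per_frame = 0.25,
                dy_per_frame = -0.125)
  drifted <- make_patch_stack(n = 48, drift = drift)
  clean <- make_patch_stack(n = 48, drift = NULL)
  st <- stabilize(drifted$stack)

  # estimated shifts are the negated true cumulative drift
  expect_identical(st$shifts$dx, -drifted$truth$shifts$dx)
  expect_identical(st$shifts$dy, -drifted$truth$shifts$dy)

  # registered frames equal the drift-free stack on the overlap
  dx <- drifted$truth$shifts$dx
  dy <- drifted$truth$shifts$dy
  h <- dim(clean$stack$frames)[2]
  w <- dim(clean$stack$frames)[3]
  ys <- (1 + max(0, -min(dy))):(h - max(0, max(dy)))
  xs <- (1 + max(0, -min(dx))):(w - max(0, max(dx)))
  expect_identical(st$stack$frames,
                   clean$stack$frames[, ys, xs, drop = FALSE])

  # motion extraction after stabilization matches the drift-free chain
  expect_equal(subtract_mean_image(st$stack)$frames,
               subtract_mean_image(
                 frame_stack(clean$stack$frames[, ys, xs, drop = FALSE],
                             fps = 500))$frames,
               tolerance = 1e-12)
})

test_that("stabilization restores the drifted spectrum", {
  drift <- list(kind = "linear", dx_per_frame = 0.3, dy_per_frame = 0.15)
  drifted <- make_patch_stack(f_hz = 10, n = 50, drift = drift)
  clean <- make_patch_stack(f_hz = 10, n = 50, drift = NULL)
  peak_of <- function(stk) {
    mean_psd_cbf(pixel_power_spectra(stk, band = c(1, 30)))$value_hz
  }
  expect_equal(peak_of(stabilize(drifted$stack)$stack),
               peak_of(clean$stack))
})

test_that("estimated shifts stay within the half-frame wrap range", {
  # phase correlation resolves translations modulo the frame size;
  # estimates therefore live in (-N/2, N/2] per axis
  drift <- list(kind = "linear", dx_per_frame = 0.4, dy_per_frame = 0.3)
  sim <- make_patch_stack(n = 20, h = 24, w = 24, drift = drift)
  st <- stabilize(sim$stack)
  expect_true(all(abs(st$shifts$dx) <= 12))
  expect_true(all(abs(st$shifts$dy) <= 12))
})

test_that("mean-image subtraction removes exactly the temporal mean", {
  # constant stacks map to zero
  const <- frame_stack(array(42, dim = c(8, 5, 5)), fps = 100)
  expect_true(all(subtract_mean_image(const)$frames == 0))

  # per-pixel temporal mean of the output is zero for arbitrary input
  set.seed(11)
  arr <- array(runif(20 * 6 * 6, 0, 255), dim = c(20, 6, 6))
  out <- subtract_mean_image(frame_stack(arr, fps = 100))
  expect_true(max(abs(colMeans(out$frames))) < 1e-12)

  # only the DC bin changes: PSD above DC is untouched
  sim <- make_sin_stack(10, n = 200, h = 4, w = 4, bit_depth = NULL)
  sp_raw <- pixel_power_spectra(sim$stack, band = c(1, 30))
  sp_ext <- pixel_power_spectra(subtract_mean_image(sim$stack),
                                band = c(1, 30))
  expect_equal(sp_ext$psd[-1, ], sp_raw$psd[-1, ], tolerance = 1e-9)
})
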