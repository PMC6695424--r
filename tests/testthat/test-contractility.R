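small_sim <- function(seed, amplitude_px, noise_sd = 0, duration_s = 3) {
  simulate_myotube_field(video_sim_config(
    width_px = 96, height_px = 96, duration_s = duration_s, n_myotubes = 3,
    amplitude_px = amplitude_px, noise_sd = noise_sd, seed = seed
  ))
}

test_that("motion trace is zero at the first frame and hand-computable", {
  f <- array(0, dim = c(1, 2, 2))
  f[1, , 2] <- c(0.2, 0.4)
  st <- frame_stack(f, fps = 10)
  expect_equal(motion_trace(st), c(0, 0.3)) # (0.2 + 0.4) / 2
  static <- frame_stack(array(0.4, c(4, 4, 10)), fps = 10)
  expect_identical(motion_trace(static), rep(0, 10))
})

test_that("first-maximum detection follows the earliest-tie rule", {
  # fps = 4, f = 1 gives smoothing width 1: the raw trace is scanned directly
  tr <- rep(0, 30)
  tr[c(10, 24)] <- 1
  expect_identical(find_first_max_contraction(tr, fps = 4, stim_freq_hz = 1), 10L)
  # plateau resolves to its first frame
  tr2 <- rep(0, 30); tr2[12:14] <- 1
  expect_identical(find_first_max_contraction(tr2, fps = 4, stim_freq_hz = 1), 12L)
})

test_that("a flat trace signals no contraction", {
  expect_error(find_first_max_contraction(rep(0, 40), 14.4, 1),
               class = "no_contraction_error")
})

test_that("detected anchor matches simulator ground truth within one frame", {
  sim <- small_sim(seed = 21, amplitude_px = 3, duration_s = 4)
  tr <- motion_trace(sim$stack)
  truth_first <- which.max(sim$truth$displacement_trace[1:14])
  det <- find_first_max_contraction(tr, 14.4, 1)
  expect_lte(abs(det - truth_first), 1)
})

test_that("frame pairing reproduces the arithmetic contract", {
  # 14.4 fps, 1 Hz, window 3 s: cycle starts at +0, +14, +29; relaxation +7
  p <- pair_frames(1, fps = 14.4, stim_freq_hz = 1, window_s = 3,
                   n_frames = 72)
  expect_identical(p$pairs$contraction, c(1L, 15L, 30L))
  expect_identical(p$pairs$relaxation - p$pairs$contraction, rep(7L, 3))
  # 10 fps, start 6 (1-based), 200 frames, window 5 s: 5 pairs, offset +5
  p2 <- pair_frames(6, fps = 10, stim_freq_hz = 1, window_s = 5,
                    n_frames = 200)
  expect_identical(nrow(p2$pairs), 5L)
  expect_identical(unique(p2$pairs$relaxation - p2$pairs$contraction), 5L)
  # pairs that overrun the stack are dropped
  p3 <- pair_frames(1, fps = 10, stim_freq_hz = 1, window_s = 3,
                    n_frames = 18)
  expect_identical(nrow(p3$pairs), 2L)
  expect_error(pair_frames(196, fps = 10, stim_freq_hz = 1, window_s = 3,
                           n_frames = 200),
               class = "insufficient_frames_error")
})

test_that("differential image is an absolute pixel subtraction", {
  f <- array(0, dim = c(2, 2, 2))
  f[, , 1] <- rbind(c(0.10, 0.20), c(0.30, 0.40))
  f[, , 2] <- rbind(c(0.10, 0.25), c(0.30, 0.40))
  st <- frame_stack(f, fps = 10)
  expect_equal(differential_image(st, 1, 2),
               rbind(c(0, 0.05), c(0, 0)))
  expect_equal(differential_image(st, 2, 1),
               rbind(c(0, 0.05), c(0, 0))) # magnitude is symmetric
  expect_equal(differential_image(st, 2, 1, signed = TRUE),
               rbind(c(0, 0.05), c(0, 0)))
  expect_equal(differential_image(st, 1, 2, signed = TRUE),
               rbind(c(0, -0.05), c(0, 0)))
  expect_error(differential_image(st, 1, 5), class = "parameter_error")
})

test_that("overlay combines per-pair images by mean or max", {
  d1 <- matrix(c(0, 0.2), 1)
  d2 <- matrix(c(0.4, 0), 1)
  expect_equal(overlay_diffs(list(d1, d2)), matrix(c(0.2, 0.1), 1))
  expect_equal(overlay_diffs(list(d1, d2), method = "max"),
               matrix(c(0.4, 0.2), 1))
  expect_identical(overlay_diffs(list(d1)), d1)
  expect_error(overlay_diffs(list()), class = "parameter_error")
})

test_that("static stacks report a zero, non-contractile movement index", {
  st <- frame_stack(array(0.5, c(16, 16, 40)), fps = 14.4)
  res <- movement_index(st)
  expect_identical(res$movement_index, 0)
  expect_true(res$non_contractile)
})

test_that("movement index equals the overlay mean and per-pair mean", {
  sim <- small_sim(seed = 13, amplitude_px = 3)
  res <- movement_index(sim$stack)
  expect_equal(res$movement_index, mean(res$overlay))
  expect_equal(res$movement_index, mean(res$per_pair_index))
})

test_that("field summaries report mean and standard error", {
  fs <- summarize_fields(c(0.1, 0.2, 0.3))
  expect_equal(fs$mean, 0.2)
  expect_equal(fs$se, stats::sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(fs$se, 0.1 / sqrt(3), tolerance = 1e-12)
  single <- summarize_fields(0.4)
  expect_equal(single$mean, 0.4)
  expect_true(is.na(single$se))
  expect_equal(summarize_fields(rep(0.2, 3))$se, 0)
  expect_error(summarize_fields(numeric(0)), class = "parameter_error")
})

test_that("stacks survive a TIFF round trip and normalize bit depth", {
  sim <- small_sim(seed = 31, amplitude_px = 2, noise_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path, fps = 14.4)
  expect_equal(back$frames, sim$stack$frames, tolerance = 1e-9)
  expect_identical(back$origin, "file")

  # 16-bit integer container: values come back normalized to [0, 1]
  path16 <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:3, function(t) sim$stack$frames[, , t])
  tiff::writeTIFF(pages, path16, bits.per.sample = 16L)
  b16 <- read_stack(path16, fps = 14.4)
  expect_true(max(b16$frames) <= 1)
  expect_equal(b16$frames, sim$stack$frames[, , 1:3], tolerance = 1e-4)

  single <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages[1], single, bits.per.sample = 32L)
  expect_error(read_stack(single, fps = 14.4), class = "format_error")
  expect_error(read_stack(path), class = "configuration_error")
})

test_that("pseudo-color rendering writes a deterministic full-size PNG", {
  ov <- matrix(runif(32 * 24), 32, 24)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_pseudocolor(ov, p1)
  render_pseudocolor(ov, p2)
  img <- png::readPNG(p1)
  expect_identical(dim(img)[1:2], dim(ov))
  expect_identical(png::readPNG(p1), png::readPNG(p2))
  # constant overlay maps to the colormap floor everywhere
  pz <- withr::local_tempfile(fileext = ".png")
  render_pseudocolor(matrix(0, 8, 8), pz)
  flat <- png::readPNG(pz)
  expect_identical(length(unique(as.vector(flat[, , 1]))), 1L)
})
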