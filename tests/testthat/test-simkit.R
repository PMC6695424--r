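test_that("twitch trace has the specified length, zeros, and sampled peak", {
  s <- simulate_twitch_trace(fps = 14.4, stim_freq_hz = 1, duration_s = 5)
  expect_length(s, 72) # round(14.4 * 5)
  expect_identical(s[1], 0)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1)
  # rise = 0.1 s, decay = 0.3 s at 14.4 fps: the two samples bracketing the
  # continuous peak are s(1/14.4) = 0.0694/0.1 and s(2/14.4) =
  # exp(-(0.1389 - 0.1)/0.3); the latter is larger, so the sampled argmax of
  # the first cycle sits at frame 3 (1-based)
  rise_val <- (1 / 14.4) / 0.1
  decay_val <- exp(-((2 / 14.4) - 0.1) / 0.3)
  expect_gt(decay_val, rise_val)
  expect_identical(which.max(s[1:14]), 3L)
})

test_that("twitch trace is periodic at the stimulation period", {
  s <- simulate_twitch_trace(fps = 14.4, stim_freq_hz = 1, duration_s = 10)
  ac <- stats::acf(s, lag.max = 20, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 14) # round(14.4) within rounding
})

test_that("twitch trace rejects impossible kinetics", {
  expect_error(simulate_twitch_trace(14.4, 1, -1), class = "parameter_error")
  expect_error(simulate_twitch_trace(14.4, 1, 5, twitch_rise_s = 0.6,
                                     twitch_decay_s = 0.6),
               class = "parameter_error")
  expect_error(simulate_twitch_trace(fps = 1.5, stim_freq_hz = 1,
                                     duration_s = 5),
               class = "parameter_error")
})

test_that("myotube field simulation is deterministic and clipped", {
  cfg <- video_sim_config(width_px = 96, height_px = 96, duration_s = 3,
                          n_myotubes = 3, amplitude_px = 2, noise_sd = 0.02,
                          seed = 42)
  a <- simulate_myotube_field(cfg)
  b <- simulate_myotube_field(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_true(all(a$stack$frames >= 0 & a$stack$frames <= 1))
  expect_length(a$truth$displacement_trace, dim(a$stack$frames)[3])
})

test_that("zero amplitude and zero noise give a static stack", {
  cfg <- video_sim_config(width_px = 96, height_px = 96, duration_s = 3,
                          n_myotubes = 3, amplitude_px = 0, noise_sd = 0,
                          seed = 1)
  sim <- simulate_myotube_field(cfg)
  f <- sim$stack$frames
  for (t in 2:dim(f)[3]) expect_identical(f[, , t], f[, , 1])
})

test_that("larger amplitude produces larger frame differences", {
  stacks <- lapply(c(1, 4), function(a) {
    simulate_myotube_field(video_sim_config(
      width_px = 96, height_px = 96, duration_s = 3, n_myotubes = 3,
      amplitude_px = a, noise_sd = 0, seed = 5
    ))
  })
  peak <- which.max(stacks[[1]]$truth$displacement_trace[1:14])
  d <- vapply(stacks, function(s) {
    mean(abs(s$stack$frames[, , peak] - s$stack$frames[, , 1]))
  }, numeric(1))
  expect_gt(d[2], d[1])
})

test_that("excessive amplitude is rejected", {
  expect_error(
    simulate_myotube_field(video_sim_config(
      width_px = 96, height_px = 96, duration_s = 3, n_myotubes = 3,
      amplitude_px = 60, noise_sd = 0, seed = 1
    )),
    class = "parameter_error"
  )
})

test_that("nuclei field honors the planted fraction edge cases", {
  none <- simulate_nuclei_field(60, 0, width_px = 220, height_px = 220,
                                seed = 2)
  expect_false(any(none$field$hna_mask))
  all_h <- simulate_nuclei_field(60, 1, width_px = 220, height_px = 220,
                                 seed = 2)
  expect_identical(all_h$truth$n_human, 60L)
  expect_identical(max(label_components(all_h$field$hna_mask)), 60L)
})

test_that("nuclei truth subset matches the seeded binomial draw", {
  sim <- simulate_nuclei_field(100, 0.15, seed = 77)
  expect_identical(length(sim$truth$human_indices),
                   as.integer(sim$truth$n_human))
  expect_identical(max(label_components(sim$field$hna_mask)),
                   as.integer(sim$truth$n_human))
  expect_identical(max(label_components(sim$field$dapi_mask)), 100L)
})

test_that("every human nucleus lies on a total-nuclei component", {
  sim <- simulate_nuclei_field(80, 0.3, seed = 9)
  expect_true(all(sim$field$dapi_mask[sim$field$hna_mask]))
})

test_that("nuclei placement failure raises a geometry error", {
  expect_error(simulate_nuclei_field(500, 0.1, width_px = 60, height_px = 60,
                                     seed = 1, max_tries = 20),
               class = "geometry_error")
})

test_that("marker table is deterministic with labeled populations", {
  a <- simulate_marker_table(seed = 4)
  b <- simulate_marker_table(seed = 4)
  expect_identical(a, b)
  expect_identical(nrow(a), 200L)
  expect_true(all(satellite_panel_markers() %in% names(a)))
  expect_true(all(a[satellite_panel_markers()] >= 0))
  empty <- simulate_marker_table(n_cells = c(satellite = 0, blood = 10),
                                 seed = 4)
  expect_false(any(empty$population == "satellite"))
})

test_that("ct table plants exact fold changes at zero noise", {
  sim <- simulate_ct_table(c(GOI = 4), c(GOI = "human"), noise_sd_ct = 0,
                           n_reps = 3, seed = 1)
  ct <- sim$ct
  goi <- ct[ct$gene == "GOI", ]
  expect_identical(nrow(goi), 6L) # 3 reps x 2 conditions
  expect_equal(mean(goi$ct_value[goi$condition == "control"]) -
                 mean(goi$ct_value[goi$condition == "EPS"]), 2) # log2(4)
  ref <- ct[ct$gene == "RPLP0", ]
  expect_equal(unique(ref$ct_value), 18)
  expect_error(simulate_ct_table(c(GOI = -1), c(GOI = "human"), seed = 1),
               class = "parameter_error")
})

test_that("secretion panel plants the default 40-analyte class structure", {
  classes <- default_analyte_classes()
  expect_length(classes, 40)
  expect_identical(unname(table(classes)["upregulated"]), 24L)
  expect_identical(unname(classes[["MIF"]]), "detected_not_upregulated")
  expect_setequal(names(classes)[classes == "cross_reactive"],
                  c("CX3CL1", "CCL3", "CCL12"))

  sim <- simulate_secretion_panel(seed = 3)
  expect_identical(sim$panel, simulate_secretion_panel(seed = 3)$panel)
  lod <- attr(sim$panel, "lod")
  nd <- names(classes)[classes == "not_detected"]
  for (an in nd) {
    expect_true(all(sim$panel$concentration[sim$panel$analyte == an] <
                      lod[[an]]))
  }
  expect_true(all(sim$panel$concentration >= 0))
})

test_that("an all-below-LOD panel stays below LOD everywhere", {
  classes <- stats::setNames(rep("not_detected", 6),
                             c("A1", "A2", "A3", "A4", "A5", "A6"))
  sim <- simulate_secretion_panel(classes, lod_pg_ml = 2, seed = 8)
  expect_true(all(sim$panel$concentration < 2))
})
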