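# Digital breathing phantom and dynamic-acquisition simulator.

test_that("zero amplitude gives identical masks and zero truth displacement", {
  cfg <- small_phantom_config(amplitude_mm = matrix(0, 3, 3), seed = 1)
  ph <- generate_phantom(cfg, render_intensity = FALSE)
  for (p in 2:6) expect_identical(ph$masks[[p]], ph$masks[[1]])
  for (st in c("pancreas", "head", "body", "tail"))
    expect_equal(max(abs(ph$truth_displacement_mm[[st]])), 0)
})

test_that("truth COM trace equals amplitude x waveform by construction", {
  w <- c(1, .6, 0, .1, .5, .9)
  cfg <- small_phantom_config(amplitude_mm = matrix(2.5, 3, 3, byrow = TRUE),
                              phase_waveform = w, seed = 1)
  ph <- generate_phantom(cfg, render_intensity = FALSE)
  for (st in c("pancreas", "head", "body", "tail")) {
    tr <- ph$truth_com_mm[[st]][, "SI"]
    expect_equal(tr - tr[3], 2.5 * w, tolerance = 1e-12)  # w[3] = 0
  }
})

test_that("mask-recomputed COM matches analytic truth within half a voxel", {
  ph <- generate_phantom(phantom_config(seed = 3), render_intensity = FALSE)
  half_vox <- ph$spacing_mm / 2
  for (p in seq_len(ph$n_phases)) {
    err <- abs(com(ph$masks[[p]], ph$spacing_mm) - ph$truth_com_mm$pancreas[p, ])
    expect_true(all(err <= half_vox))
    for (s in 1:3) {
      st <- c("head", "body", "tail")[s]
      err_s <- abs(com(ph$seg_labels[[p]] == s, ph$spacing_mm) -
                     ph$truth_com_mm[[st]][p, ])
      expect_true(all(err_s <= half_vox))
    }
  }
})

test_that("whole-voxel rigid shifts conserve the mask voxel count exactly", {
  sp <- c(1.17, 1.17, 4.0)
  amp <- matrix(rep(c(1.17, 2.34, 4.0), each = 3), 3, 3)
  cfg <- small_phantom_config(amplitude_mm = amp,
                              phase_waveform = c(0, 1, 0, 1, 0, 1),
                              spacing_mm = sp, seed = 1)
  ph <- generate_phantom(cfg, render_intensity = FALSE)
  counts <- vapply(ph$masks, sum, numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("truth displacement is odd under amplitude sign flip", {
  base <- small_phantom_config(seed = 1)
  flip <- small_phantom_config(amplitude_mm = -default_amplitudes(), seed = 1)
  ph1 <- generate_phantom(base, render_intensity = FALSE)
  ph2 <- generate_phantom(flip, render_intensity = FALSE)
  for (st in c("pancreas", "head", "body", "tail"))
    expect_equal(ph2$truth_displacement_mm[[st]],
                 -ph1$truth_displacement_mm[[st]], tolerance = 1e-12)
})

test_that("same seed reproduces bit-identical phantoms; seeds differ in noise only", {
  a <- generate_phantom(small_phantom_config(seed = 11))
  b <- generate_phantom(small_phantom_config(seed = 11))
  expect_identical(a$intensity, b$intensity)
  c <- generate_phantom(small_phantom_config(seed = 12))
  expect_identical(a$masks, c$masks)
  expect_identical(a$intensity_clean, c$intensity_clean)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("a segment pushed off the grid raises an error naming phase and axis", {
  amp <- default_amplitudes()
  amp["tail", "SI"] <- 500
  cfg <- small_phantom_config(amplitude_mm = amp, seed = 1)
  expect_error(generate_phantom(cfg, render_intensity = FALSE),
               "tail.*phase 1.*SI")
})

test_that("acquisition emits n_slices x n_measurements slices with analytic truth", {
  ph <- generate_phantom(small_phantom_config(seed = 2))
  acq <- acq_config(n_slices = 10, n_measurements = 6, breathing_period_s = 3.7,
                    seed = 4)
  ser <- simulate_dynamic_acquisition(ph, acq)
  expect_length(ser$images, 60)
  # closed-form phase of each acquisition time
  f <- (ser$meta$time_ms / 1000 / 3.7) %% 1
  expected <- (floor(f * 6 + 0.5) %% 6) + 1
  expect_equal(ser$meta$true_phase, as.integer(expected))
  # interleaved ordering: odd slice positions first within a measurement
  first_sweep <- ser$meta$slice_index[ser$meta$measurement == 1]
  expect_equal(first_sweep, c(seq(1, 10, 2), seq(2, 10, 2)))
})

test_that("zero-motion phantom yields identical repeated slices up to noise", {
  cfg <- small_phantom_config(amplitude_mm = matrix(0, 3, 3), torso_breath_mm = 0, noise_sd = 0,
                              seed = 1)
  ph <- generate_phantom(cfg)
  ser <- simulate_dynamic_acquisition(ph, acq_config(n_slices = 6,
                                                     n_measurements = 4, seed = 2))
  for (si in unique(ser$meta$slice_index)) {
    ids <- which(ser$meta$slice_index == si)
    for (i in ids[-1]) expect_identical(ser$images[[i]], ser$images[[ids[1]]])
  }
})
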