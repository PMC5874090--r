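# Segmentation-reliability indexes: integral profiles, profile registration,
# Pearson index and volume consistency.

test_that("integral profiles count voxels along each axis", {
  cube <- array(FALSE, c(4, 4, 4))
  cube[2:3, 2:3, 2:3] <- TRUE
  for (ax in c("LL", "AP", "SI")) {
    pr <- integral_profile(cube, ax)
    expect_equal(pr$values, c(0, 4, 4, 0))
    expect_equal(sum(pr$values), sum(cube))
  }
  single <- array(FALSE, c(5, 5, 5)); single[2, 3, 4] <- TRUE
  expect_equal(integral_profile(single, "LL")$values, c(0, 1, 0, 0, 0))
  expect_equal(integral_profile(single, "SI")$values, c(0, 0, 0, 1, 0))
})

test_that("profiles of an LL-mirrored mask are reverses of each other", {
  set.seed(51)
  m <- array(runif(14 * 6 * 6) < 0.4, c(14, 6, 6))
  mm <- m[14:1, , ]
  expect_equal(integral_profile(mm, "LL")$values,
               rev(integral_profile(m, "LL")$values))
})

test_that("profile registration recovers integer shifts and applies the rounding rule", {
  ref <- list(axis = "LL", values = c(0, 0, 2, 5, 2, 0, 0, 0, 0, 0),
              origin_voxel = 1L)
  shifted <- list(axis = "LL", values = c(0, 0, 0, 0, 0, 2, 5, 2, 0, 0),
                  origin_voxel = 1L)
  reg <- register_profile(shifted, ref)
  expect_equal(reg$shift, -3)
  expect_equal(reg$values[reg$support], ref$values[reg$support])
  same <- register_profile(ref, ref)
  expect_equal(same$shift, 0)
  expect_equal(same$values, ref$values)
  # rounding is half away from zero
  expect_equal(pancmotion:::round_half_away(c(2.4, 2.5, -2.4, -2.5, 0.5)),
               c(2, 3, -2, -3, 1))
  empty <- list(axis = "LL", values = rep(0, 5), origin_voxel = 1L)
  expect_error(register_profile(empty, ref), "empty")
})

test_that("identical masks give Pearson 1 with zero IQR", {
  set.seed(52)
  m <- array(runif(10 * 8 * 6) < 0.4, c(10, 8, 6))
  maps <- rep(list(m), 5)
  for (ax in c("LL", "AP", "SI")) {
    pe <- pearson_profile_index(maps, ax)
    expect_equal(pe$median, 1)
    expect_equal(pe$iqr, 0)
  }
})

test_that("whole-voxel rigid translations leave the Pearson index at exactly 1", {
  set.seed(53)
  base <- array(FALSE, c(16, 12, 8))
  base[4:9, 3:8, 2:5] <- array(runif(6 * 6 * 4) < 0.7, c(6, 6, 4))
  shifts <- list(c(0, 0, 0), c(3, 0, 0), c(-2, 1, 0), c(1, -1, 2), c(2, 2, 1))
  maps <- lapply(shifts, function(s)
    pancmotion:::shift_array(base, s[1], 1) |>
      pancmotion:::shift_array(s[2], 2) |>
      pancmotion:::shift_array(s[3], 3) > 0)
  for (ax in c("LL", "AP", "SI")) {
    pe <- pearson_profile_index(maps, ax)
    expect_equal(pe$per_phase, rep(1, 5), tolerance = 1e-12)
  }
  vc <- volume_consistency(maps, c(1.17, 1.17, 4))
  expect_equal(vc$per_phase, rep(0, 5))
})

test_that("voxel dropout degrades the Pearson index and volume consistency monotonically", {
  # contour jitter model: independent voxel dropout on otherwise identical
  # per-phase masks, so dropout is the only source of inter-phase variation
  ph <- generate_phantom(phantom_config(seed = 6), render_intensity = FALSE)
  base <- ph$masks[[1]]
  idx <- which(base)
  rates <- c(0.05, 0.10, 0.20)
  dropout_maps <- function(rate, n_phases = 8) {
    lapply(seq_len(n_phases), function(i) {
      m <- base
      m[idx[stats::runif(length(idx)) < rate]] <- FALSE
      m
    })
  }
  set.seed(60)
  med_pearson <- vapply(rates, function(r)
    pearson_profile_index(dropout_maps(r), "LL")$median, numeric(1))
  # volume consistency has higher sampling noise: average the index over
  # replicate dropout draws
  mean_vc <- vapply(rates, function(r)
    mean(replicate(40, volume_consistency(dropout_maps(r), ph$spacing_mm)$median)),
    numeric(1))
  expect_true(all(med_pearson < 1))
  expect_true(all(diff(med_pearson) < 0))
  expect_true(all(diff(mean_vc) > 0))
})

test_that("volume consistency implements the percent-of-maximum formula", {
  m100 <- array(FALSE, c(30, 20, 10)); m100[1:10, 1:10, 1:10] <- TRUE
  m90 <- array(FALSE, c(30, 20, 10)); m90[1:10, 1:9, 1:10] <- TRUE
  vc <- volume_consistency(list(m100, m90), c(10, 10, 10))
  expect_equal(vc$volume_cc, c(1000, 900))
  expect_equal(vc$per_phase, c(0, 10))
  # invariant under voxel-volume rescaling
  vc2 <- volume_consistency(list(m100, m90), c(1, 2, 3))
  expect_equal(vc2$per_phase, vc$per_phase)
  # equal volumes give all zeros
  vc3 <- volume_consistency(list(m100, m100, m100), c(1, 1, 1))
  expect_equal(vc3$per_phase, c(0, 0, 0))
  empty <- array(FALSE, c(30, 20, 10))
  expect_error(volume_consistency(list(m100, empty), c(1, 1, 1)), "empty")
})

test_that("zero-variance profiles are reported as missing with a warning", {
  m <- array(FALSE, c(4, 4, 4)); m[, 2, 2] <- TRUE   # flat LL profile
  maps <- list(m, m, m)
  expect_warning(pe <- pearson_profile_index(maps, "LL"), "zero-variance")
  expect_true(all(is.na(pe$per_phase)))
})

test_that("reliability report covers all structures with a Table-1 layout", {
  ph <- generate_phantom(small_phantom_config(seed = 8), render_intensity = FALSE)
  part <- partition_4d(ph$masks, ph$spacing_mm, seed = 2)
  rr <- reliability_report(part)
  expect_equal(rr$structure, c("pancreas", "head", "body", "tail"))
  expect_true(all(rr$pearson_LL_median >= -1 & rr$pearson_LL_median <= 1))
  expect_true(all(rr$volume_consistency_median >= 0))
  # clusters on the coarse test grid may vary a few percent more than the
  # whole gland, but stay in the same range
  expect_true(all(rr$volume_consistency_median <=
                    rr$volume_consistency_median[1] + 10))
})
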