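# Mutual information, reference volume, surrogate and phase sorting.

test_that("MI matches the brute-force joint-histogram oracle", {
  set.seed(21)
  for (rep in 1:20) {
    a <- matrix(runif(256), 16, 16)
    b <- matrix(runif(256), 16, 16)
    expect_equal(mutual_information(a, b, 8), brute_force_mi(a, b, 8),
                 tolerance = 1e-12)
    expect_equal(mutual_information(a, b, 8), mutual_information(b, a, 8),
                 tolerance = 1e-12)
    expect_gte(mutual_information(a, b, 8), 0)
  }
})

test_that("MI degenerate and self-similarity cases", {
  const <- matrix(1, 8, 8)
  expect_equal(mutual_information(const, const, 16), 0)
  # two equally frequent intensity levels: MI(X, X) = H(X) = 1 bit
  two <- matrix(rep(c(0, 5), each = 32), 8, 8)
  expect_equal(mutual_information(two, two, 16), 1.0)
  # independent uniform noise: MI below a small histogram-bias bound
  set.seed(5)
  a <- matrix(runif(4096), 64, 64)
  b <- matrix(runif(4096), 64, 64)
  expect_lt(mutual_information(a, b, 8), 0.05)
})

make_toy_series <- function(images, slice_index, spacing = c(1, 1, 1),
                            dt = 100) {
  n <- length(images)
  structure(list(images = images,
                 meta = data.frame(seq = seq_len(n), slice_index = slice_index,
                                   volume_slice = slice_index,
                                   measurement = stats::ave(slice_index,
                                     slice_index, FUN = seq_along),
                                   time_ms = (seq_len(n) - 1) * dt),
                 spacing_mm = spacing,
                 n_slices = length(unique(slice_index)),
                 n_measurements = max(table(slice_index)),
                 slice_time_ms = dt),
            class = "dyn_series")
}

test_that("chain reference on 2 positions x 3 measurements equals exhaustive argmax", {
  set.seed(31)
  base1 <- matrix(runif(64), 8, 8)
  base2 <- matrix(runif(64), 8, 8)
  imgs <- list()
  for (j in 1:3) imgs[[j]] <- base1 + matrix(rnorm(64, sd = 0.1 * j), 8, 8)
  for (j in 1:3) imgs[[3 + j]] <- base2 + matrix(rnorm(64, sd = 0.1 * j), 8, 8)
  ser <- make_toy_series(imgs, rep(1:2, each = 3))
  ref <- build_reference_volume(ser, 16, method = "chain")
  mi <- matrix(NA, 3, 3)
  for (i in 1:3) for (j in 1:3)
    mi[i, j] <- mutual_information(imgs[[i]], imgs[[3 + j]], 16)
  best <- arrayInd(which.max(mi), dim(mi))
  expect_equal(ref$chosen$measurement, as.integer(best))
})

test_that("chain reference prefers the clean measurement per position", {
  set.seed(32)
  base <- lapply(1:4, function(k) {
    m <- matrix(0, 12, 12)
    m[4:9, (2 + k):(7 + k)] <- 1
    m
  })
  imgs <- list(); idx <- integer(0)
  for (k in 1:4) for (j in 1:3) {
    noise_sd <- if (j == 2) 0.01 else 3   # measurement 2 is the clean one
    imgs[[length(imgs) + 1]] <- base[[k]] + matrix(rnorm(144, sd = noise_sd), 12, 12)
    idx <- c(idx, k)
  }
  ser <- make_toy_series(imgs, idx)
  ref <- build_reference_volume(ser, 8, method = "chain")
  expect_true(all(ref$chosen$measurement == 2))
})

test_that("extreme reference picks the rare (transient) state per position", {
  set.seed(33)
  common <- matrix(runif(144), 12, 12)
  rare <- matrix(runif(144), 12, 12)
  imgs <- list(); idx <- integer(0)
  for (k in 1:3) for (j in 1:5) {
    state <- if (j == 4) rare else common
    imgs[[length(imgs) + 1]] <- state + matrix(rnorm(144, sd = 0.05), 12, 12)
    idx <- c(idx, k)
  }
  ser <- make_toy_series(imgs, idx)
  ref <- build_reference_volume(ser, 16, method = "extreme")
  expect_true(all(ref$chosen$measurement == 4))
})

test_that("surrogate attains its group maximum at the reference slice itself", {
  set.seed(34)
  imgs <- lapply(1:9, function(i) matrix(runif(64), 8, 8))
  ser <- make_toy_series(imgs, rep(1:3, each = 3))
  ref <- build_reference_volume(ser, 16)
  sur <- extract_surrogate(ser, ref, 16)
  for (k in 1:3) {
    chosen_seq <- which(ser$meta$slice_index == k)[ref$chosen$measurement[k]]
    grp <- sur[sur$slice_index == k, ]
    expect_equal(grp$seq[which.max(grp$mi)], chosen_seq)
  }
})

test_that("zero-motion zero-noise series yields a constant surrogate", {
  cfg <- small_phantom_config(amplitude_mm = matrix(0, 3, 3), torso_breath_mm = 0, noise_sd = 0,
                              seed = 1)
  ph <- generate_phantom(cfg)
  ser <- simulate_dynamic_acquisition(ph, acq_config(n_slices = 5,
                                                     n_measurements = 4, seed = 2))
  ref <- build_reference_volume(ser, 16)
  sur <- extract_surrogate(ser, ref, 16)
  for (k in unique(sur$slice_index))
    expect_equal(stats::sd(sur$mi[sur$slice_index == k]), 0)
})

synthetic_surrogate <- function(period_ms = 4000, n = 240, dt = 200,
                                noise = 0, f0 = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  f <- ((t / period_ms) - f0) %% 1
  # asymmetric periodic response peaking at cycle fraction 0
  mi <- cos(2 * pi * f) + 0.3 * cos(4 * pi * f) + rnorm(n, sd = noise)
  data.frame(seq = seq_len(n), slice_index = 1L, time_ms = t, mi = mi)
}

test_that("phase assignment recovers period and origin of a periodic surrogate", {
  sig <- synthetic_surrogate(period_ms = 4000, noise = 0.05)
  lab <- assign_phases(sig, 6)
  expect_lt(abs(attr(lab, "period_ms") - 4000), 40)
  f0 <- attr(lab, "anchor_fraction")
  expect_lt(min(f0, 1 - f0), 0.03)
  truth <- (floor(((sig$time_ms / 4000) %% 1) * 6 + 0.5) %% 6) + 1
  expect_gt(mean(lab$phase == truth), 0.9)
})

test_that("sampling exactly 6 per cycle fills every bin equally", {
  n_cycles <- 8
  sig <- synthetic_surrogate(period_ms = 4200, n = 6 * n_cycles, dt = 700)
  lab <- assign_phases(sig, 6)
  expect_true(all(table(lab$phase) == n_cycles))
})

test_that("phase assignment is equivariant to a whole-period time shift", {
  sig <- synthetic_surrogate(period_ms = 4000, noise = 0.05, seed = 7)
  lab1 <- assign_phases(sig, 6)
  sig2 <- sig
  sig2$time_ms <- sig2$time_ms + 4000
  lab2 <- assign_phases(sig2, 6)
  expect_equal(lab2$phase, lab1$phase)
})

test_that("too-short or flat surrogates are rejected", {
  flat <- data.frame(seq = 1:10, slice_index = 1L,
                     time_ms = (0:9) * 300, mi = rep(1, 10))
  expect_error(assign_phases(flat, 6), "modulation|short")
  short <- synthetic_surrogate(n = 10, dt = 200)
  expect_error(assign_phases(short, 6), "short")
})

test_that("reconstruction averages cells, fills gaps cyclically and logs them", {
  set.seed(36)
  imgs <- list(); idx <- integer(0); ph <- integer(0)
  for (k in 1:2) for (p in 1:4) for (r in 1:2) {
    imgs[[length(imgs) + 1]] <- matrix(p * 10 + k + rnorm(16, sd = 0.01), 4, 4)
    idx <- c(idx, k); ph <- c(ph, p)
  }
  ser <- make_toy_series(imgs, idx)
  labels <- data.frame(seq = ser$meta$seq, phase = ph,
                       fraction = (ph - 1) / 4)
  vol <- reconstruct_4d(ser, labels, 4, select = "all")
  expect_equal(nrow(vol$fill_log), 0)
  members <- which(idx == 1 & ph == 2)
  expect_equal(vol$phases[[2]][, , 1],
               (imgs[[members[1]]] + imgs[[members[2]]]) / 2)

  # empty one (phase, position) cell: filled from the cyclically nearest
  # phase, ties toward the earlier phase
  keep <- !(idx == 1 & ph == 3)
  ser2 <- make_toy_series(imgs[keep], idx[keep])
  labels2 <- data.frame(seq = ser2$meta$seq, phase = ph[keep],
                        fraction = (ph[keep] - 1) / 4)
  vol2 <- reconstruct_4d(ser2, labels2, 4, select = "all")
  expect_equal(vol2$fill_log,
               data.frame(slice_index = 1L, phase = 3L, donor_phase = 2L))
  expect_equal(vol2$phases[[3]][, , 1], vol2$phases[[2]][, , 1])

  # a slice position absent from the whole series is an error
  ser3 <- make_toy_series(imgs, ifelse(idx == 2, 3L, 1L))
  ser3$n_slices <- 3L
  expect_error(build_reference_volume(ser3, 8), "missing slice indices: 2")
})
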