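# Digital 4D breathing phantom: a three-lobed, pancreas-like binary mask that
# moves quasi-rigidly (per-segment rigid shifts) over a discrete breathing
# cycle, plus a simulator of the dynamic interleaved multi-slice acquisition.
#
# Sub-voxel motion is realized by shifting the continuous ellipsoid centers
# before voxelization, so masks stay binary and the analytic (truth) COM is
# exact by construction.

#' Default per-segment motion amplitudes (mm)
#'
#' Peak-to-trough displacement per segment (rows: head, body, tail) and
#' direction (columns: LL, AP, SI). LL and SI amplitudes exceed AP, and the
#' tail moves 1.5 times as much as the head, reflecting the typical pattern
#' of respiratory pancreas motion under immobilization (median SI and LL
#' excursions of a few mm, AP below 1 mm, head slightly less mobile than
#' tail).
#'
#' @return 3x3 numeric matrix with dimnames (segment, axis)
#' @export
default_amplitudes <- function() {
  m <- rbind(head = c(2.4, 0.8, 3.0),
             body = c(3.0, 1.0, 3.75),
             tail = c(3.6, 1.2, 4.5))
  colnames(m) <- AXES
  m
}

#' Default 6-phase breathing waveform
#'
#' Fractional displacement per phase in `[0, 1]`, with phase 1 = end
#' inhalation (peak) and an exhalation plateau around phases 3-4, so that
#' early exhalation (phase 3) is the most position-stable phase of the
#' cycle. Exhalation occupies more of the cycle than inhalation, as in free
#' breathing.
#'
#' @param n_phases number of phases (only 6 has a built-in default)
#' @return numeric vector of length `n_phases`
#' @export
default_waveform <- function(n_phases = 6L) {
  if (n_phases != 6L)
    stop("a built-in waveform is only defined for 6 phases; supply `phase_waveform`")
  c(1.00, 0.20, 0.06, 0.10, 0.55, 0.85)
}

#' Configuration of the digital pancreas phantom
#'
#' @param grid_shape voxels per axis (LL, AP, SI)
#' @param spacing_mm voxel size per axis in mm
#' @param n_phases number of breathing phases
#' @param amplitude_mm 3x3 matrix of peak-to-trough motion (mm); rows head,
#'   body, tail; columns LL, AP, SI. Sign encodes direction along the axis
#'   (positive LL = patient-left, positive SI = superior)
#' @param phase_waveform per-phase fractional displacement in `[0, 1]`,
#'   length `n_phases`; phase 1 = end inhalation
#' @param segment_fractions fraction of gland length per segment
#'   (head, body, tail); must sum to 1
#' @param gland_length_mm total LL extent allotted to the gland (mm)
#' @param cross_section_mm 3x2 matrix of AP and SI lobe semi-axes (mm)
#' @param torso_breath_mm anterior rise of the background torso wall at end
#'   inhalation (mm); gives every axial slice respiratory image content
#' @param noise_sd additive Gaussian intensity noise (image intensities are
#'   on a 0-1 scale); masks are always noise-free
#' @param position_label,device_label categorical setup metadata
#' @param seed random-state integer (noise only)
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 25L),
                           spacing_mm = c(1.17, 1.17, 4.0),
                           n_phases = 6L,
                           amplitude_mm = default_amplitudes(),
                           phase_waveform = default_waveform(n_phases),
                           segment_fractions = c(0.40, 0.28, 0.32),
                           gland_length_mm = 80,
                           cross_section_mm = rbind(head = c(14, 12),
                                                    body = c(11, 10),
                                                    tail = c(11, 11)),
                           torso_breath_mm = 2.5,
                           noise_sd = 0.02,
                           position_label = "prone",
                           device_label = "vacuum",
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            n_phases >= 2,
            is.matrix(amplitude_mm), all(dim(amplitude_mm) == c(3, 3)),
            all(is.finite(amplitude_mm)),
            length(phase_waveform) == n_phases,
            all(phase_waveform >= 0), all(phase_waveform <= 1),
            length(segment_fractions) == 3, all(segment_fractions > 0),
            abs(sum(segment_fractions) - 1) < 1e-8,
            gland_length_mm > 0, noise_sd >= 0, torso_breath_mm >= 0)
  dimnames(amplitude_mm) <- list(c("head", "body", "tail"), AXES)
  stopifnot(is.matrix(cross_section_mm), all(dim(cross_section_mm) == c(3, 2)),
            all(cross_section_mm > 0))
  dimnames(cross_section_mm) <- list(c("head", "body", "tail"), c("AP", "SI"))
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 n_phases = as.integer(n_phases), amplitude_mm = amplitude_mm,
                 phase_waveform = phase_waveform,
                 segment_fractions = segment_fractions,
                 gland_length_mm = gland_length_mm,
                 cross_section_mm = cross_section_mm,
                 torso_breath_mm = torso_breath_mm,
                 noise_sd = noise_sd, position_label = position_label,
                 device_label = device_label, seed = as.integer(seed)),
            class = "phantom_config")
}

# ellipsoid membership on the voxel-center grid
ellipsoid_mask <- function(coords, center, semi) {
  dx2 <- ((coords[[1]] - center[1]) / semi[1])^2
  dy2 <- ((coords[[2]] - center[2]) / semi[2])^2
  dz2 <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# lobe geometry (base centers and semi-axes) derived from the config
phantom_geometry <- function(config) {
  extent <- config$grid_shape * config$spacing_mm
  mid <- extent / 2
  seg_len <- config$segment_fractions * config$gland_length_mm
  centers_ll <- mid[1] - config$gland_length_mm / 2 + cumsum(seg_len) - seg_len / 2
  semis <- cbind(LL = 0.45 * seg_len, config$cross_section_mm)
  colnames(semis) <- AXES
  rownames(semis) <- c("head", "body", "tail")
  # gland sits slightly posterior-of-center so a moving liver-like structure
  # fits anteriorly for background contrast
  centers <- cbind(LL = centers_ll, AP = rep(mid[2] + 0.125 * extent[2], 3),
                   SI = rep(mid[3], 3))
  rownames(centers) <- c("head", "body", "tail")
  list(centers = centers, semis = semis, extent = extent, mid = mid)
}

#' Generate a 4D breathing phantom
#'
#' Builds per-phase binary masks of a three-lobed ellipsoidal gland in which
#' each segment (head, body, tail) is rigidly displaced by
#' `amplitude * waveform[phase]`, records the analytic ground-truth COM
#' trajectory per structure, and renders per-phase intensity volumes
#' (gland + moving liver-like structure + static torso background, lightly
#' smoothed; Gaussian noise added on intensities only).
#'
#' @param config a [phantom_config()]
#' @param render_intensity if `FALSE`, skip rendering intensity volumes
#'   (masks and ground truth only; faster when only mask-level analyses are
#'   needed)
#' @return object of class `phantom4d` with elements `masks` (list of
#'   logical arrays per phase), `seg_labels` (integer arrays, 0 background /
#'   1 head / 2 body / 3 tail), `intensity` and `intensity_clean` (numeric
#'   arrays per phase), `truth_com_mm` (list per structure of phase x 3
#'   matrices), `truth_displacement_mm` (same shape, relative to the
#'   designated reference phase), `truth_reference_phase`, `spacing_mm`,
#'   and setup labels.
#' @export
generate_phantom <- function(config = phantom_config(), render_intensity = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  geo <- phantom_geometry(config)
  coords <- lapply(1:3, function(a)
    vox_axis_coords(config$grid_shape[a], config$spacing_mm[a]))
  P <- config$n_phases
  w <- config$phase_waveform
  segs <- c("head", "body", "tail")

  # per-phase continuous segment centers; error if a segment leaves the grid
  centers_ph <- vector("list", P)
  for (p in seq_len(P)) {
    cp <- geo$centers + config$amplitude_mm * w[p]
    for (s in seq_along(segs)) for (a in 1:3) {
      lo <- cp[s, a] - geo$semis[s, a]
      hi <- cp[s, a] + geo$semis[s, a]
      if (lo < 0 || hi > geo$extent[a])
        stop(sprintf("segment '%s' leaves the grid at phase %d along %s",
                     segs[s], p, AXES[a]))
    }
    centers_ph[[p]] <- cp
  }

  # breathing background for image contrast: a torso whose anterior wall
  # rises with inhalation (AP semi-axis tracks the waveform, so every axial
  # slice carries respiratory information, as in real abdominal MR) and a
  # liver-like structure moving with 1.5x the body-segment amplitudes
  torso_center <- geo$mid
  torso_semi <- c(0.46, 0.38, 0.70) * geo$extent
  torso_ap_breath <- config$torso_breath_mm
  liver_center <- c(geo$mid[1], geo$mid[2] - 0.23 * geo$extent[2], geo$mid[3])
  liver_semi <- c(0.30 * geo$extent[1], 0.145 * geo$extent[2], 0.42 * geo$extent[3])
  liver_amp <- 1.5 * config$amplitude_mm["body", ]

  masks <- seg_labels <- intensity_clean <- intensity <- vector("list", P)
  set.seed(config$seed)
  for (p in seq_len(P)) {
    lab <- array(0L, config$grid_shape)
    for (s in seq_along(segs)) {
      m <- ellipsoid_mask(coords, centers_ph[[p]][s, ], geo$semis[s, ])
      lab[m] <- s
    }
    if (!all(tabulate(lab[lab > 0], 3) > 0))
      stop("a phantom segment voxelized to an empty mask at phase ", p)
    seg_labels[[p]] <- lab
    masks[[p]] <- lab > 0L
    if (render_intensity) {
      torso <- ellipsoid_mask(coords, torso_center,
                              torso_semi + c(0, torso_ap_breath, 0) * w[p])
      liver <- ellipsoid_mask(coords, liver_center + liver_amp * w[p], liver_semi)
      img <- pmax(0.25 * torso, 0.5 * liver, 1.0 * (lab > 0))
      img <- smooth_gauss3d(img, c(1, 1, 0.5))
      intensity_clean[[p]] <- img
      intensity[[p]] <- img + stats::rnorm(length(img), sd = config$noise_sd)
    }
  }

  # analytic truth: segment COM = shifted ellipsoid center; pancreas COM =
  # continuous-volume-weighted mean of the (disjoint) segment COMs
  seg_vol <- apply(geo$semis, 1, prod) * 4 / 3 * pi
  truth <- list()
  for (s in seq_along(segs))
    truth[[segs[s]]] <- t(vapply(centers_ph, function(cp) cp[s, ], numeric(3)))
  truth$pancreas <- Reduce(`+`, lapply(seq_along(segs), function(s)
    seg_vol[s] * truth[[segs[s]]])) / sum(seg_vol)
  truth <- truth[STRUCTURES]
  for (s in STRUCTURES) colnames(truth[[s]]) <- AXES

  ref <- suppressWarnings(com_stability(truth$pancreas)$reference_phase)
  disp <- lapply(truth, function(tr) sweep(tr, 2, tr[ref, ]))

  structure(list(masks = masks, seg_labels = seg_labels,
                 intensity = intensity, intensity_clean = intensity_clean,
                 truth_com_mm = truth, truth_displacement_mm = disp,
                 truth_reference_phase = ref,
                 spacing_mm = config$spacing_mm, n_phases = P,
                 noise_sd = config$noise_sd,
                 position_label = config$position_label,
                 device_label = config$device_label,
                 config = config),
            class = "phantom4d")
}

#' Configuration of the dynamic multi-slice acquisition
#'
#' @param n_slices number of axial slice positions imaged repeatedly
#' @param n_measurements repeated measurements per slice position
#' @param slice_time_ms time to acquire one 2D image
#' @param slice_order `"interleaved"` (odd positions then even) or
#'   `"sequential"`
#' @param breathing_period_s breathing cycle length in seconds
#' @param seed random-state integer (acquisition noise)
#' @return object of class `acq_config`
#' @export
acq_config <- function(n_slices = 25L, n_measurements = 30L,
                       slice_time_ms = 216.97,
                       slice_order = c("interleaved", "sequential"),
                       breathing_period_s = 4.3, seed = 1L) {
  slice_order <- match.arg(slice_order)
  stopifnot(n_slices >= 2, n_measurements >= 1, slice_time_ms > 0,
            breathing_period_s * 1000 > 2 * slice_time_ms)
  structure(list(n_slices = as.integer(n_slices),
                 n_measurements = as.integer(n_measurements),
                 slice_time_ms = slice_time_ms, slice_order = slice_order,
                 breathing_period_s = breathing_period_s,
                 seed = as.integer(seed)),
            class = "acq_config")
}

#' Simulate the dynamic interleaved acquisition of a phantom
#'
#' Emits `n_slices * n_measurements` 2D axial slices in acquisition-time
#' order. Each slice is sampled from the phase-resolved (noise-free)
#' intensity volume whose phase is the breathing phase at that slice's
#' acquisition time — the continuous cycle fraction derived from
#' `breathing_period_s`, quantized to the nearest phantom phase — with
#' fresh additive Gaussian noise per acquisition. Ground-truth phases and
#' cycle fractions are stored per slice.
#'
#' @param phantom a [generate_phantom()] result
#' @param acq an [acq_config()]
#' @return object of class `dyn_series`: `images` (list of matrices),
#'   `meta` (data.frame: seq, slice_index, volume_slice, measurement,
#'   time_ms, true_fraction, true_phase), plus geometry fields
#' @export
simulate_dynamic_acquisition <- function(phantom, acq = acq_config()) {
  stopifnot(inherits(phantom, "phantom4d"), inherits(acq, "acq_config"))
  dz <- dim(phantom$intensity_clean[[1]])[3]
  if (dz < acq$n_slices)
    stop("phantom SI extent (", dz, " slices) smaller than n_slices")
  start <- (dz - acq$n_slices) %/% 2L
  order_idx <- switch(acq$slice_order,
                      interleaved = c(seq(1L, acq$n_slices, 2L),
                                      seq(2L, acq$n_slices, 2L)),
                      sequential = seq_len(acq$n_slices))
  N <- acq$n_slices * acq$n_measurements
  q <- 0:(N - 1)
  slice_index <- order_idx[(q %% acq$n_slices) + 1L]
  measurement <- q %/% acq$n_slices + 1L
  time_ms <- q * acq$slice_time_ms
  P <- phantom$n_phases
  frac <- (time_ms / 1000 / acq$breathing_period_s) %% 1
  phase <- (round_half_away(frac * P) %% P) + 1L

  set.seed(acq$seed)
  images <- vector("list", N)
  for (i in seq_len(N)) {
    img <- phantom$intensity_clean[[phase[i]]][, , start + slice_index[i]]
    images[[i]] <- img + stats::rnorm(length(img), sd = phantom$noise_sd)
  }
  structure(list(images = images,
                 meta = data.frame(seq = seq_len(N), slice_index = slice_index,
                                   volume_slice = start + slice_index,
                                   measurement = measurement, time_ms = time_ms,
                                   true_fraction = frac, true_phase = phase),
                 spacing_mm = phantom$spacing_mm,
                 n_slices = acq$n_slices, n_measurements = acq$n_measurements,
                 slice_time_ms = acq$slice_time_ms,
                 breathing_period_s = acq$breathing_period_s,
                 slice_start = start),
            class = "dyn_series")
}
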