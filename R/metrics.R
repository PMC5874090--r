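# Segmentation-reliability indexes: Pearson correlation of COM-registered
# integral map profiles, and volume consistency across breathing phases.
# Both assume the organ moves quasi-rigidly, so a trustworthy segmentation
# keeps (approximately) the same shape and volume in every phase.

#' Integral map profile of a binary map
#'
#' The 1D marginal of the map along one axis: the sum of voxel values over
#' the two other axes. The profile sum equals the map's voxel count.
#'
#' @param map binary 3D array
#' @param axis `"LL"`, `"AP"` or `"SI"` (or 1:3)
#' @return list: `axis`, `values` (numeric vector), `origin_voxel` (= 1)
#' @export
integral_profile <- function(map, axis) {
  a <- if (is.character(axis)) match(axis, AXES) else as.integer(axis)
  stopifnot(length(dim(map)) == 3, a %in% 1:3)
  list(axis = AXES[a], values = as.numeric(apply(map != 0, a, sum)),
       origin_voxel = 1L)
}

profile_com <- function(values) sum(seq_along(values) * values) / sum(values)

#' Register one integral profile onto a reference profile
#'
#' Shifts `p` by the nearest-integer voxel offset of the reference-minus-p
#' profile COM (rounding half away from zero), zero-filling vacated bins.
#' The returned `support` marks the bins still backed by original data, to
#' which correlations are cropped (zero-padding would deflate them
#' spuriously).
#'
#' @param p,ref [integral_profile()] results on the same axis
#' @return list: `axis`, `values` (shifted), `shift` (voxels), `support`
#'   (integer indices of valid bins)
#' @export
register_profile <- function(p, ref) {
  stopifnot(identical(p$axis, ref$axis))
  if (sum(p$values) == 0 || sum(ref$values) == 0)
    stop("cannot register an empty profile")
  shift <- round_half_away(profile_com(ref$values) - profile_com(p$values))
  n <- length(p$values)
  out <- numeric(n)
  src <- seq_len(n) - shift
  ok <- src >= 1 & src <= n
  out[ok] <- p$values[src[ok]]
  list(axis = p$axis, values = out, shift = shift, support = which(ok))
}

#' Pearson profile-correlation reliability index
#'
#' Every phase's integral profile is rigidly registered (by profile-COM
#' shift) onto the reference phase; Pearson correlations are then computed
#' between each phase's registered profile and every other phase's, over
#' the bins in both profiles' supports. The per-phase scalar is the median
#' of that phase's pairwise correlations; the index is summarized as the
#' median and interquartile range across phases.
#'
#' @param maps list of per-phase binary maps for one structure
#' @param axis `"LL"`, `"AP"` or `"SI"`
#' @param ref_phase phase whose profile is the registration target
#' @return list: `per_phase` (numeric, NA where a profile has zero
#'   variance), `median`, `iqr`, `pairwise` (phase x phase matrix)
#' @export
pearson_profile_index <- function(maps, axis, ref_phase = 1L) {
  P <- length(maps)
  stopifnot(P >= 2, ref_phase >= 1, ref_phase <= P)
  profs <- lapply(maps, integral_profile, axis = axis)
  reg <- lapply(profs, register_profile, ref = profs[[ref_phase]])
  pw <- matrix(NA_real_, P, P)
  diag(pw) <- 1
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    sup <- intersect(reg[[i]]$support, reg[[j]]$support)
    vi <- reg[[i]]$values[sup]; vj <- reg[[j]]$values[sup]
    if (stats::sd(vi) == 0 || stats::sd(vj) == 0) {
      warning("zero-variance profile in phase pair (", i, ",", j,
              "); correlation undefined")
      next
    }
    pw[i, j] <- pw[j, i] <- stats::cor(vi, vj)
  }
  per_phase <- vapply(seq_len(P), function(i) {
    v <- pw[i, -i]
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  }, numeric(1))
  ok <- !is.na(per_phase)
  list(per_phase = per_phase,
       median = if (any(ok)) stats::median(per_phase[ok]) else NA_real_,
       iqr = if (any(ok)) iqr_lin(per_phase[ok]) else NA_real_,
       pairwise = pw)
}

#' Volume-consistency reliability index
#'
#' Per phase, the percentage volume difference with respect to the maximum
#' phase volume, `100 * (Vmax - V) / Vmax`; summarized as median and IQR
#' across phases. Volumes are in cc (voxel count x voxel volume).
#'
#' @param maps list of per-phase binary maps for one structure
#' @param spacing_mm voxel size per axis (mm)
#' @return list: `volume_cc` (per phase), `per_phase` (percent),
#'   `median`, `iqr`
#' @export
volume_consistency <- function(maps, spacing_mm) {
  stopifnot(length(maps) >= 2)
  counts <- vapply(maps, function(m) sum(m != 0), numeric(1))
  if (any(counts == 0)) stop("structure empty in phase ",
                             paste(which(counts == 0), collapse = ", "))
  vol_cc <- counts * prod(spacing_mm) / 1000
  vmax <- max(vol_cc)
  per <- 100 * (vmax - vol_cc) / vmax
  list(volume_cc = vol_cc, per_phase = per,
       median = stats::median(per), iqr = iqr_lin(per))
}

#' Segmentation-reliability report for a partitioned 4D mask set
#'
#' Computes, per structure (pancreas, head, body, tail), the Pearson
#' profile index along LL, AP and SI and the volume consistency, in the
#' layout of a segmentation-reliability summary table.
#'
#' @param labels4d a [partition_4d()] result
#' @param ref_phase registration reference phase; if `NULL` it is selected
#'   as the whole-gland COM-stability minimum (see
#'   [select_reference_phase()])
#' @return data.frame with one row per structure: Pearson median/IQR per
#'   axis, median volume (cc) and IQR, volume consistency median/IQR (%)
#' @export
reliability_report <- function(labels4d, ref_phase = NULL) {
  sp <- labels4d$spacing_mm
  if (is.null(ref_phase)) {
    traj <- com_trajectory(structure_masks(labels4d, "pancreas"), sp)
    ref_phase <- com_stability(traj)$reference_phase
  }
  rows <- lapply(STRUCTURES, function(st) {
    maps <- structure_masks(labels4d, st)
    pe <- lapply(AXES, function(ax)
      pearson_profile_index(maps, ax, ref_phase = ref_phase))
    vc <- volume_consistency(maps, sp)
    data.frame(structure = st,
               pearson_LL_median = pe[[1]]$median, pearson_LL_iqr = pe[[1]]$iqr,
               pearson_AP_median = pe[[2]]$median, pearson_AP_iqr = pe[[2]]$iqr,
               pearson_SI_median = pe[[3]]$median, pearson_SI_iqr = pe[[3]]$iqr,
               volume_cc_median = stats::median(vc$volume_cc),
               volume_cc_iqr = iqr_lin(vc$volume_cc),
               volume_consistency_median = vc$median,
               volume_consistency_iqr = vc$iqr)
  })
  out <- do.call(rbind, rows)
  attr(out, "ref_phase") <- ref_phase
  out
}
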