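# Shared small helpers. Axis convention used throughout the package:
# array axis 1 = LL (positive = patient-left), 2 = AP, 3 = SI (positive = superior).

AXES <- c("LL", "AP", "SI")
STRUCTURES <- c("pancreas", "head", "body", "tail")

#' Physical coordinates of voxel centers along one axis
#'
#' Voxel i (1-based) has its center at (i - 1) * spacing + spacing / 2 mm.
#'
#' @param n number of voxels
#' @param spacing voxel size in mm
#' @return numeric vector of length `n`
#' @keywords internal
vox_axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing + spacing / 2

# round half away from zero (documented rounding rule for profile registration)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# interquartile range with linear interpolation of the empirical cdf at (n+1)p,
# the convention under which e.g. {-1, 0, 1, 2, 3} has Q1 = -0.5, Q3 = 2.5, IQR = 3
iqr_lin <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 6, names = FALSE)
  unname(q[2] - q[1])
}

med_iqr <- function(x) c(median = unname(stats::median(x)), iqr = iqr_lin(x))

# zero-fill shift of a 3D array by k voxels along one axis (k may be negative)
shift_array <- function(a, k, axis) {
  if (k == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- idx_dst <- rep(list(quote(expr = )), 3)
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  out
}

# separable Gaussian smoothing of a 3D array, sigma in voxels per axis
smooth_gauss3d <- function(a, sigma_vox = c(1, 1, 0.5), radius = 2L) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    off <- -radius:radius
    w <- exp(-off^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (i in seq_along(off)) acc <- acc + w[i] * shift_array(a, off[i], axis)
    a <- acc
  }
  a
}

#' Center of mass of a binary map
#'
#' Unweighted mean of the member voxel-center coordinates, in mm, following
#' the package axis convention (LL, AP, SI).
#'
#' @param mask 3D array, nonzero entries are members
#' @param spacing_mm voxel size per axis (mm)
#' @return named numeric 3-vector (LL, AP, SI) in mm
#' @export
com <- function(mask, spacing_mm) {
  stopifnot(length(dim(mask)) == 3, length(spacing_mm) == 3)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: center of mass is undefined")
  out <- colMeans((idx - 1) %*% diag(spacing_mm)) + spacing_mm / 2
  names(out) <- AXES
  out
}

# validate a list of per-phase binary masks sharing geometry
validate_mask4d <- function(masks, spacing_mm) {
  stopifnot(is.list(masks), length(masks) >= 2)
  d <- dim(masks[[1]])
  for (p in seq_along(masks)) {
    if (!identical(dim(masks[[p]]), d))
      stop("mask geometry differs at phase ", p)
    if (sum(masks[[p]] != 0) == 0L)
      stop("mask is empty at phase ", p)
  }
  invisible(TRUE)
}
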