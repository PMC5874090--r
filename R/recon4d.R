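# Retrospective phase-sorted 4D reconstruction from a dynamic 2D slice
# series. An image-based respiratory surrogate is obtained as the mutual
# information (MI) between each acquired slice and a self-consistent
# reference volume; surrogate extrema then anchor the division of each
# breathing cycle into equal phase-fraction bins.

#' Mutual information between two images (bits)
#'
#' Computed from the joint intensity histogram after min-max scaling each
#' image independently to `[0, 1]`, with base-2 logarithms. Symmetric and
#' non-negative. A constant image carries zero entropy, so any MI involving
#' one is defined as 0.
#'
#' @param a,b numeric matrices of equal shape
#' @param n_bins number of histogram bins per image (>= 2)
#' @return scalar MI in bits
#' @export
mutual_information <- function(a, b, n_bins = 64L) {
  stopifnot(identical(dim(a), dim(b)), n_bins >= 2)
  sa <- scale_unit(a); sb <- scale_unit(b)
  if (is.null(sa) || is.null(sb)) return(0)
  ia <- bin_unit(sa, n_bins); ib <- bin_unit(sb, n_bins)
  joint <- tabulate((ia - 1L) * n_bins + ib, nbins = n_bins * n_bins)
  n <- length(ia)
  pj <- joint / n
  pa <- tabulate(ia, n_bins) / n
  pb <- tabulate(ib, n_bins) / n
  nz <- which(pj > 0)
  ra <- ((nz - 1L) %/% n_bins) + 1L
  rb <- ((nz - 1L) %% n_bins) + 1L
  sum(pj[nz] * log2(pj[nz] / (pa[ra] * pb[rb])))
}

scale_unit <- function(x) {
  r <- range(x)
  if (r[2] <= r[1]) return(NULL)
  (x - r[1]) / (r[2] - r[1])
}

# Shannon entropy (bits) of a min-max scaled image under the same binning
image_entropy <- function(a, n_bins = 64L) {
  sa <- scale_unit(a)
  if (is.null(sa)) return(0)
  p <- tabulate(bin_unit(sa, n_bins), n_bins) / length(sa)
  -sum(p[p > 0] * log2(p[p > 0]))
}

# normalized MI, 2 I(a,b) / (H(a) + H(b)): removes the dependence of raw MI
# on per-image entropy, so similarity comparisons across image pairs with
# different structural content are on a common scale
normalized_mi <- function(a, b, n_bins = 64L) {
  h <- image_entropy(a, n_bins) + image_entropy(b, n_bins)
  if (h == 0) return(0)
  2 * mutual_information(a, b, n_bins) / h
}

bin_unit <- function(x, n_bins) pmin(floor(x * n_bins) + 1L, n_bins)

slice_groups <- function(series) split(seq_len(nrow(series$meta)), series$meta$slice_index)

#' Build a self-consistent reference volume from a dynamic series
#'
#' One measurement is chosen per slice position and the choices are stacked
#' into a 3D volume. The chain starts at a central slice position and
#' extends outward, each new position taking the measurement with maximal
#' MI against the already-chosen neighboring slice, so all chosen slices
#' depict (approximately) the same respiratory state.
#'
#' With `method = "extreme"` (default), each slice position independently
#' takes the measurement with the *smallest* total normalized MI to the
#' other measurements at that position: the most transient respiratory
#' state. In free breathing, exhalation occupies most of the cycle, so the
#' most transient state is end inhalation — every chosen slice then depicts
#' end inhalation without any cross-slice chaining, and the surrogate
#' maxima (best match to the reference) mark end-inhalation recurrences.
#' `method = "medoid"` takes the *largest* total normalized MI instead (the
#' most representative, mid-cycle state; note the MI surrogate against a
#' mid-cycle reference is ambiguous between the inhale and exhale branches).
#' `method = "chain"` reproduces a greedy adjacent-slice chain: the central
#' adjacent pair of positions takes the measurement pair of maximal MI and
#' the chain extends outward, each next position taking the measurement
#' with maximal MI against the already-chosen neighboring slice; it depends
#' on every adjacent slice pair being respiration-discriminative and can
#' drift where one is not.
#'
#' @param series a `dyn_series`
#' @param n_bins MI histogram bins
#' @param method `"extreme"`, `"medoid"` or `"chain"`
#' @return list with `volume` (3D array), `chosen` (data.frame slice_index,
#'   measurement), `method`
#' @export
build_reference_volume <- function(series, n_bins = 64L,
                                   method = c("extreme", "medoid", "chain")) {
  method <- match.arg(method)
  grp <- slice_groups(series)
  pos <- sort(as.integer(names(grp)))
  if (length(pos) < 2) stop("need at least 2 slice positions")
  missing_pos <- setdiff(seq_len(series$n_slices), pos)
  if (length(missing_pos))
    stop("missing slice indices: ", paste(missing_pos, collapse = ", "))

  img_at <- function(p, j) series$images[[grp[[as.character(p)]][j]]]
  n_meas <- vapply(grp, length, integer(1))
  chosen <- setNames(rep(NA_integer_, length(pos)), pos)

  if (method %in% c("extreme", "medoid")) {
    for (p in pos) {
      m <- n_meas[[as.character(p)]]
      if (m == 1) { chosen[as.character(p)] <- 1L; next }
      H <- vapply(seq_len(m), function(j)
        image_entropy(img_at(p, j), n_bins), numeric(1))
      tot <- numeric(m)
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        h <- H[i] + H[j]
        v <- if (h == 0) 0 else
          2 * mutual_information(img_at(p, i), img_at(p, j), n_bins) / h
        tot[i] <- tot[i] + v
        tot[j] <- tot[j] + v
      }
      chosen[as.character(p)] <-
        if (method == "extreme") which.min(tot) else which.max(tot)
    }
  } else {
    k0 <- floor(length(pos) / 2)         # central position (left of center)
    c1 <- pos[k0]; c2 <- pos[k0 + 1]
    m1 <- n_meas[[as.character(c1)]]; m2 <- n_meas[[as.character(c2)]]
    mi <- matrix(NA_real_, m1, m2)
    for (i in seq_len(m1)) for (j in seq_len(m2))
      mi[i, j] <- mutual_information(img_at(c1, i), img_at(c2, j), n_bins)
    best <- arrayInd(which.max(mi), dim(mi))
    chosen[as.character(c1)] <- best[1]
    chosen[as.character(c2)] <- best[2]
    pick <- function(p, neighbor_img) {
      m <- n_meas[[as.character(p)]]
      mi <- vapply(seq_len(m), function(j)
        mutual_information(img_at(p, j), neighbor_img, n_bins), numeric(1))
      which.max(mi)
    }
    for (k in seq_along(pos)) {
      pk <- pos[k]
      if (k > k0 + 1)
        chosen[as.character(pk)] <-
          pick(pk, img_at(pos[k - 1], chosen[as.character(pos[k - 1])]))
    }
    for (k in rev(seq_len(k0 - 1))) {
      pk <- pos[k]
      chosen[as.character(pk)] <-
        pick(pk, img_at(pos[k + 1], chosen[as.character(pos[k + 1])]))
    }
  }

  d2 <- dim(series$images[[1]])
  vol <- array(NA_real_, c(d2, length(pos)))
  for (k in seq_along(pos)) vol[, , k] <- img_at(pos[k], chosen[as.character(pos[k])])
  list(volume = vol,
       chosen = data.frame(slice_index = pos,
                           measurement = unname(chosen[as.character(pos)])),
       method = method)
}

#' Extract the MI respiratory surrogate signal
#'
#' For every acquired slice, the MI against the reference slice at the same
#' slice position, emitted in acquisition-time order.
#'
#' @param series a `dyn_series`
#' @param ref a [build_reference_volume()] result
#' @param n_bins MI histogram bins
#' @return data.frame (seq, slice_index, time_ms, mi) ordered by time
#' @export
extract_surrogate <- function(series, ref, n_bins = 64L) {
  pos <- ref$chosen$slice_index
  mi <- numeric(nrow(series$meta))
  for (i in seq_len(nrow(series$meta))) {
    k <- match(series$meta$slice_index[i], pos)
    mi[i] <- mutual_information(series$images[[i]], ref$volume[, , k], n_bins)
  }
  out <- data.frame(seq = series$meta$seq, slice_index = series$meta$slice_index,
                    time_ms = series$meta$time_ms, mi = mi)
  out[order(out$time_ms), ]
}

# R^2 of a two-harmonic regression of z on cycle fraction (t / T mod 1);
# returns the fit too when coef = TRUE
harmonic_fit <- function(t, z, T, coef = FALSE) {
  f <- (t / T) %% 1
  X <- cbind(1, sin(2 * pi * f), cos(2 * pi * f),
             sin(4 * pi * f), cos(4 * pi * f))
  b <- tryCatch(solve(crossprod(X), crossprod(X, z)),
                error = function(e) NULL)
  if (is.null(b)) return(if (coef) NULL else -Inf)
  res <- z - X %*% b
  r2 <- 1 - sum(res^2) / sum((z - mean(z))^2)
  if (coef) list(beta = b, r2 = r2) else r2
}

#' Assign a breathing-phase label to every slice of a series
#'
#' The surrogate is min-max normalized within each slice-index group (MI
#' scales differ across anatomy). The breathing cycle is then estimated
#' globally from all samples pooled in acquisition-time order: a
#' coarse-to-fine grid search over the period in `period_range_s` maximizes
#' the R^2 of a two-harmonic regression of the normalized signal on cycle
#' fraction, and the fraction at which the fitted curve attains its
#' extremum (maximum for `anchor = "peak"`) defines the cycle origin.
#' Pooling keeps the effective sampling rate at one sample per slice time,
#' far above the breathing rate, so the period estimate is alias-free even
#' though each single slice position is sampled below the breathing rate;
#' slice positions with little respiratory content merely dilute the fit.
#'
#' With the reference volume anchored at the most transient respiratory
#' state (end inhalation, see [build_reference_volume()]), the surrogate
#' maxima mark end-inhalation recurrences, so bin 1 is centered on end
#' inhalation by construction. Every slice receives the continuous cycle
#' fraction of its acquisition time, quantized to the nearest of
#' `n_phases` equal bins.
#'
#' @param sig surrogate data.frame from [extract_surrogate()]
#' @param n_phases number of phase bins
#' @param anchor `"peak"` (default; cycle origin at the surrogate maximum =
#'   best match to the reference state) or `"trough"`
#' @param period_range_s admissible breathing-period range (seconds)
#' @return data.frame (seq, time_ms, fraction, phase); attributes
#'   `period_ms`, `anchor_fraction`, `r2`
#' @export
assign_phases <- function(sig, n_phases = 6L, anchor = c("peak", "trough"),
                          period_range_s = c(2, 8)) {
  anchor <- match.arg(anchor)
  stopifnot(n_phases >= 2, nrow(sig) >= 4)
  sig <- sig[order(sig$time_ms), ]
  z <- stats::ave(sig$mi, sig$slice_index, FUN = function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0.5, length(v))
  })
  # time origin at the first sample: phase labels are then exactly invariant
  # under any global time shift of the series
  t <- sig$time_ms - sig$time_ms[1]
  if (stats::sd(z) == 0)
    stop("no respiratory modulation detected in the surrogate signal")
  span <- max(t) - min(t)
  if (span < 2 * period_range_s[1] * 1000)
    stop("series too short: need at least 2 breathing cycles")

  # coarse-to-fine period search
  Ts <- seq(period_range_s[1] * 1000, min(period_range_s[2] * 1000, span / 2),
            by = 10)
  r2 <- vapply(Ts, function(T) harmonic_fit(t, z, T), numeric(1))
  T_best <- Ts[which.max(r2)]
  Tf <- seq(T_best - 15, T_best + 15, by = 1)
  r2f <- vapply(Tf, function(T) harmonic_fit(t, z, T), numeric(1))
  T_best <- Tf[which.max(r2f)]
  fit <- harmonic_fit(t, z, T_best, coef = TRUE)
  if (is.null(fit))
    stop("breathing-cycle fit failed; the surrogate may be degenerate")

  fg <- seq(0, 1, by = 0.001)
  Xg <- cbind(1, sin(2 * pi * fg), cos(2 * pi * fg),
              sin(4 * pi * fg), cos(4 * pi * fg))
  curve <- as.numeric(Xg %*% fit$beta)
  f0 <- fg[if (anchor == "peak") which.max(curve) else which.min(curve)]

  frac <- ((t / T_best) - f0) %% 1
  phase <- (round_half_away(frac * n_phases) %% n_phases) + 1L
  out <- data.frame(seq = sig$seq, time_ms = sig$time_ms, fraction = frac,
                    phase = phase)
  attr(out, "period_ms") <- T_best
  attr(out, "anchor_fraction") <- f0
  attr(out, "r2") <- fit$r2
  out
}

#' Reconstruct a phase-resolved 4D volume from labeled slices
#'
#' With `select = "central"` (default) each (phase, slice position) cell
#' takes the `top_k` member slices whose cycle fraction lies closest
#' (cyclically) to the bin center, averaged if `top_k > 1`: members near a
#' bin boundary are the ones most likely mislabeled by one phase, so the
#' most central member (`top_k = 1`, the default) gives the sharpest
#' respiratory gating. `select = "all"` averages every member of the cell
#' (stronger noise suppression, more inter-phase blur). Cells empty in one
#' phase are filled from the
#' cyclically nearest populated phase at the same slice position, ties
#' broken toward the earlier phase, with a `fill_log` entry.
#'
#' @param series a `dyn_series`
#' @param labels data.frame from [assign_phases()] (columns seq, phase and,
#'   for `select = "central"`, fraction)
#' @param n_phases number of phases
#' @param select `"central"` or `"all"`
#' @param top_k members averaged per cell under `"central"`
#' @return list with `phases` (list of 3D arrays), `fill_log` (data.frame
#'   slice_index, phase, donor_phase), `spacing_mm`
#' @export
reconstruct_4d <- function(series, labels, n_phases = 6L,
                           select = c("central", "all"), top_k = 1L) {
  select <- match.arg(select)
  ord <- match(series$meta$seq, labels$seq)
  ph <- labels$phase[ord]
  if (anyNA(ph)) stop("phase labels do not cover the series")
  weight_in <- rep(TRUE, length(ph))
  if (select == "central") {
    if (is.null(labels$fraction))
      stop("'central' selection needs a 'fraction' column in labels")
    fr <- labels$fraction[ord]
    cdist <- abs(fr - (ph - 1) / n_phases)
    cdist <- pmin(cdist, 1 - cdist)
    cell <- interaction(ph, series$meta$slice_index, drop = TRUE)
    weight_in <- unsplit(lapply(split(cdist, cell), function(d)
      rank(d, ties.method = "first") <= top_k), cell)
  }
  pos <- sort(unique(series$meta$slice_index))
  d2 <- dim(series$images[[1]])
  cells <- vector("list", n_phases)
  counts <- matrix(0L, n_phases, length(pos))
  for (p in seq_len(n_phases)) cells[[p]] <- array(0, c(d2, length(pos)))
  for (i in seq_len(nrow(series$meta))) {
    if (!weight_in[i]) next
    k <- match(series$meta$slice_index[i], pos)
    p <- ph[i]
    cells[[p]][, , k] <- cells[[p]][, , k] + series$images[[i]]
    counts[p, k] <- counts[p, k] + 1L
  }
  empty_all <- which(colSums(counts) == 0)
  if (length(empty_all))
    stop("slice positions with no data in any phase: ",
         paste(pos[empty_all], collapse = ", "))
  for (p in seq_len(n_phases)) for (k in seq_along(pos))
    if (counts[p, k] > 0)
      cells[[p]][, , k] <- cells[[p]][, , k] / counts[p, k]
  fill_log <- data.frame(slice_index = integer(), phase = integer(),
                         donor_phase = integer())
  for (p in seq_len(n_phases)) for (k in seq_along(pos)) {
    if (counts[p, k] == 0) {
      dist <- pmin((seq_len(n_phases) - p) %% n_phases,
                   (p - seq_len(n_phases)) %% n_phases)
      dist[counts[, k] == 0] <- Inf
      donor <- which(dist == min(dist))[1]  # ties toward the earlier phase
      cells[[p]][, , k] <- cells[[donor]][, , k]
      fill_log <- rbind(fill_log,
                        data.frame(slice_index = pos[k], phase = p,
                                   donor_phase = donor))
    }
  }
  list(phases = cells, fill_log = fill_log, spacing_mm = series$spacing_mm)
}

#' Threshold-segment a structure from a reconstructed 4D volume
#'
#' Simple intensity thresholding per phase; used to recover the bright
#' gland from reconstructed phantom volumes.
#'
#' @param vol4d a [reconstruct_4d()] result
#' @param threshold intensity cut (inclusive above)
#' @return list of logical arrays, one per phase
#' @export
segment_by_threshold <- function(vol4d, threshold = 0.6) {
  lapply(vol4d$phases, function(v) v >= threshold)
}
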