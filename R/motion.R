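# COM trajectories across breathing phases, the phase-stability index that
# selects the reference (gating) phase, and COM displacements relative to
# that reference.

#' COM trajectory of a structure across phases
#'
#' @param maps list of per-phase binary maps
#' @param spacing_mm voxel size per axis (mm)
#' @return phase x 3 matrix (columns LL, AP, SI) in mm
#' @export
com_trajectory <- function(maps, spacing_mm) {
  out <- t(vapply(maps, com, numeric(3), spacing_mm = spacing_mm))
  colnames(out) <- AXES
  out
}

#' COM phase-stability index
#'
#' For each phase, the mean absolute COM displacement relative to the two
#' adjacent breathing phases:
#' `stability(ph) = (|COM(ph-1) - COM(ph)| + |COM(ph+1) - COM(ph)|) / 2`,
#' computed per direction with absolute component differences and in 3D
#' with Euclidean norms of the two adjacent difference vectors. Adjacency
#' is cyclic by default (breathing is periodic: phase 1 neighbors the last
#' phase); with `adjacency = "truncated"` the boundary phases use their
#' single neighbor. The reference phase is the argmin of the 3D stability,
#' ties resolved toward the lower phase index (with a warning).
#'
#' @param traj phase x 3 COM matrix (mm), >= 3 phases
#' @param adjacency `"cyclic"` or `"truncated"`
#' @return list: `per_direction` (phase x 3 matrix, mm), `stability_3d`
#'   (numeric per phase, mm), `reference_phase`
#' @export
com_stability <- function(traj, adjacency = c("cyclic", "truncated")) {
  adjacency <- match.arg(adjacency)
  traj <- as.matrix(traj)
  P <- nrow(traj)
  stopifnot(P >= 3, ncol(traj) == 3)
  per_dir <- matrix(NA_real_, P, 3, dimnames = list(NULL, AXES))
  s3d <- numeric(P)
  for (p in seq_len(P)) {
    nb <- c(p - 1, p + 1)
    if (adjacency == "cyclic") {
      nb <- ((nb - 1) %% P) + 1
    } else {
      nb <- nb[nb >= 1 & nb <= P]
    }
    diffs <- traj[nb, , drop = FALSE] - matrix(traj[p, ], length(nb), 3,
                                               byrow = TRUE)
    per_dir[p, ] <- colMeans(abs(diffs))
    s3d[p] <- mean(sqrt(rowSums(diffs^2)))
  }
  mins <- which(s3d == min(s3d))
  if (length(mins) > 1)
    warning("tied minimum 3D stability at phases ",
            paste(mins, collapse = ", "), "; selecting the lowest index")
  list(per_direction = per_dir, stability_3d = s3d,
       reference_phase = mins[1])
}

#' Reference-phase selection
#'
#' The breathing phase with maximal stability, i.e. the minimum of the 3D
#' COM-stability index.
#'
#' @param stab a [com_stability()] result
#' @return integer phase id
#' @export
select_reference_phase <- function(stab) stab$reference_phase

#' COM displacement relative to a reference phase
#'
#' Displacements are rounded to nm precision (1e-6 mm): differences below
#' numerical noise are physically meaningless and would otherwise break
#' exact ties in the rank-based setup statistics.
#'
#' @param traj phase x 3 COM matrix (mm)
#' @param ref_phase reference phase id
#' @return phase x 4 matrix: signed LL/AP/SI displacement and 3D magnitude
#' @export
com_displacement <- function(traj, ref_phase) {
  traj <- as.matrix(traj)
  stopifnot(ref_phase >= 1, ref_phase <= nrow(traj))
  d <- round(sweep(traj, 2, traj[ref_phase, ]), 6)
  cbind(d, D3 = round(sqrt(rowSums(d^2)), 6))
}

#' Motion records for one 4D dataset
#'
#' Computes the COM trajectory per structure, selects the reference phase
#' from the whole-gland 3D stability, and expresses every structure's
#' motion as COM displacement relative to that shared reference, producing
#' one long-format row per (structure, phase).
#'
#' @param labels4d a [partition_4d()] result, or a plain list of per-phase
#'   binary masks (then only the whole pancreas is analyzed)
#' @param spacing_mm voxel size per axis (mm); ignored when `labels4d` is a
#'   `segment_labels4d`
#' @param dataset,position,device metadata labels attached to each record
#' @param adjacency stability adjacency rule, see [com_stability()]
#' @return data.frame: dataset, position, device, structure, phase, LL, AP,
#'   SI, D3 (mm), is_reference; with attribute `ref_phase`
#' @export
motion_records <- function(labels4d, spacing_mm = NULL, dataset = "dataset1",
                           position = "prone", device = "vacuum",
                           adjacency = "cyclic") {
  if (inherits(labels4d, "segment_labels4d")) {
    sp <- labels4d$spacing_mm
    trajs <- lapply(STRUCTURES, function(st)
      com_trajectory(structure_masks(labels4d, st), sp))
    names(trajs) <- STRUCTURES
  } else {
    stopifnot(!is.null(spacing_mm))
    trajs <- list(pancreas = com_trajectory(labels4d, spacing_mm))
  }
  motion_records_from_traj(trajs, dataset, position, device, adjacency)
}

#' Motion records from precomputed COM trajectories
#'
#' @param trajs named list of phase x 3 COM matrices (must include
#'   `pancreas`, whose stability selects the reference phase)
#' @param dataset,position,device metadata labels
#' @param adjacency stability adjacency rule
#' @return long-format data.frame as in [motion_records()]
#' @export
motion_records_from_traj <- function(trajs, dataset = "dataset1",
                                     position = "prone", device = "vacuum",
                                     adjacency = "cyclic") {
  stopifnot("pancreas" %in% names(trajs))
  ref <- com_stability(trajs$pancreas, adjacency = adjacency)$reference_phase
  rows <- lapply(names(trajs), function(st) {
    d <- com_displacement(trajs[[st]], ref)
    data.frame(dataset = dataset, position = position, device = device,
               structure = st, phase = seq_len(nrow(d)),
               LL = d[, 1], AP = d[, 2], SI = d[, 3], D3 = d[, 4],
               is_reference = seq_len(nrow(d)) == ref)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "ref_phase") <- ref
  out
}

#' Summarize motion records as median and IQR per setup
#'
#' Groups records by (dataset, position, device, structure) and reports,
#' per motion direction, the median and interquartile range of the COM
#' displacements over the non-reference phases (quartiles by linear
#' interpolation at (n+1)p; IQR = Q3 - Q1). Empty groups are omitted with a
#' warning.
#'
#' @param records data.frame from [motion_records()] (possibly row-bound
#'   over datasets/setups)
#' @return data.frame: grouping columns plus `<dir>_median`, `<dir>_iqr`
#'   for LL, AP, SI and D3
#' @export
summarize_motion <- function(records) {
  keep <- !records$is_reference
  if (!any(keep)) {
    warning("no non-reference records to summarize")
    return(data.frame())
  }
  rec <- records[keep, ]
  key <- interaction(rec$dataset, rec$position, rec$device, rec$structure,
                     drop = TRUE)
  rows <- lapply(split(rec, key), function(g) {
    out <- data.frame(dataset = g$dataset[1], position = g$position[1],
                      device = g$device[1], structure = g$structure[1],
                      n_phases = nrow(g))
    for (dir in c(AXES, "D3")) {
      mi <- med_iqr(g[[dir]])
      out[[paste0(dir, "_median")]] <- mi["median"]
      out[[paste0(dir, "_iqr")]] <- mi["iqr"]
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Flag box-plot outliers by the 1.5 IQR fence rule
#'
#' Values larger than `q3 + 1.5 (q3 - q1)` or smaller than
#' `q1 - 1.5 (q3 - q1)` are flagged. Flagging only: no value is ever
#' excluded from the statistics.
#'
#' @param x numeric vector
#' @return logical vector
#' @export
flag_outliers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 6, names = FALSE)
  fence <- 1.5 * (q[2] - q[1])
  x > q[2] + fence | x < q[1] - fence
}
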