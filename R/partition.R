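# Partition of each phase's binary pancreas map into head/body/tail by
# Lloyd k-means (k = 3) on physical voxel-center coordinates, with centroid
# propagation across breathing phases and a phase-1 re-run from the last
# phase's centroids to wash out random-initialization effects.

mask_coords_mm <- function(mask, spacing_mm) {
  idx <- which(mask != 0, arr.ind = TRUE)
  sweep((idx - 1) %*% diag(spacing_mm), 2, spacing_mm / 2, `+`)
}

#' k-means clustering of one binary map
#'
#' Lloyd iterations on the voxel-center coordinates (mm) of the mask, with
#' Euclidean distance, until the assignment is fixed or `max_iter`
#' iterations. If a cluster empties during iteration its centroid is
#' re-seeded at the voxel farthest from the remaining centroids (recorded
#' in `reseeds`).
#'
#' @param mask binary 3D array with >= 3 member voxels
#' @param spacing_mm voxel size per axis (mm)
#' @param init 3x3 matrix of initial centroids (rows = clusters, columns =
#'   LL/AP/SI in mm); must be distinct
#' @param max_iter iteration cap
#' @return list: `labels` (integer vector over mask voxels, in
#'   `which(mask)` order), `centroids` (3x3 matrix), `wcss` (within-cluster
#'   sum of squares per iteration), `iterations`, `reseeds`
#' @export
kmeans_phase <- function(mask, spacing_mm, init, max_iter = 100L) {
  x <- mask_coords_mm(mask, spacing_mm)
  n <- nrow(x)
  if (n < 3) stop("mask has fewer than 3 voxels; cannot form 3 clusters")
  stopifnot(is.matrix(init), all(dim(init) == c(3, 3)))
  if (anyDuplicated(init)) stop("initial centroids must be distinct")
  cen <- init
  assign_nearest <- function(cen) {
    d <- vapply(1:3, function(k)
      rowSums(sweep(x, 2, cen[k, ])^2), numeric(n))
    max.col(-d, ties.method = "first")
  }
  lab <- assign_nearest(cen)
  wcss <- numeric(0)
  reseeds <- 0L
  for (it in seq_len(max_iter)) {
    for (k in 1:3) {
      if (!any(lab == k)) {        # re-seed empty cluster at farthest voxel
        others <- cen[seq_len(3) != k, , drop = FALSE]
        dmin <- apply(vapply(seq_len(nrow(others)), function(j)
          rowSums(sweep(x, 2, others[j, ])^2), numeric(n)), 1, min)
        cen[k, ] <- x[which.max(dmin), ]
        reseeds <- reseeds + 1L
        lab <- assign_nearest(cen)
      }
    }
    for (k in 1:3) cen[k, ] <- colMeans(x[lab == k, , drop = FALSE])
    wcss <- c(wcss, sum(vapply(1:3, function(k)
      sum(sweep(x[lab == k, , drop = FALSE], 2, cen[k, ])^2), numeric(1))))
    new_lab <- assign_nearest(cen)
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  colnames(cen) <- AXES
  list(labels = lab, centroids = cen, wcss = wcss, iterations = it,
       reseeds = reseeds)
}

#' Partition a 4D mask set into head, body and tail segments
#'
#' Phase 1 is clustered from a seeded random initialization (3 distinct mask
#' voxels); each subsequent phase is initialized from the previous phase's
#' final centroids; finally phase 1 is re-clustered from the last phase's
#' centroids, replacing the first result. Anatomical identities are then
#' assigned by sorting each phase's final centroids along LL: the head is
#' the most patient-right cluster (smallest LL coordinate under the
#' positive-LL-is-left convention).
#'
#' @param masks list of per-phase binary 3D arrays (shared geometry)
#' @param spacing_mm voxel size per axis (mm)
#' @param seed integer seed for the phase-1 random initialization
#' @return object of class `segment_labels4d`: `labels` (list of integer
#'   arrays, 0 background / 1 head / 2 body / 3 tail), `centroids_mm`
#'   (data.frame phase, segment, LL, AP, SI), `init_centroids_mm`,
#'   `spacing_mm`
#' @export
partition_4d <- function(masks, spacing_mm, seed = 1L) {
  validate_mask4d(masks, spacing_mm)
  P <- length(masks)
  if (sum(masks[[1]] != 0) < 3) stop("degenerate mask: fewer than 3 voxels")
  set.seed(seed)
  x1 <- mask_coords_mm(masks[[1]], spacing_mm)
  init <- x1[sample.int(nrow(x1), 3), , drop = FALSE]
  init_used <- vector("list", P + 1)
  fits <- vector("list", P)
  cur <- init
  for (p in seq_len(P)) {
    init_used[[p]] <- cur
    fits[[p]] <- kmeans_phase(masks[[p]], spacing_mm, cur)
    cur <- fits[[p]]$centroids
  }
  # re-run phase 1 from the last phase's centroids
  init_used[[P + 1]] <- cur
  fits[[1]] <- kmeans_phase(masks[[1]], spacing_mm, cur)

  labels <- vector("list", P)
  cen_rows <- list()
  for (p in seq_len(P)) {
    ord <- order(fits[[p]]$centroids[, 1])      # head = smallest LL
    relabel <- integer(3)
    relabel[ord] <- 1:3
    lab_map <- array(0L, dim(masks[[p]]))
    lab_map[which(masks[[p]] != 0)] <- relabel[fits[[p]]$labels]
    labels[[p]] <- lab_map
    cen <- fits[[p]]$centroids[ord, , drop = FALSE]
    cen_rows[[p]] <- data.frame(phase = p, segment = c("head", "body", "tail"),
                                LL = cen[, 1], AP = cen[, 2], SI = cen[, 3])
  }
  structure(list(labels = labels,
                 centroids_mm = do.call(rbind, c(cen_rows, make.row.names = FALSE)),
                 init_centroids_mm = init_used,
                 spacing_mm = spacing_mm,
                 fits = fits),
            class = "segment_labels4d")
}

#' Extract the binary map of one structure from partition labels
#'
#' @param labels4d a [partition_4d()] result (or a list of label arrays)
#' @param structure one of `"pancreas"`, `"head"`, `"body"`, `"tail"`
#' @return list of logical arrays, one per phase
#' @export
structure_masks <- function(labels4d, structure = STRUCTURES) {
  structure <- match.arg(structure)
  labs <- if (inherits(labels4d, "segment_labels4d")) labels4d$labels else labels4d
  code <- match(structure, c("head", "body", "tail"))
  lapply(labs, function(l) if (structure == "pancreas") l > 0L else l == code)
}
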