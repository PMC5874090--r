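# NIfTI and CSV entry points. Volumes are written one NIfTI file per phase
# with the voxel spacing in the header; dynamic series get a CSV sidecar.

#' Write a 4D mask (or any per-phase volume list) as per-phase NIfTI files
#'
#' @param masks list of 3D arrays (one per phase)
#' @param spacing_mm voxel size per axis (mm)
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix; files are `<prefix>_phase<p>.nii.gz`
#' @return invisible character vector of file paths
#' @export
write_mask4d <- function(masks, spacing_mm, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (p in seq_along(masks)) {
    img <- RNifti::asNifti(array(as.numeric(masks[[p]]), dim(masks[[p]])))
    RNifti::pixdim(img) <- spacing_mm
    paths[p] <- file.path(dir, sprintf("%s_phase%d.nii.gz", prefix, p))
    RNifti::writeNifti(img, paths[p])
  }
  invisible(paths)
}

#' Read a 4D mask from per-phase NIfTI files
#'
#' Validates that all phases share geometry (dimensions and voxel spacing)
#' and that every volume is binary (values 0/1 only).
#'
#' @param paths character vector of NIfTI file paths, in phase order
#' @return list: `masks` (list of logical arrays), `spacing_mm`
#' @export
read_mask4d <- function(paths) {
  stopifnot(length(paths) >= 2)
  imgs <- lapply(paths, RNifti::readNifti)
  d1 <- dim(imgs[[1]])
  sp1 <- RNifti::pixdim(imgs[[1]])[1:3]
  bad_geom <- which(vapply(imgs, function(x)
    !identical(dim(x), d1) ||
      any(abs(RNifti::pixdim(x)[1:3] - sp1) > 1e-6), logical(1)))
  if (length(bad_geom))
    stop("geometry mismatch across phases in: ",
         paste(basename(paths[bad_geom]), collapse = ", "))
  for (i in seq_along(imgs)) {
    v <- unique(as.vector(imgs[[i]]))
    if (!all(v %in% c(0, 1)))
      stop("non-binary mask in ", basename(paths[i]),
           " (values: ", paste(utils::head(sort(v), 5), collapse = ", "), ")")
  }
  masks <- lapply(imgs, function(x) array(x != 0, dim(x)))
  validate_mask4d(masks, sp1)
  list(masks = masks, spacing_mm = sp1)
}

#' Write a dynamic slice series as a NIfTI stack plus CSV sidecar
#'
#' @param series a `dyn_series`
#' @param dir output directory
#' @param prefix file-name prefix
#' @return invisible list with `nifti` and `csv` paths
#' @export
write_dyn_series <- function(series, dir, prefix = "series") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d2 <- dim(series$images[[1]])
  stack <- array(0, c(d2, length(series$images)))
  for (i in seq_along(series$images)) stack[, , i] <- series$images[[i]]
  img <- RNifti::asNifti(stack)
  RNifti::pixdim(img) <- c(series$spacing_mm[1:2], 1)
  np <- file.path(dir, paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(img, np)
  cp <- file.path(dir, paste0(prefix, "_sidecar.csv"))
  utils::write.csv(series$meta, cp, row.names = FALSE)
  invisible(list(nifti = np, csv = cp))
}

#' Read a dynamic slice series written by [write_dyn_series()]
#'
#' @param nifti_path NIfTI stack path
#' @param csv_path sidecar CSV path
#' @param spacing_mm in-plane + slice voxel size (LL, AP, SI) in mm
#' @return a `dyn_series`
#' @export
read_dyn_series <- function(nifti_path, csv_path, spacing_mm) {
  stack <- RNifti::readNifti(nifti_path)
  meta <- utils::read.csv(csv_path)
  n <- dim(stack)[3]
  stopifnot(nrow(meta) == n)
  images <- lapply(seq_len(n), function(i) stack[, , i])
  structure(list(images = images, meta = meta, spacing_mm = spacing_mm,
                 n_slices = length(unique(meta$slice_index)),
                 n_measurements = max(meta$measurement),
                 slice_time_ms = stats::median(diff(sort(meta$time_ms)))),
            class = "dyn_series")
}
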