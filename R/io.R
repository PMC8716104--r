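#' Read and write package data files
#'
#' Plain-text interchange helpers: anatomical axes as JSON point lists
#' (as exported from surface-drawing tools), spatial profiles and beta maps
#' as TSV, and (when RNifti is available) beta maps as one NIfTI volume per
#' condition on the patch grid.
#'
#' @param path File path.
#' @param axis,profile,betas,patch Objects to write.
#' @name facegrad_io
NULL

#' @rdname facegrad_io
#' @export
read_axis_json <- function(path) {
  pts <- jsonlite::fromJSON(path)
  anatomical_axis(pts)
}

#' @rdname facegrad_io
#' @export
write_axis_json <- function(axis, path) {
  stopifnot(inherits(axis, "anatomical_axis"))
  jsonlite::write_json(
    unclass(as.matrix(axis[, c("x_mm", "y_mm")])), path, digits = NA
  )
  invisible(path)
}

#' @rdname facegrad_io
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname facegrad_io
#' @export
write_betamap_tsv <- function(betas, patch, path) {
  check_columns(betas, c("voxel", "condition", "beta"), "betas")
  wide <- tidyr::pivot_wider(betas[, c("voxel", "condition", "beta")],
                             names_from = "condition", values_from = "beta")
  out <- left_join(patch[, c("voxel", "x_mm", "y_mm")], wide, by = "voxel")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname facegrad_io
#' @param dir Output directory; one `<condition>.nii.gz` per condition.
#' @export
write_betamap_nifti <- function(betas, patch, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_facegrad("NIfTI output needs the RNifti package.",
                  "facegrad_missing_dependency")
  }
  check_columns(betas, c("voxel", "condition", "beta"), "betas")
  dims <- attr(patch, "dims")
  spacing <- attr(patch, "spacing_mm")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (cond in unique(betas$condition)) {
    vol <- array(NA_real_, dim = dims)
    sub <- betas[betas$condition == cond, ]
    idx <- match(sub$voxel, patch$voxel)
    vol[cbind(patch$row[idx], patch$col[idx], patch$slice[idx])] <- sub$beta
    img <- RNifti::asNifti(vol, pixdim = rep(spacing, 3))
    p <- file.path(dir, paste0(cond, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname facegrad_io
#' @export
read_betamap_nifti <- function(dir, patch) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_facegrad("NIfTI input needs the RNifti package.",
                  "facegrad_missing_dependency")
  }
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    cond <- sub("\\.nii(\\.gz)?$", "", basename(f))
    vol <- RNifti::readNifti(f)
    beta <- vol[cbind(patch$row, patch$col, patch$slice)]
    tibble(voxel = patch$voxel, condition = cond, beta = as.numeric(beta))
  })
  new_betamap(bind_rows(rows))
}
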