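#' 3D greyscale volume with physical voxel size
#'
#' Container for a micro-CT volume stored as an integer array with
#' dimensions `c(nz, ny, nx)`, where `z` is the slice index. Slices are
#' parallel to the chorionic plate and `z` increases from the chorionic
#' towards the basal plate, matching the acquisition convention.
#'
#' @param voxels 3D numeric/integer array, dimension `c(nz, ny, nx)`.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @param orientation free-text orientation tag.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size_um,
                         orientation = "slices parallel to chorionic plate; z chorionic -> basal") {
  if (length(dim(voxels)) != 3L) config_error("voxels must be a 3D array")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0) {
    config_error("voxel_size_um must be a positive number")
  }
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 orientation = orientation),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d slices of %d x %d, voxel %.4g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(" intensity range:", paste(range(x$voxels), collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Read a TIFF slice stack as a volume
#'
#' Reads all numbered 16-bit greyscale TIFF slices in a directory (sorted by
#' file name) into a [volume_image()]. The physical voxel size is taken from
#' the `stack.yaml` sidecar written by [write_stack()], or from the
#' `voxel_size_um` argument.
#'
#' @param path directory containing `slice_*.tif` files.
#' @param voxel_size_um voxel size override; required when no sidecar exists.
#' @return a [volume_image()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0L) data_error(paste0("no slices found in ", path))
  sidecar <- file.path(path, "stack.yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    voxel_size_um <- voxel_size_um %||% meta$voxel_size_um
  }
  if (is.null(voxel_size_um)) {
    data_error("missing scale metadata: no stack.yaml sidecar and no voxel_size_um given")
  }
  slices <- lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1] # tolerate greyscale saved with channels
    m
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    data_error("slice files do not share a common image size")
  }
  vox <- array(0L, c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) vox[z, , ] <- slices[[z]]
  storage.mode(vox) <- "integer"
  volume_image(vox, voxel_size_um)
}

#' Write a volume as a TIFF slice stack
#'
#' Writes one 16-bit greyscale TIFF per slice (`slice_0000.tif`, ...) plus a
#' `stack.yaml` sidecar holding the voxel size and orientation. The
#' write/read round trip is lossless for integer intensities in
#' \[0, 65535\].
#'
#' @param volume a [volume_image()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  vox <- volume$voxels
  if (min(vox) < 0 || max(vox) > 65535) {
    data_error("intensities outside the 16-bit range cannot be written")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(vox)[1]
  for (z in seq_len(nz)) {
    tiff::writeTIFF(vox[z, , ] / 65535,
                    file.path(path, sprintf("slice_%04d.tif", z - 1L)),
                    bits.per.sample = 16L, compression = "none")
  }
  yaml::write_yaml(list(voxel_size_um = volume$voxel_size_um,
                        orientation = volume$orientation,
                        n_slices = nz), file.path(path, "stack.yaml"))
  invisible(path)
}

#' Write / read a boolean mask as an 8-bit TIFF stack
#'
#' @param mask logical 3D array.
#' @param path directory.
#' @return `path` (writer) or the logical array (reader), invisibly/visibly.
#' @export
write_mask_stack <- function(mask, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(mask)[1]
  for (z in seq_len(nz)) {
    tiff::writeTIFF((mask[z, , ]) * 1.0,
                    file.path(path, sprintf("slice_%04d.tif", z - 1L)),
                    bits.per.sample = 8L, compression = "none")
  }
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0L) data_error(paste0("no slices found in ", path))
  slices <- lapply(files, function(f) tiff::readTIFF(f) > 0.5)
  vox <- array(FALSE, c(length(slices), nrow(slices[[1]]), ncol(slices[[1]])))
  for (z in seq_along(slices)) vox[z, , ] <- slices[[z]]
  vox
}
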