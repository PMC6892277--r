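#' Split a volume into labelled in-plane chunks
#'
#' Divides a volume into a `grid[1] x grid[2]` array of three-dimensional
#' chunks (full z extent each), the decomposition used to keep whole-placenta
#' stacks tractable. Each chunk carries a position label so that the pieces
#' can be recombined bit-exactly. Volumes whose in-plane size is not an
#' exact multiple of the grid are padded at the high edge with `pad_value`
#' (air); the padding is discarded again on merge. An optional halo extends
#' each chunk into its neighbours so that local morphological operations
#' computed chunk-wise agree with whole-volume results.
#'
#' @param volume a [volume_image()].
#' @param grid in-plane grid `c(rows, cols)`; default `c(10, 10)`.
#' @param halo halo width in voxels added on each in-plane side (clipped at
#'   the volume border). Default 7, the largest structuring radius used
#'   downstream (one more than the 6-voxel radius filter).
#' @param pad_value intensity used for edge padding.
#' @return a list of `volume_chunk` objects; attributes record the original
#'   dimensions, grid and voxel size.
#' @seealso [merge_chunks()]
#' @export
split_chunks <- function(volume, grid = c(10L, 10L), halo = 7L,
                         pad_value = 0L) {
  stopifnot(inherits(volume, "volume_image"))
  grid <- as.integer(grid)
  halo <- as.integer(halo)
  if (any(grid < 1L)) config_error("grid must have positive dimensions")
  if (halo < 0L) config_error("halo must be non-negative")
  d <- dim(volume$voxels)
  tile <- c(ceiling(d[2] / grid[1]), ceiling(d[3] / grid[2]))
  pd <- c(d[1], tile[1] * grid[1], tile[2] * grid[2])
  padded <- array(as.integer(pad_value), pd)
  padded[, seq_len(d[2]), seq_len(d[3])] <- volume$voxels

  # every chunk carries the grid metadata so that any subset or reordering
  # of the list can still be merged
  meta <- list(orig_dim = d, padded_dim = pd, grid = grid, tile = tile,
               halo = halo, voxel_size_um = volume$voxel_size_um,
               orientation = volume$orientation)
  chunks <- vector("list", prod(grid))
  k <- 0L
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      y0 <- (i - 1L) * tile[1] + 1L; y1 <- i * tile[1]
      x0 <- (j - 1L) * tile[2] + 1L; x1 <- j * tile[2]
      hy0 <- max(1L, y0 - halo); hy1 <- min(pd[2], y1 + halo)
      hx0 <- max(1L, x0 - halo); hx1 <- min(pd[3], x1 + halo)
      k <- k + 1L
      chunks[[k]] <- structure(list(
        label = sprintf("r%02dc%02d", i, j),
        row = i, col = j,
        core_y = c(y0, y1), core_x = c(x0, x1),
        halo_lo = c(y0 - hy0, x0 - hx0),
        voxels = padded[, hy0:hy1, hx0:hx1, drop = FALSE],
        meta = meta
      ), class = "volume_chunk")
    }
  }
  chunks
}

#' Recombine labelled chunks into a volume
#'
#' Places each chunk's core region (halos discarded) back at the position
#' encoded in its label; chunk order is irrelevant. `merge_chunks(split_chunks(v))`
#' reproduces `v` bit-exactly.
#'
#' @param chunks output of [split_chunks()] (possibly reordered).
#' @return a [volume_image()].
#' @export
merge_chunks <- function(chunks) {
  if (length(chunks) == 0L || is.null(chunks[[1]]$meta)) {
    data_error("chunks are missing their grid metadata")
  }
  meta <- chunks[[1]]$meta
  grid <- meta$grid
  pd <- meta$padded_dim
  d <- meta$orig_dim
  labels <- vapply(chunks, `[[`, "", "label")
  expected <- as.vector(outer(seq_len(grid[1]), seq_len(grid[2]),
                              function(i, j) sprintf("r%02dc%02d", i, j)))
  if (anyDuplicated(labels) || !setequal(labels, expected)) {
    data_error("inconsistent chunk labels: duplicates or missing positions")
  }
  out <- array(0L, pd)
  for (ch in chunks) {
    y0 <- ch$core_y[1]; y1 <- ch$core_y[2]
    x0 <- ch$core_x[1]; x1 <- ch$core_x[2]
    sy <- ch$halo_lo[1] + seq_len(y1 - y0 + 1L)
    sx <- ch$halo_lo[2] + seq_len(x1 - x0 + 1L)
    out[, y0:y1, x0:x1] <- ch$voxels[, sy, sx, drop = FALSE]
  }
  volume_image(out[, seq_len(d[2]), seq_len(d[3]), drop = FALSE],
               meta$voxel_size_um, meta$orientation)
}

#' Per-voxel region labels for the in-plane chunk grid
#'
#' Assigns every voxel the index of the chunk-grid cell it falls in,
#' providing the regional unit for coarse vascular density maps.
#'
#' @param d volume dimensions `c(nz, ny, nx)`.
#' @param grid in-plane grid `c(rows, cols)`.
#' @return integer array of region ids (1 .. prod(grid)).
#' @export
chunk_region_labels <- function(d, grid = c(10L, 10L)) {
  grid <- as.integer(grid)
  tile <- c(ceiling(d[2] / grid[1]), ceiling(d[3] / grid[2]))
  row2d <- pmin(grid[1], (matrix(seq_len(d[2]), d[2], d[3]) - 1L) %/% tile[1] + 1L)
  col2d <- pmin(grid[2], (matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE) - 1L) %/% tile[2] + 1L)
  lab2d <- (row2d - 1L) * grid[2] + col2d
  array(rep(as.integer(lab2d), each = d[1]), d)
}
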