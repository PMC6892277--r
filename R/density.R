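#' Regional vascular density map
#'
#' Vascular density of a region is the vessel voxel count divided by the
#' tissue voxel count (vessels are part of the tissue mask by
#' construction), as a percentage. Regions without tissue are flagged with
#' `NA` rather than zero.
#'
#' @param vessel_mask,tissue_mask congruent logical 3D arrays.
#' @param region_labels integer array of the same dimension assigning each
#'   voxel to a region (`0`/`NA` = outside all regions), e.g. from
#'   [chunk_region_labels()].
#' @return data frame `region, n_tissue, n_vessel, density_pct` covering
#'   every region id present in `region_labels`.
#' @export
density_map <- function(vessel_mask, tissue_mask, region_labels) {
  if (!identical(dim(vessel_mask), dim(tissue_mask)) ||
      !identical(dim(vessel_mask), dim(region_labels))) {
    config_error("masks and region labels must share dimensions")
  }
  regions <- sort(unique(region_labels[region_labels > 0]))
  nmax <- max(regions)
  n_t <- tabulate(region_labels[tissue_mask], nbins = nmax)
  n_v <- tabulate(region_labels[vessel_mask], nbins = nmax)
  out <- data.frame(region = regions,
                    n_tissue = n_t[regions],
                    n_vessel = n_v[regions])
  out$density_pct <- ifelse(out$n_tissue > 0,
                            100 * out$n_vessel / out$n_tissue, NA_real_)
  out
}

#' Regional density computed chunk-wise
#'
#' Computes the same per-region density map as [density_map()], but by
#' segmenting the volume one chunk at a time (with halos) and accumulating
#' counts over each chunk's core only; results are identical to
#' whole-volume processing while bounding memory by the chunk size.
#'
#' @param volume a [volume_image()].
#' @param thresholds a [threshold_pair()] (computed once for the whole
#'   volume, as thresholds are a per-placenta property).
#' @param grid,halo chunk grid passed to [split_chunks()].
#' @return data frame as in [density_map()], regions = chunk-grid cells.
#' @export
density_map_chunked <- function(volume, thresholds, grid = c(10L, 10L),
                                halo = 7L) {
  chunks <- split_chunks(volume, grid = grid, halo = halo, pad_value = 0L)
  grid <- chunks[[1]]$meta$grid
  res <- lapply(chunks, function(ch) {
    seg <- segment_volume(ch$voxels, thresholds)
    cy <- ch$halo_lo[1] + seq_len(ch$core_y[2] - ch$core_y[1] + 1L)
    cx <- ch$halo_lo[2] + seq_len(ch$core_x[2] - ch$core_x[1] + 1L)
    data.frame(region = (ch$row - 1L) * grid[2] + ch$col,
               n_tissue = sum(seg$tissue_mask[, cy, cx]),
               n_vessel = sum(seg$vessel_mask[, cy, cx]))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$region), ]
  rownames(out) <- NULL
  out$density_pct <- ifelse(out$n_tissue > 0,
                            100 * out$n_vessel / out$n_tissue, NA_real_)
  out
}

#' Radial vascular density profile
#'
#' Mean vascular density in each of 100 normalised-distance regions from
#' the cord insertion (bin 0) to the placental edge (bin 99). A voxel's bin
#' is the integer part of the normalised distance of its in-plane position
#' (bins are half-open `[b, b + 1)`; bin 99 includes 100). Bins containing
#' no tissue are flagged `NA`.
#'
#' @param vessel_mask,tissue_mask congruent logical 3D arrays.
#' @param geometry a [compute_distance_map()] result for the same in-plane
#'   extent.
#' @param placenta_id optional id attached to the output.
#' @return an object of class `density_profile`: data frame
#'   `bin, n_tissue, n_vessel, density_pct` with one row per bin 0-99.
#' @export
radial_profile <- function(vessel_mask, tissue_mask, geometry,
                           placenta_id = NA_character_) {
  stopifnot(inherits(geometry, "placenta_geometry"))
  d <- dim(tissue_mask)
  if (!identical(dim(vessel_mask), d)) {
    config_error("masks must share dimensions")
  }
  if (!identical(dim(geometry$norm), d[2:3])) {
    config_error("geometry does not match the in-plane extent of the masks")
  }
  bin2d <- floor(geometry$norm)
  bin2d[bin2d > 99] <- 99
  bin3d <- rep(as.vector(bin2d), each = d[1])
  t_idx <- as.vector(tissue_mask)
  v_idx <- as.vector(vessel_mask)
  usable_t <- t_idx & !is.na(bin3d)
  usable_v <- v_idx & !is.na(bin3d)
  n_t <- tabulate(bin3d[usable_t] + 1L, nbins = 100L)
  n_v <- tabulate(bin3d[usable_v] + 1L, nbins = 100L)
  out <- data.frame(bin = 0:99, n_tissue = n_t, n_vessel = n_v)
  out$density_pct <- ifelse(out$n_tissue > 0,
                            100 * out$n_vessel / out$n_tissue, NA_real_)
  attr(out, "placenta_id") <- placenta_id
  attr(out, "n_outside_geometry") <- sum(t_idx & is.na(bin3d))
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Global vascular density of a masked volume
#'
#' @param vessel_mask,tissue_mask logical arrays.
#' @return density as a percentage.
#' @export
global_density <- function(vessel_mask, tissue_mask) {
  n_t <- sum(tissue_mask)
  if (n_t == 0L) return(NA_real_)
  100 * sum(vessel_mask) / n_t
}

#' Block-level vascular density in the basal-third region of interest
#'
#' For a tissue-block volume (fine-scale imaging), restricts the analysis
#' to the bottom third of the tissue extent along z - the basal side, where
#' the villous vascular tree lies - and computes the vascular density as
#' vessel volume over tissue-plus-vessel volume, as a percentage. The ROI
#' is derived from the tissue bounding extent along z, a deterministic
#' surrogate for the manually drawn region.
#'
#' @param block_volume a [volume_image()] of one tissue block (z increasing
#'   towards the basal plate).
#' @param thresholds a [threshold_pair()]; when `NULL`, thresholds are
#'   found from the block's own histogram.
#' @param roi_fraction fraction of the tissue z-extent kept at the basal
#'   end (default 1/3).
#' @return list with `vessel_volume_vox`, `tissue_volume_vox`,
#'   `density_pct`, `roi_slices` and the thresholds used.
#' @export
block_density <- function(block_volume, thresholds = NULL,
                          roi_fraction = 1 / 3) {
  if (is.null(thresholds)) thresholds <- find_thresholds(block_volume)
  seg <- segment_volume(block_volume, thresholds)
  zs <- which(apply(seg$tissue_mask, 1, any))
  if (length(zs) < 3L) data_error("tissue occupies fewer than 3 slices")
  extent <- max(zs) - min(zs) + 1L
  n_roi <- max(1L, floor(extent * roi_fraction))
  roi <- (max(zs) - n_roi + 1L):max(zs)
  n_t <- sum(seg$tissue_mask[roi, , ])
  n_v <- sum(seg$vessel_mask[roi, , ])
  list(vessel_volume_vox = n_v,
       tissue_volume_vox = n_t,
       density_pct = if (n_t > 0) 100 * n_v / n_t else NA_real_,
       roi_slices = roi,
       thresholds = thresholds)
}

#' Sample block-style local densities across a segmented placenta
#'
#' Emulates the block-sampling design: extracts `n_blocks` cubic
#' subvolumes at random in-plane positions within the placenta, computes
#' the local vascular density of each, and records the normalised location
#' of the block centre from the supplied geometry. Used to study the
#' density-versus-location relationship.
#'
#' @param vessel_mask,tissue_mask segmented masks of the whole volume.
#' @param geometry a [compute_distance_map()] result.
#' @param n_blocks number of blocks to sample.
#' @param half_size half edge length of the in-plane block extent, voxels.
#' @param min_separation minimum in-plane distance between block centres,
#'   voxels; tissue blocks are physically distinct pieces, so sampled
#'   blocks must not overlap (default four block half-widths).
#' @param seed RNG seed for the block positions.
#' @return data frame `block, normalised_location, density_pct`.
#' @export
sample_block_densities <- function(vessel_mask, tissue_mask, geometry,
                                   n_blocks = 80L, half_size = 6L,
                                   min_separation = 4L * half_size,
                                   seed = 1L) {
  d <- dim(tissue_mask)
  norm <- geometry$norm
  candidates <- which(!is.na(norm) & norm >= 5 & norm <= 95, arr.ind = TRUE)
  if (nrow(candidates) < n_blocks) data_error("mask too small to sample blocks")
  with_seed(seed, {
    ord <- sample(nrow(candidates))
    pick <- matrix(0L, 0L, 2L)
    for (i in ord) {
      p <- candidates[i, ]
      if (nrow(pick) &&
          min((pick[, 1] - p[1])^2 + (pick[, 2] - p[2])^2) <
            min_separation^2) next
      pick <- rbind(pick, p)
      if (nrow(pick) == n_blocks) break
    }
    if (nrow(pick) < n_blocks) {
      data_error("could not place the requested number of separated blocks")
    }
    out <- data.frame(block = seq_len(n_blocks),
                      normalised_location = norm[pick],
                      density_pct = NA_real_)
    for (b in seq_len(n_blocks)) {
      ys <- max(1L, pick[b, 1] - half_size):min(d[2], pick[b, 1] + half_size)
      xs <- max(1L, pick[b, 2] - half_size):min(d[3], pick[b, 2] + half_size)
      n_t <- sum(tissue_mask[, ys, xs])
      if (n_t > 0) out$density_pct[b] <- 100 * sum(vessel_mask[, ys, xs]) / n_t
    }
    out
  })
}

#' Plot a radial density profile
#'
#' Convenience base-graphics plot of mean vascular density against
#' normalised distance from the cord insertion.
#'
#' @param x a [radial_profile()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$bin, x$density_pct, type = "l",
                 xlab = "normalised distance from cord insertion",
                 ylab = "vascular density (%)", ...)
  invisible(x)
}
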