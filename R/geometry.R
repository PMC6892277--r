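#' Maximum intensity projection along the stack axis
#'
#' @param volume a [volume_image()] or 3D array.
#' @return matrix of per-pixel maxima over all slices.
#' @export
max_intensity_projection <- function(volume) {
  vox <- if (inherits(volume, "volume_image")) volume$voxels else volume
  d <- dim(vox)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) {
    data_error("projection needs a non-empty 3D volume")
  }
  out <- vox[1, , ]
  for (z in seq_len(d[1])[-1]) out <- pmax(out, vox[z, , ])
  out
}

#' Cord-centred normalised distance map
#'
#' Measures the pixel distance from the cord insertion point to the
#' placental edge through 360 degrees and normalises every in-mask pixel's
#' radial distance against the edge distance of its angular sector. Each
#' in-mask pixel is assigned to the nearest of `n_rays` equally spaced
#' sectors around the cord point; the edge distance of a sector is the
#' radial distance of the outermost in-mask pixel within the sector and
#' its two neighbours (at 1-degree spacing a sector's own arc is narrower
#' than one pixel near the edge, so the one-sector window closes lattice
#' gaps), and non-convex masks therefore use the outermost crossing - the
#' true placental edge. The outermost pixel of each window maps to exactly
#' 100; normalised distances run from 0 at the cord insertion to 100 at
#' the edge.
#'
#' @param mask logical matrix (planar placenta mask, typically thresholded
#'   from a maximum intensity projection; should be free of stray
#'   foreground specks, which would inflate their sector's edge distance).
#' @param cord_point `c(y, x)` cord insertion pixel; must lie inside the mask.
#' @param n_rays number of angular sectors (default 360, i.e. 1 degree).
#' @return an object of class `placenta_geometry`: list with `mask`,
#'   `cord_point`, `norm` (matrix of normalised distances, `NA` outside the
#'   mask), `edge_dist_px` (per-sector edge distances) and `n_rays`.
#' @export
compute_distance_map <- function(mask, cord_point, n_rays = 360L) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    config_error("mask must be a logical matrix")
  }
  cy <- cord_point[1]; cx <- cord_point[2]
  ny <- nrow(mask); nx <- ncol(mask)
  ry <- round(cy); rx <- round(cx)
  if (ry < 1 || ry > ny || rx < 1 || rx > nx || !mask[ry, rx]) {
    data_error("cord point lies outside the placenta mask")
  }
  pix <- which(mask, arr.ind = TRUE)
  dy <- pix[, 1] - cy
  dx <- pix[, 2] - cx
  r <- sqrt(dy^2 + dx^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  sector <- (round(ang / (2 * pi / n_rays)) %% n_rays) + 1L
  edge <- rep(0, n_rays)
  mx <- tapply(r, sector, max)
  edge[as.integer(names(mx))] <- mx
  if (any(edge <= 0)) {
    occupied <- which(edge > 0)
    if (length(occupied) < n_rays / 2) {
      data_error("mask has zero-length rays: the edge touches the cord point")
    }
    # sparse sectors (tiny masks): borrow the nearest occupied sector
    for (k in which(edge <= 0)) {
      delta <- pmin(abs(occupied - k), n_rays - abs(occupied - k))
      edge[k] <- edge[occupied[which.min(delta)]]
    }
  }
  # outermost pixel within the sector and its neighbours (circular)
  edge <- pmax(edge, edge[c(n_rays, seq_len(n_rays - 1L))],
               edge[c(seq_len(n_rays)[-1L], 1L)])
  norm <- matrix(NA_real_, ny, nx)
  norm[pix] <- pmin(100, 100 * r / edge[sector])
  structure(list(mask = mask, cord_point = c(cy, cx), norm = norm,
                 edge_dist_px = edge, n_rays = n_rays),
            class = "placenta_geometry")
}

#' @export
print.placenta_geometry <- function(x, ...) {
  cat(sprintf("<placenta_geometry> %d x %d mask, cord at (%.1f, %.1f), %d rays\n",
              nrow(x$mask), ncol(x$mask), x$cord_point[1], x$cord_point[2],
              x$n_rays))
  cat(sprintf(" edge distance: %.1f - %.1f px\n",
              min(x$edge_dist_px), max(x$edge_dist_px)))
  invisible(x)
}

#' Normalised block location between cord insertion and placental edge
#'
#' The location of a tissue block is expressed as the distance from the
#' cord insertion to the block centre divided by the distance from the cord
#' insertion to the placental edge through the block, times 100 (0 = at the
#' cord, 100 = at the edge). Both distances are measured on the chorionic
#' plate photograph, in mm.
#'
#' @param d_block_mm cord-to-block distance(s), mm.
#' @param d_edge_mm cord-to-edge distance(s) through the block, mm.
#' @return normalised location(s) in \[0, 100\].
#' @export
normalise_block_location <- function(d_block_mm, d_edge_mm) {
  if (any(d_edge_mm <= 0)) config_error("cord-to-edge distance must be positive")
  if (any(d_block_mm < 0) || any(d_block_mm > d_edge_mm)) {
    config_error("cord-to-block distance must lie in [0, cord-to-edge distance]")
  }
  100 * d_block_mm / d_edge_mm
}
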