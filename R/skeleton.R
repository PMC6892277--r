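#' Skeletonise a vessel mask
#'
#' Reduces a binary 3D vessel mask to a one-voxel-wide centred medial curve
#' by distance-ordered homotopic thinning: voxels are visited in increasing
#' order of Euclidean distance to the background and removed when removal
#' preserves digital topology (26-connectivity for vessels, 6 for
#' background) and the voxel is not a curve endpoint. Connected components
#' of the mask therefore map to connected skeleton components, and
#' re-skeletonising a skeleton leaves it unchanged.
#'
#' @param vessel_mask logical 3D array.
#' @return an object of class `vessel_skeleton`: list with `coords`
#'   (integer matrix with columns `z, y, x`), `component_id`, `dim`, and -
#'   after [measure_radius()] - `radius_vox` / `radius_um`. An empty mask
#'   yields an empty skeleton.
#' @export
skeletonise <- function(vessel_mask) {
  d <- dim(vessel_mask)
  if (length(d) != 3L) config_error("vessel_mask must be a 3D logical array")
  if (!any(vessel_mask)) {
    return(structure(list(coords = matrix(integer(0), 0, 3,
                                          dimnames = list(NULL, c("z", "y", "x"))),
                          component_id = integer(0), dim = d,
                          radius_vox = NULL, radius_um = NULL,
                          voxel_size_um = NULL),
                     class = "vessel_skeleton"))
  }
  edt <- cpp_edt(vessel_mask, d)
  skel <- cpp_skeletonize(as.logical(vessel_mask), d, edt)
  dim(skel) <- d
  coords <- which(skel, arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  lab <- cpp_label26(skel, d)
  structure(list(coords = coords,
                 component_id = lab[coords],
                 dim = d, radius_vox = NULL, radius_um = NULL,
                 voxel_size_um = NULL),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d centreline voxels in %d component(s)\n",
              nrow(x$coords), length(unique(x$component_id))))
  if (!is.null(x$radius_vox) && length(x$radius_vox)) {
    cat(sprintf(" radius: median %.2f vox (range %.2f - %.2f)\n",
                median(x$radius_vox), min(x$radius_vox), max(x$radius_vox)))
  }
  invisible(x)
}

skeleton_linear_idx <- function(skel) {
  d <- skel$dim
  skel$coords[, 1] + d[1] * (skel$coords[, 2] - 1L) +
    d[1] * d[2] * (skel$coords[, 3] - 1L)
}

#' Measure the vessel radius along the skeleton
#'
#' The radius at each centreline voxel is its Euclidean distance to the
#' boundary of the thresholded vessel mask (the Euclidean distance
#' transform of the mask evaluated on the centreline).
#'
#' @param skeleton a [skeletonise()] result.
#' @param vessel_mask the mask the skeleton was derived from.
#' @param voxel_size_um optional isotropic voxel size; when given, radii are
#'   also reported in micrometres.
#' @return the skeleton with `radius_vox` (and `radius_um`) filled in.
#' @export
measure_radius <- function(skeleton, vessel_mask, voxel_size_um = NULL) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  if (nrow(skeleton$coords) == 0L) {
    skeleton$radius_vox <- numeric(0)
    if (!is.null(voxel_size_um)) skeleton$radius_um <- numeric(0)
    return(skeleton)
  }
  if (!all(vessel_mask[skeleton$coords])) {
    data_error("skeleton voxels are not contained in the vessel mask")
  }
  edt <- cpp_edt(vessel_mask, dim(vessel_mask))
  skeleton$radius_vox <- as.numeric(edt[skeleton$coords])
  if (!is.null(voxel_size_um)) {
    skeleton$radius_um <- skeleton$radius_vox * voxel_size_um
    skeleton$voxel_size_um <- voxel_size_um
  }
  skeleton
}

#' Remove short spur branches from a skeleton
#'
#' Deletes terminal branches (endpoint to nearest junction) shorter than
#' `min_length` voxels; boundary roughness of the mask otherwise leaves
#' spurious short twigs on the centreline.
#'
#' @param skeleton a [skeletonise()] result.
#' @param min_length spurs strictly shorter than this many voxels are removed.
#' @return the pruned skeleton (radii, if present, are subset accordingly).
#' @export
prune_skeleton <- function(skeleton, min_length = 5L) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  n <- nrow(skeleton$coords)
  if (n == 0L || min_length <= 1L) return(skeleton)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  keep <- rep(TRUE, n)
  coords <- skeleton$coords
  index <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(key(coords[i, , drop = FALSE]), i, envir = index)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  neighbours <- function(i) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    ids <- integer(0)
    for (r in seq_len(nrow(nb))) {
      k <- paste(nb[r, 1], nb[r, 2], nb[r, 3])
      j <- index[[k]]
      if (!is.null(j) && keep[j]) ids <- c(ids, j)
    }
    ids
  }
  repeat {
    removed <- FALSE
    degree <- vapply(seq_len(n), function(i) if (keep[i]) length(neighbours(i)) else -1L, integer(1))
    for (e in which(degree == 1L)) {
      if (!keep[e]) next
      path <- e
      prev <- -1L
      cur <- e
      repeat {
        nb <- setdiff(neighbours(cur), prev)
        if (length(nb) != 1L) break
        prev <- cur
        cur <- nb
        if (length(neighbours(cur)) > 2L) break # reached a junction
        path <- c(path, cur)
        if (length(path) >= min_length) break
      }
      if (length(path) < min_length && length(neighbours(cur)) > 2L) {
        keep[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skeleton$coords <- skeleton$coords[keep, , drop = FALSE]
  skeleton$component_id <- skeleton$component_id[keep]
  if (!is.null(skeleton$radius_vox)) skeleton$radius_vox <- skeleton$radius_vox[keep]
  if (!is.null(skeleton$radius_um)) skeleton$radius_um <- skeleton$radius_um[keep]
  skeleton
}

#' Exclude large (chorionic-scale) vessels from a mask
#'
#' Removes from the vessel mask all voxels whose local radius exceeds the
#' threshold; at the whole-placenta voxel size of 116.5 um the default
#' 6-voxel radius corresponds to roughly 700 um, separating chorionic and
#' stem vessels from the villous tree. Each mask voxel inherits the radius
#' of its nearest centreline voxel.
#'
#' @param vessel_mask logical 3D array.
#' @param skeleton a skeleton with measured radii ([measure_radius()]).
#' @param radius_threshold_vox exclusion threshold in voxels (> 0).
#' @return the filtered mask (always a subset of the input mask).
#' @export
exclude_large_vessels <- function(vessel_mask, skeleton,
                                  radius_threshold_vox = 6) {
  if (radius_threshold_vox <= 0) {
    config_error("radius_threshold_vox must be positive")
  }
  if (!any(vessel_mask)) return(vessel_mask)
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  if (is.null(skeleton$radius_vox)) {
    config_error("skeleton has no radii; run measure_radius() first")
  }
  if (nrow(skeleton$coords) == 0L) return(vessel_mask)
  d <- dim(vessel_mask)
  seed_idx <- skeleton_linear_idx(skeleton)
  nearest <- cpp_nearest_seed(as.integer(seed_idx), d)
  mask_idx <- which(vessel_mask)
  inherited <- skeleton$radius_vox[match(nearest[mask_idx], seed_idx)]
  out <- vessel_mask
  out[mask_idx[inherited > radius_threshold_vox]] <- FALSE
  out
}

#' Skeleton as a data frame
#'
#' @param skeleton a [skeletonise()] result (radii optional).
#' @return data frame `z, y, x, radius_vox, radius_um, component_id`.
#' @export
skeleton_to_df <- function(skeleton) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  data.frame(
    z = skeleton$coords[, 1], y = skeleton$coords[, 2],
    x = skeleton$coords[, 3],
    radius_vox = skeleton$radius_vox %||% rep(NA_real_, nrow(skeleton$coords)),
    radius_um = skeleton$radius_um %||% rep(NA_real_, nrow(skeleton$coords)),
    component_id = skeleton$component_id
  )
}
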