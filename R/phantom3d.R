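#' Specify a 3D placental volume phantom
#'
#' Builds the parameter set for [generate_volume_phantom()]. The phantom
#' emulates a contrast-perfused placenta imaged as an axial micro-CT stack:
#' a disc of tissue oriented with slices parallel to the chorionic plate,
#' a bright branching vessel tree rooted on the chorionic face near a cord
#' insertion point, a controllable fraction of unperfused terminal segments
#' (rendered at tissue intensity, hence invisible to thresholding, like
#' vessels the casting agent failed to reach), and an optional radial
#' gradient in tree placement density.
#'
#' @param shape integer vector `c(nz, ny, nx)`; slices are the first index.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param disc_radius_vox,disc_thickness_vox tissue disc geometry in voxels.
#' @param cord_point in-plane cord insertion coordinate `c(y, x)`;
#'   default is the disc centre.
#' @param n_trees number of stem-tree roots seeded on the chorionic face.
#' @param branch_generations branching depth; `0` renders each tree as a
#'   single straight axial segment (useful for analytic checks).
#' @param root_radius_vox stem segment radius in voxels (must be >= 1).
#' @param root_length_vox length of the straight segment when
#'   `branch_generations = 0`; default 80\% of the disc thickness.
#' @param taper radius multiplier per generation, in (0, 1).
#' @param fill_fraction fraction of terminal segments that carry contrast,
#'   in \[0, 1\].
#' @param density_gradient radial modulation of tree placement density in
#'   \[-1, 1\]; 0 is homogeneous, positive values thin the periphery.
#' @param target_density optional target global vascular density (fraction,
#'   e.g. 0.05); trees are added beyond `n_trees` until the rendered
#'   perfused-vessel volume fraction reaches it.
#' @param grey_levels named intensities `c(air, tissue, contrast)` on the
#'   16-bit scale; must be strictly increasing.
#' @param noise_sd additive Gaussian noise SD; default 10\% of the
#'   tissue-air gap, small enough to keep the histogram modes separable.
#' @param seed integer seed; output is bit-identical for a fixed spec.
#'
#' @return an object of class `phantom_spec_3d`.
#' @seealso [generate_volume_phantom()]
#' @export
phantom_spec_3d <- function(shape = c(40L, 160L, 160L),
                            voxel_size_um = 116.5,
                            disc_radius_vox = 72,
                            disc_thickness_vox = 32,
                            cord_point = NULL,
                            n_trees = 48,
                            branch_generations = 3,
                            root_radius_vox = 1.8,
                            root_length_vox = NULL,
                            taper = 0.8,
                            fill_fraction = 1,
                            density_gradient = 0,
                            target_density = NULL,
                            grey_levels = c(air = 8000, tissue = 26000,
                                            contrast = 52000),
                            noise_sd = NULL,
                            seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    config_error("shape must be c(nz, ny, nx) with all dims >= 4")
  }
  if (length(grey_levels) != 3L || !all(diff(unname(grey_levels)) > 0)) {
    config_error("grey_levels must be three increasing intensities (air < tissue < contrast)")
  }
  if (root_radius_vox < 1) config_error("root_radius_vox must be >= 1")
  if (root_radius_vox >= disc_thickness_vox) {
    config_error("vessels cannot fit inside the disc: root radius >= disc thickness")
  }
  if (fill_fraction < 0 || fill_fraction > 1) {
    config_error("fill_fraction must lie in [0, 1]")
  }
  if (taper <= 0 || taper >= 1) config_error("taper must lie in (0, 1)")
  if (abs(density_gradient) > 1) {
    config_error("density_gradient must lie in [-1, 1]")
  }
  if (disc_radius_vox > min(shape[2:3]) / 2 - 1) {
    config_error("disc does not fit in the in-plane field of view")
  }
  if (disc_thickness_vox > shape[1] - 2) {
    config_error("disc thicker than the stack")
  }
  if (is.null(cord_point)) {
    cord_point <- c(round((shape[2] + 1) / 2), round((shape[3] + 1) / 2))
  }
  if (is.null(noise_sd)) {
    noise_sd <- 0.1 * (grey_levels[["tissue"]] - grey_levels[["air"]])
  }
  structure(list(
    shape = shape, voxel_size_um = voxel_size_um,
    disc_radius_vox = disc_radius_vox,
    disc_thickness_vox = disc_thickness_vox,
    cord_point = cord_point, n_trees = n_trees,
    branch_generations = as.integer(branch_generations),
    root_radius_vox = root_radius_vox, root_length_vox = root_length_vox,
    taper = taper, fill_fraction = fill_fraction,
    density_gradient = density_gradient, target_density = target_density,
    grey_levels = unname(grey_levels), noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec_3d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unit <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation of v around unit axis u by angle a
rotate_about <- function(v, u, a) {
  v * cos(a) + pracma_cross(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# linear voxel indices of a capsule (cylinder with spherical caps) between
# p0 and p1 (numeric (z,y,x), 1-based voxel centres) with radius r
capsule_indices <- function(dim, p0, p1, r) {
  lo <- pmax(1, floor(pmin(p0, p1) - r))
  hi <- pmin(dim, ceiling(pmax(p0, p1) + r))
  if (any(lo > hi)) return(integer(0))
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  g <- expand.grid(z = zs, y = ys, x = xs, KEEP.OUT.ATTRS = FALSE)
  d <- p1 - p0
  L2 <- sum(d^2)
  if (L2 == 0) {
    t <- 0
  } else {
    t <- ((g$z - p0[1]) * d[1] + (g$y - p0[2]) * d[2] + (g$x - p0[3]) * d[3]) / L2
    t <- pmin(1, pmax(0, t))
  }
  dist2 <- (g$z - (p0[1] + t * d[1]))^2 +
    (g$y - (p0[2] + t * d[2]))^2 +
    (g$x - (p0[3] + t * d[3]))^2
  keep <- dist2 <= r^2
  g$z[keep] + dim[1] * (g$y[keep] - 1L) + dim[1] * dim[2] * (g$x[keep] - 1L)
}

# grow one tree by recursive midpoint branching; returns a list of segments
# (p0, p1, r, terminal) in voxel coordinates (z, y, x)
grow_tree <- function(root_yx, spec, disc) {
  segs <- list()
  root <- c(disc$z0 + 0.5, root_yx[1], root_yx[2])
  if (spec$branch_generations == 0L) {
    len <- spec$root_length_vox %||% (0.8 * spec$disc_thickness_vox)
    return(list(list(p0 = root, p1 = root + c(len, 0, 0),
                     r = spec$root_radius_vox, terminal = TRUE)))
  }
  len0 <- 0.35 * spec$disc_thickness_vox
  clamp_dir <- function(dir) {
    # keep growth heading towards the basal plate; lateral drift is free
    # (out-of-disc voxels are simply clipped by the tissue mask)
    if (dir[1] < 0.05) dir[1] <- 0.05
    unit(dir)
  }
  recurse <- function(p0, dir, gen) {
    len <- len0 * 0.75^gen * runif(1, 0.8, 1.2)
    r <- spec$root_radius_vox * spec$taper^gen
    dir <- clamp_dir(dir)
    p1 <- p0 + len * dir
    p1[1] <- min(p1[1], disc$z1 - 0.5)
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, r = r,
                                       terminal = gen == spec$branch_generations - 1L)
    if (gen >= spec$branch_generations - 1L) return(invisible())
    theta <- runif(1, 25, 50) * pi / 180
    perp <- pracma_cross(dir, unit(rnorm(3)))
    if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma_cross(dir, c(0, 1, 0))
    perp <- unit(perp)
    recurse(p1, unit(rotate_about(dir, perp, theta)), gen + 1L)
    recurse(p1, unit(rotate_about(dir, perp, -theta)), gen + 1L)
    invisible()
  }
  recurse(root, unit(c(1, rnorm(2, 0, 0.25))), 0L)
  segs
}

# analytic distance from `cord` to the edge of a circular disc of radius R
# centred at `centre`, along in-plane unit directions (ey, ex); vectorised
disc_edge_distance <- function(cord, centre, R, ey, ex) {
  v <- cord - centre
  ve <- v[1] * ey + v[2] * ex
  disc2 <- ve^2 - (sum(v^2) - R^2)
  -ve + sqrt(pmax(0, disc2))
}

#' Generate a 3D placental volume phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec_3d()] and returns both
#' the greyscale volume (16-bit intensities) and voxel-exact ground truth:
#' tissue and perfused-vessel masks, centreline samples with true radii, the
#' analytic cord-normalised distance of every in-plane position, and the
#' true vascular density per normalised-distance bin.
#'
#' @param spec a [phantom_spec_3d()].
#' @return a list with elements `volume` (a [volume_image()]) and `truth`, a
#'   list holding `tissue_mask`, `vessel_mask` (perfused voxels only),
#'   `centreline` (data frame `z, y, x, radius_vox, radius_um`),
#'   `norm_distance_2d` (matrix, `NA` outside the disc),
#'   `density_by_bin` (data frame `bin, n_tissue, n_vessel, density_pct`),
#'   `global_density_pct`, `cord_point` and `n_segments`.
#' @export
generate_volume_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_3d"))
  dim3 <- spec$shape
  nz <- dim3[1]; ny <- dim3[2]; nx <- dim3[3]
  cy <- round((ny + 1) / 2); cx <- round((nx + 1) / 2)
  R <- spec$disc_radius_vox
  z0 <- floor((nz - spec$disc_thickness_vox) / 2) + 1L
  z1 <- z0 + as.integer(spec$disc_thickness_vox) - 1L
  disc <- list(cy = cy, cx = cx, R = R, z0 = z0, z1 = z1)

  # tissue disc
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  in_disc2d <- (yy - cy)^2 + (xx - cx)^2 <= R^2
  tissue_mask <- array(FALSE, dim3)
  tissue_mask[z0:z1, , ] <- rep(as.vector(in_disc2d), each = z1 - z0 + 1L)
  n_tissue <- sum(tissue_mask)

  perfused <- array(FALSE, dim3)
  centreline <- list()

  with_seed(spec$seed, {
    sample_root <- function() {
      # area-weighted radius modulated by the density gradient. Roots are
      # sampled on a disc enlarged by the expected lateral tree extent
      # (plus-sampling): trees rooted just outside the tissue reach in and
      # compensate the volume that edge-rooted trees lose to clipping, so
      # a zero gradient yields a radially stationary vessel density.
      margin <- if (spec$branch_generations == 0L) {
        -0.3 * R # straight axial tree: keep it fully inside the disc
      } else {
        0.5 * spec$disc_thickness_vox
      }
      rmax <- R + margin
      repeat {
        r <- rmax * sqrt(runif(1))
        w <- 1 - spec$density_gradient * min(r / R, 1)
        wmax <- max(1 - spec$density_gradient, 1)
        if (runif(1) <= w / wmax) break
      }
      a <- runif(1, 0, 2 * pi)
      c(cy + r * sin(a), cx + r * cos(a))
    }
    render_tree <- function() {
      segs <- grow_tree(sample_root(), spec, disc)
      term <- which(vapply(segs, `[[`, TRUE, "terminal"))
      n_perf <- round(spec$fill_fraction * length(term))
      perf_term <- if (n_perf > 0) term[sample(length(term), n_perf)] else integer(0)
      for (i in seq_along(segs)) {
        s <- segs[[i]]
        is_perf <- !s$terminal || i %in% perf_term
        if (!is_perf) next
        idx <- capsule_indices(dim3, s$p0, s$p1, s$r)
        idx <- idx[tissue_mask[idx]]
        perfused[idx] <<- TRUE
        # centreline samples at ~unit spacing
        len <- sqrt(sum((s$p1 - s$p0)^2))
        ts <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
        pts <- t(vapply(ts, function(t) s$p0 + t * (s$p1 - s$p0), numeric(3)))
        centreline[[length(centreline) + 1L]] <<-
          cbind(round(pts), radius_vox = s$r)
      }
    }
    n_grown <- 0L
    for (i in seq_len(spec$n_trees)) {
      render_tree(); n_grown <- n_grown + 1L
    }
    if (!is.null(spec$target_density)) {
      while (sum(perfused) / n_tissue < spec$target_density && n_grown < 500L) {
        render_tree(); n_grown <- n_grown + 1L
      }
    }

    g <- spec$grey_levels
    vol <- array(g[1], dim3)
    vol[tissue_mask] <- g[2]
    vol[perfused] <- g[3]
    if (spec$noise_sd > 0) {
      vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
    }
    vol <- pmin(65535, pmax(0, round(vol)))
    storage.mode(vol) <- "integer"
    dim(vol) <- dim3
    vol
  }) -> voxels

  # analytic normalised distance of each in-plane position from the cord
  cord <- spec$cord_point
  dy <- yy - cord[1]; dx <- xx - cord[2]
  r2d <- sqrt(dy^2 + dx^2)
  norm2d <- matrix(NA_real_, ny, nx)
  px <- which(in_disc2d)
  e_y <- ifelse(r2d[px] > 0, dy[px] / r2d[px], 0)
  e_x <- ifelse(r2d[px] > 0, dx[px] / r2d[px], 1)
  edge <- disc_edge_distance(cord, c(cy, cx), R, e_y, e_x)
  norm2d[px] <- pmin(100, 100 * r2d[px] / pmax(edge, .Machine$double.eps))

  # true density per normalised-distance bin (brute-force voxel counts)
  bin2d <- matrix(NA_integer_, ny, nx)
  bin2d[px] <- pmin(99L, as.integer(floor(norm2d[px])))
  vessel_cols <- colSums(matrix(perfused, nz, ny * nx))
  dim(vessel_cols) <- c(ny, nx)
  thick <- z1 - z0 + 1L
  n_t <- tapply(rep(thick, length(px)), bin2d[px], sum)
  n_v <- tapply(vessel_cols[px], bin2d[px], sum)
  bins <- data.frame(bin = 0:99, n_tissue = 0, n_vessel = 0)
  bins$n_tissue[as.integer(names(n_t)) + 1L] <- as.vector(n_t)
  bins$n_vessel[as.integer(names(n_v)) + 1L] <- as.vector(n_v)
  bins$density_pct <- ifelse(bins$n_tissue > 0,
                             100 * bins$n_vessel / bins$n_tissue, NA_real_)

  cl <- do.call(rbind, centreline)
  cl_df <- if (is.null(cl)) {
    data.frame(z = integer(0), y = integer(0), x = integer(0),
               radius_vox = numeric(0), radius_um = numeric(0))
  } else {
    df <- data.frame(z = cl[, 1], y = cl[, 2], x = cl[, 3],
                     radius_vox = cl[, 4])
    df <- df[!duplicated(df[, 1:3]) & df$z >= 1 & df$z <= nz &
               df$y >= 1 & df$y <= ny & df$x >= 1 & df$x <= nx, ]
    df$radius_um <- df$radius_vox * spec$voxel_size_um
    df
  }

  list(
    volume = volume_image(voxels, spec$voxel_size_um),
    truth = list(
      tissue_mask = tissue_mask,
      vessel_mask = perfused,
      centreline = cl_df,
      norm_distance_2d = norm2d,
      density_by_bin = bins,
      global_density_pct = 100 * sum(perfused) / n_tissue,
      cord_point = cord,
      disc = disc,
      n_segments = length(centreline),
      spec = spec
    )
  )
}

#' Write a 3D phantom and its ground truth to disk
#'
#' Writes the greyscale volume as a numbered 16-bit TIFF slice stack with a
#' YAML sidecar (spec and seed), the ground-truth masks as 8-bit stacks, and
#' the centreline and per-bin density tables as CSV.
#'
#' @param phantom result of [generate_volume_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(phantom$volume, file.path(dir, "stack"))
  write_mask_stack(phantom$truth$tissue_mask, file.path(dir, "truth_tissue"))
  write_mask_stack(phantom$truth$vessel_mask, file.path(dir, "truth_vessel"))
  write.csv(phantom$truth$centreline,
            file.path(dir, "truth_centreline.csv"), row.names = FALSE)
  write.csv(phantom$truth$density_by_bin,
            file.path(dir, "truth_density_by_bin.csv"), row.names = FALSE)
  spec <- phantom$truth$spec
  yaml::write_yaml(list(
    spec = lapply(unclass(spec), function(x) if (is.null(x)) NULL else unname(x)),
    cord_point = as.numeric(phantom$truth$cord_point),
    global_density_pct = phantom$truth$global_density_pct
  ), file.path(dir, "phantom.yaml"))
  invisible(dir)
}
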