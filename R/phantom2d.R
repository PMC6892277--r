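#' Specify a 2D micrograph phantom
#'
#' Builds the parameter set for [generate_micrograph_phantom()]. The
#' phantom emulates an H&E micrograph of perfused placental tissue at known
#' scale: villous-tissue regions on a white background, perfused vessel
#' lumens (a bright contrast core with the pale shrinkage rim that the
#' casting agent leaves after histological processing - both counted as
#' lumen), and unperfused lumens filled with red cells. Ellipse lists give
#' centre `(cy, cx)` in pixels, semi-axes `(a, b)` in pixels and rotation
#' `angle` in radians.
#'
#' @param size_px image size `c(height, width)` in pixels. The default
#'   field (1200 x 1536 px at 0.9 um/px, i.e. 1080 x 1382 um) matches a
#'   x100 photomicrograph, so the whole-field area exceeds the 1,000,000
#'   um^2 particle-size cap and the background component is excluded by
#'   the standard filters.
#' @param um_per_px physical scale, micrometres per pixel.
#' @param villi,perfused,unperfused data frames with columns
#'   `cy, cx, a, b, angle`; `NULL` means none.
#' @param colours named list of RGB triplets in \[0, 1\] for `background`,
#'   `villous`, `microfil`, `rim`, `unperfused`.
#' @param noise_sd SD of additive Gaussian colour noise.
#' @param seed integer seed.
#' @return an object of class `phantom_spec_2d`.
#' @export
phantom_spec_2d <- function(size_px = c(1200L, 1536L),
                            um_per_px = 0.9,
                            villi = NULL,
                            perfused = NULL,
                            unperfused = NULL,
                            colours = list(
                              background = c(0.96, 0.96, 0.97),
                              villous = c(0.80, 0.55, 0.70),
                              microfil = c(0.95, 0.85, 0.35),
                              rim = c(0.97, 0.95, 0.90),
                              unperfused = c(0.75, 0.25, 0.25)
                            ),
                            noise_sd = 0.015,
                            seed = 1L) {
  size_px <- as.integer(size_px)
  if (length(size_px) != 2L || any(size_px < 16L)) {
    config_error("size_px must be c(height, width), both >= 16")
  }
  if (um_per_px <= 0) config_error("um_per_px must be positive")
  empty <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                      b = numeric(0), angle = numeric(0))
  norm_df <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(empty)
    df <- as.data.frame(df)
    if (is.null(df$angle)) df$angle <- 0
    if (any(df$a < 2) || any(df$b < 2)) {
      config_error("ellipse semi-axes must be >= 2 px for a faithful raster")
    }
    df[, c("cy", "cx", "a", "b", "angle")]
  }
  structure(list(size_px = size_px, um_per_px = um_per_px,
                 villi = norm_df(villi), perfused = norm_df(perfused),
                 unperfused = norm_df(unperfused), colours = colours,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec_2d")
}

# logical matrix of pixels inside a rotated ellipse (rasterised over the
# bounding box only)
ellipse_mask <- function(size_px, cy, cx, a, b, angle) {
  out <- matrix(FALSE, size_px[1], size_px[2])
  ext <- max(a, b)
  ys <- max(1L, floor(cy - ext)):min(size_px[1], ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(size_px[2], ceiling(cx + ext))
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  out[ys, xs] <- (u / a)^2 + (v / b)^2 <= 1
  out
}

ellipse_in_image <- function(df, size_px) {
  ext <- pmax(df$a, df$b)
  all(df$cy - ext >= 1 & df$cy + ext <= size_px[1] &
        df$cx - ext >= 1 & df$cx + ext <= size_px[2])
}

#' Generate a 2D micrograph phantom with ground truth
#'
#' Rasterises the spec into an RGB image plus per-class ground-truth masks
#' and per-ellipse lumen areas. Lumens of different classes must not
#' overlap and every lumen must lie inside a villous region (vessels live
#' in villi; a lumen on the background would merge with the
#' perfused-plus-background class).
#'
#' @param spec a [phantom_spec_2d()].
#' @return list with `image` (H x W x 3 array in \[0, 1\]), `labels`
#'   (integer matrix: 1 = perfused lumen + background, 2 = unperfused
#'   lumen, 3 = villous tissue), `masks` (logical matrices
#'   `perfused_bg`, `unperfused`, `villous`, plus `perfused_lumen` for the
#'   lumens alone), `areas` (data frame of per-ellipse analytic and
#'   rasterised areas in um^2) and `um_per_px`.
#' @export
generate_micrograph_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_2d"))
  sz <- spec$size_px
  for (nm in c("villi", "perfused", "unperfused")) {
    if (nrow(spec[[nm]]) && !ellipse_in_image(spec[[nm]], sz)) {
      config_error(sprintf("%s ellipses must lie fully inside the image", nm))
    }
  }
  villous <- matrix(FALSE, sz[1], sz[2])
  for (i in seq_len(nrow(spec$villi))) {
    e <- spec$villi[i, ]
    villous <- villous | ellipse_mask(sz, e$cy, e$cx, e$a, e$b, e$angle)
  }
  raster_lumens <- function(df) {
    masks <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      e <- df[i, ]
      masks[[i]] <- ellipse_mask(sz, e$cy, e$cx, e$a, e$b, e$angle)
    }
    masks
  }
  perf <- raster_lumens(spec$perfused)
  unperf <- raster_lumens(spec$unperfused)
  all_lumens <- c(perf, unperf)
  if (length(all_lumens) > 1L) {
    acc <- matrix(0L, sz[1], sz[2])
    for (m in all_lumens) acc <- acc + m
    if (any(acc > 1L)) config_error("overlapping lumen ellipses are not allowed")
  }
  for (m in all_lumens) {
    if (any(m & !villous)) {
      config_error("every lumen must lie inside a villous region")
    }
  }

  perfused_any <- Reduce(`|`, perf, matrix(FALSE, sz[1], sz[2]))
  unperfused_any <- Reduce(`|`, unperf, matrix(FALSE, sz[1], sz[2]))
  villous_only <- villous & !perfused_any & !unperfused_any

  labels <- matrix(1L, sz[1], sz[2]) # background + perfused lumens
  labels[villous_only] <- 3L
  labels[unperfused_any] <- 2L

  img <- render_class_image(labels, spec$colours, perf, spec)
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      noisy <- img + rnorm(length(img), 0, spec$noise_sd)
      pmin(pmax(noisy, 0), 1) # array first: keeps dim
    })
  }

  area_rows <- function(df, masks, class) {
    if (nrow(df) == 0L) {
      return(data.frame(class = character(0), ellipse = integer(0),
                        area_analytic_um2 = numeric(0),
                        area_raster_um2 = numeric(0)))
    }
    data.frame(class = class, ellipse = seq_len(nrow(df)),
               area_analytic_um2 = pi * df$a * df$b * spec$um_per_px^2,
               area_raster_um2 = vapply(masks, sum, 0L) * spec$um_per_px^2)
  }
  areas <- rbind(area_rows(spec$perfused, perf, "perfused"),
                 area_rows(spec$unperfused, unperf, "unperfused"))

  list(image = img, labels = labels,
       masks = list(perfused_bg = labels == 1L,
                    unperfused = unperfused_any,
                    villous = villous_only,
                    perfused_lumen = perfused_any),
       areas = areas, um_per_px = spec$um_per_px)
}

# paint the RGB image for a label matrix; perfused lumens get a microfil
# core (60% of the semi-axes) inside the pale rim
render_class_image <- function(labels, colours, perf_masks, spec) {
  sz <- dim(labels)
  npix <- prod(sz)
  pal <- rbind(colours$background, colours$unperfused, colours$villous)
  img <- array(0, c(sz[1], sz[2], 3))
  for (ch in 1:3) img[, , ch] <- pal[labels, ch]
  for (i in seq_len(nrow(spec$perfused))) {
    e <- spec$perfused[i, ]
    rim_idx <- which(perf_masks[[i]])
    core_idx <- which(ellipse_mask(sz, e$cy, e$cx, 0.6 * e$a, 0.6 * e$b,
                                   e$angle))
    for (ch in 1:3) {
      off <- npix * (ch - 1L)
      img[rim_idx + off] <- colours$rim[ch]
      img[core_idx + off] <- colours$microfil[ch]
    }
  }
  img
}

#' Generate a random micrograph phantom layout
#'
#' Convenience wrapper producing a consistent random layout: non-
#' overlapping villous regions, each holding non-overlapping perfused and
#' unperfused lumens with a containment margin.
#'
#' @param n_villi number of villous regions.
#' @param n_perfused,n_unperfused total lumen counts.
#' @param size_px,um_per_px,seed as in [phantom_spec_2d()].
#' @param lumen_radius_px range of lumen semi-axes, pixels.
#' @return a [phantom_spec_2d()].
#' @export
random_micrograph_spec <- function(n_villi = 5L, n_perfused = 8L,
                                   n_unperfused = 4L,
                                   size_px = c(1200L, 1536L), um_per_px = 0.9,
                                   lumen_radius_px = c(6, 60), seed = 1L) {
  with_seed(seed, {
    margin <- 160
    villi <- data.frame(
      cy = runif(n_villi, margin, size_px[1] - margin),
      cx = runif(n_villi, margin, size_px[2] - margin),
      a = runif(n_villi, 80, 150), b = runif(n_villi, 70, 140),
      angle = runif(n_villi, 0, pi)
    )
    place_lumens <- function(n, existing) {
      out <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                        b = numeric(0), angle = numeric(0))
      tries <- 0L
      while (nrow(out) < n && tries < 4000L) {
        tries <- tries + 1L
        v <- villi[sample(nrow(villi), 1L), ]
        a <- runif(1, lumen_radius_px[1], lumen_radius_px[2])
        b <- runif(1, lumen_radius_px[1], a)
        # place well inside the host villus
        rad <- runif(1, 0, 0.55)
        th <- runif(1, 0, 2 * pi)
        cy <- v$cy + rad * v$b * sin(th)
        cx <- v$cx + rad * v$a * cos(th)
        ext <- max(a, b)
        # inside host (conservative inner-circle bound) and clear of others
        if (sqrt((cy - v$cy)^2 + (cx - v$cx)^2) + ext > 0.9 * min(v$a, v$b)) next
        others <- rbind(existing, out)
        if (nrow(others) &&
            any(sqrt((others$cy - cy)^2 + (others$cx - cx)^2) <
                  pmax(others$a, others$b) + ext + 3)) next
        out <- rbind(out, data.frame(cy = cy, cx = cx, a = a, b = b,
                                     angle = runif(1, 0, pi)))
      }
      out
    }
    perf <- place_lumens(n_perfused, NULL)
    unperf <- place_lumens(n_unperfused, perf)
    phantom_spec_2d(size_px = size_px, um_per_px = um_per_px,
                    villi = villi, perfused = perf, unperfused = unperf,
                    seed = seed)
  })
}
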