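# Moore-neighbour boundary trace of a single connected component.
# `m` is a logical matrix containing the component padded by >= 1 false
# ring. Returns counts of even (axis) and odd (diagonal) chain steps.
trace_boundary <- function(m) {
  start <- which(m, arr.ind = TRUE)
  if (nrow(start) == 1L) return(list(n_even = 0L, n_odd = 0L))
  # first pixel in column-major order; its W neighbour is background
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]
  # clockwise Moore neighbourhood starting W (in (dy, dx), y downwards)
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  dir <- 1L # index into offs of the backtrack direction (W)
  n_even <- 0L
  n_odd <- 0L
  first_move <- NA_integer_
  visited_first <- FALSE
  max_steps <- 4L * sum(m) + 8L
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (k in 0:7) {
      probe <- ((dir - 1L + k) %% 8L) + 1L
      ny <- cur[1] + offs[probe, 1]
      nx <- cur[2] + offs[probe, 2]
      if (m[ny, nx]) {
        if (probe %% 2L == 1L) n_even <- n_even + 1L else n_odd <- n_odd + 1L
        # next backtrack direction: one step clockwise past where we came from
        dir <- ((probe - 1L - 2L) %% 8L) + 1L
        cur <- c(ny, nx)
        found <- TRUE
        if (is.na(first_move)) first_move <- probe
        break
      }
    }
    if (!found) break # isolated pixel (should not happen here)
    if (all(cur == start)) {
      if (visited_first) break
      visited_first <- TRUE
      # continue once more to close the contour in the same direction
      if (step > 1L) break
    }
  }
  list(n_even = n_even, n_odd = n_odd)
}

# perimeter of a component in pixel units (Kulpa's corrected chain-length
# estimator: unbiased for smooth convex shapes)
component_perimeter <- function(m) {
  tb <- trace_boundary(m)
  if (tb$n_even + tb$n_odd == 0L) return(4) # single pixel: unit square
  0.9481 * (tb$n_even + sqrt(2) * tb$n_odd)
}

#' Particle analysis of a binary class mask
#'
#' Labels connected components (8-connectivity), measures the
#' cross-sectional area, perimeter, circularity and centroid of each in
#' physical units, and retains the particles within the area and
#' circularity limits. The defaults (area 60 to 1,000,000 um^2,
#' circularity 0.20 to 1.00) exclude segmentation debris and the sprawling
#' background component. Circularity is `4 * pi * area / perimeter^2`,
#' capped at 1; the perimeter uses a weighted boundary-step estimator.
#'
#' @param mask logical matrix for one class.
#' @param um_per_px physical scale (micrometres per pixel); required.
#' @param class label recorded in the output (e.g. "perfused").
#' @param area_range_um2 inclusive area limits, um^2.
#' @param circ_range inclusive circularity limits.
#' @return data frame of retained particles: `class, particle, area_um2,
#'   perimeter_um, circularity, centroid_y, centroid_x`. The discarded
#'   count is attached as attribute `n_discarded`.
#' @export
analyse_particles <- function(mask, um_per_px, class = "particle",
                              area_range_um2 = c(60, 1e6),
                              circ_range = c(0.20, 1.00)) {
  if (missing(um_per_px) || is.null(um_per_px) || !is.finite(um_per_px) ||
      um_per_px <= 0) {
    data_error("missing scale metadata: um_per_px is required")
  }
  if (!is.logical(mask) || !is.matrix(mask)) {
    config_error("mask must be a logical matrix")
  }
  empty <- data.frame(class = character(0), particle = integer(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0))
  if (!any(mask)) {
    attr(empty, "n_discarded") <- 0L
    return(empty)
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  lab <- t(EBImage::imageData(lab)) # back to (row = y, col = x)
  nlab <- max(lab)
  rows <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    px <- which(lab == k, arr.ind = TRUE)
    area_px <- nrow(px)
    ylim <- range(px[, 1]); xlim <- range(px[, 2])
    sub <- matrix(FALSE, ylim[2] - ylim[1] + 3L, xlim[2] - xlim[1] + 3L)
    sub[cbind(px[, 1] - ylim[1] + 2L, px[, 2] - xlim[1] + 2L)] <- TRUE
    per_px <- component_perimeter(sub)
    circ <- if (per_px > 0) min(1, 4 * pi * area_px / per_px^2) else 1
    rows[[k]] <- data.frame(
      class = class, particle = k,
      area_um2 = area_px * um_per_px^2,
      perimeter_um = per_px * um_per_px,
      circularity = circ,
      centroid_y = mean(px[, 1]), centroid_x = mean(px[, 2]))
  }
  out <- do.call(rbind, rows)
  keep <- out$area_um2 >= area_range_um2[1] & out$area_um2 <= area_range_um2[2] &
    out$circularity >= circ_range[1] & out$circularity <= circ_range[2]
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_discarded") <- sum(!keep)
  res
}

#' Vascular fill above an area cutoff
#'
#' The fraction of vessel lumen area that carries contrast, among vessels
#' larger than the cutoff: `100 * sum(perfused areas > cutoff) / sum(all
#' vessel areas > cutoff)`. Cutoffs of 10,000 um^2 and 200 um^2 match the
#' vessel sizes resolvable at the whole-placenta and block imaging scales
#' respectively. With no qualifying vessel the fill is undefined (`NA`).
#'
#' @param particles data frame from [analyse_particles()] with `class`
#'   values `"perfused"` / `"unperfused"`.
#' @param area_cutoff_um2 strict lower area cutoff, um^2.
#' @return fill percentage, or `NA` if no vessel qualifies.
#' @export
vascular_fill <- function(particles, area_cutoff_um2) {
  qual <- particles[particles$area_um2 > area_cutoff_um2, , drop = FALSE]
  total <- sum(qual$area_um2)
  if (total == 0) return(NA_real_)
  100 * sum(qual$area_um2[qual$class == "perfused"]) / total
}

#' Histological vascular density
#'
#' Vessel lumen area (perfused and unperfused) as a percentage of the
#' villous tissue plus lumen area, mirroring the volumetric density
#' definition used at the imaging scales.
#'
#' @param particles data frame from [analyse_particles()].
#' @param villous_area_um2 total segmented villous cross-sectional area.
#' @return density percentage.
#' @export
vascular_density_histology <- function(particles, villous_area_um2) {
  if (!is.finite(villous_area_um2) || villous_area_um2 <= 0) {
    data_error("villous area must be positive")
  }
  v <- sum(particles$area_um2)
  100 * v / (villous_area_um2 + v)
}

#' Apply the vascular-fill inclusion rule
#'
#' Blocks whose villous vascular fill (at the > 200 um^2 cutoff) is below
#' the threshold are excluded, so that density estimates reflect
#' vascularity rather than incomplete perfusion. Inclusion is non-strict:
#' a block at exactly the threshold is kept.
#'
#' @param blocks data frame with a `fill_200` column (per-block fill \%).
#' @param min_fill inclusion threshold, percent.
#' @return the included subset; the number excluded is attached as
#'   attribute `n_excluded`.
#' @export
apply_inclusion_rule <- function(blocks, min_fill = 75) {
  if (!"fill_200" %in% names(blocks)) {
    config_error("blocks must carry a fill_200 column")
  }
  included <- !is.na(blocks$fill_200) & blocks$fill_200 >= min_fill
  out <- blocks[included, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!included)
  out
}

#' Analyse one micrograph end-to-end
#'
#' Classifies the pixels, runs the particle analysis on the perfused and
#' unperfused classes, and measures the villous area.
#'
#' @param image H x W x 3 RGB array.
#' @param um_per_px physical scale.
#' @param classifier passed to [classify_pixels()].
#' @param labels optional pre-made label matrix (skips classification).
#' @param ... particle filter arguments for [analyse_particles()].
#' @return list with `particles` (both classes), `villous_area_um2`,
#'   `labels`.
#' @export
analyse_micrograph <- function(image, um_per_px,
                               classifier = default_pixel_classifier(),
                               labels = NULL, ...) {
  if (missing(um_per_px) || is.null(um_per_px) || !is.finite(um_per_px) ||
      um_per_px <= 0) {
    data_error("missing scale metadata: um_per_px is required")
  }
  if (is.null(labels)) labels <- classify_pixels(image, classifier)
  perf <- analyse_particles(labels == 1L, um_per_px, class = "perfused", ...)
  unperf <- analyse_particles(labels == 2L, um_per_px, class = "unperfused", ...)
  particles <- rbind(perf, unperf)
  attr(particles, "n_discarded") <-
    attr(perf, "n_discarded") + attr(unperf, "n_discarded")
  list(particles = particles,
       villous_area_um2 = sum(labels == 3L) * um_per_px^2,
       labels = labels)
}
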