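#' Tissue / vessel threshold pair
#'
#' Holds the two greyscale thresholds used at both imaging scales: the
#' tissue threshold midway between the air and tissue histogram peaks, and
#' the contrast (Microfil) threshold midway between the tissue and contrast
#' peaks.
#'
#' @param tissue_threshold,microfil_threshold intensities.
#' @param peaks optional named intensities of the three histogram peaks.
#' @return an object of class `threshold_pair`.
#' @export
threshold_pair <- function(tissue_threshold, microfil_threshold,
                           peaks = NULL) {
  if (tissue_threshold >= microfil_threshold) {
    config_error("tissue threshold must be below the contrast threshold")
  }
  structure(list(tissue_threshold = tissue_threshold,
                 microfil_threshold = microfil_threshold,
                 peaks = peaks),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> tissue >= %.6g, contrast >= %.6g\n",
              x$tissue_threshold, x$microfil_threshold))
  if (!is.null(x$peaks)) {
    cat(" histogram peaks:", paste(signif(x$peaks, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

# local maxima of the smoothed histogram, ranked by topographic prominence.
# Returns bin indices of plateau starts (lowest-intensity bin on ties).
find_histogram_peaks <- function(smoothed) {
  n <- length(smoothed)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && smoothed[j + 1L] == smoothed[i]) j <- j + 1L
    left <- if (i == 1L) -Inf else smoothed[i - 1L]
    right <- if (j == n) -Inf else smoothed[j + 1L]
    if (smoothed[i] > left && smoothed[i] > right) {
      peaks <- c(peaks, i) # lowest-intensity bin of the plateau
    }
    i <- j + 1L
  }
  if (length(peaks) == 0L) return(data.frame(bin = integer(0), prominence = numeric(0)))
  prominence <- vapply(peaks, function(p) {
    h <- smoothed[p]
    saddle <- -Inf
    for (side in c(-1L, 1L)) {
      k <- p
      lo <- h
      repeat {
        k <- k + side
        if (k < 1L || k > n) { s <- -Inf; break } # ran off the edge: full drop
        lo <- min(lo, smoothed[k])
        if (smoothed[k] > h) { s <- lo; break }
      }
      saddle <- max(saddle, s)
    }
    if (is.infinite(saddle)) h else h - saddle
  }, numeric(1))
  data.frame(bin = peaks, prominence = prominence)
}

#' Find tissue and contrast thresholds from the greyscale histogram
#'
#' Detects the air, tissue and contrast modes of the volume's greyscale
#' histogram and places the segmentation thresholds at the arithmetic
#' midpoints between adjacent peak intensities. The histogram is smoothed
#' with a moving average of width 1/64 of the intensity range before peak
#' detection; the three most prominent maxima are kept and each peak
#' location is refined to the raw-histogram maximum within the smoothing
#' window (lowest intensity on ties).
#'
#' @param volume a [volume_image()] or a numeric array/vector of intensities.
#' @param n_bins maximum number of histogram bins (default 512; the bin
#'   width never drops below one intensity unit).
#' @return a [threshold_pair()] with the detected peaks attached.
#' @export
find_thresholds <- function(volume, n_bins = 512L) {
  x <- if (inherits(volume, "volume_image")) as.vector(volume$voxels) else as.vector(volume)
  rng <- range(x)
  span <- rng[2] - rng[1]
  if (span <= 0) data_error("histogram is degenerate: constant intensities")
  w <- max(1, ceiling((span + 1) / n_bins))
  bin <- (x - rng[1]) %/% w + 1L
  counts <- tabulate(bin, nbins = max(bin))
  # moving-average smoothing, width 1/64 of the intensity range
  k <- max(1L, round((span / 64) / w))
  if (k %% 2L == 0L) k <- k + 1L
  smoothed <- as.vector(stats::filter(counts, rep(1 / k, k), sides = 2))
  edge <- (k - 1L) %/% 2L
  if (edge > 0L) { # shrinking-window means at the edges
    nsm <- length(counts)
    for (i in seq_len(edge)) {
      smoothed[i] <- mean(counts[1:min(nsm, i + edge)])
      smoothed[nsm - i + 1L] <- mean(counts[max(1L, nsm - i + 1L - edge):nsm])
    }
  }
  pk <- find_histogram_peaks(smoothed)
  # greedy pick by prominence, keeping peaks at least 4 smoothing widths
  # apart so that flank wiggles of a big mode cannot displace a small mode
  pk <- pk[order(-pk$prominence), ]
  min_sep <- 4L * k
  sel <- integer(0)
  for (b in pk$bin) {
    if (length(sel) && min(abs(sel - b)) <= min_sep) next
    sel <- c(sel, b)
    if (length(sel) == 3L) break
  }
  if (length(sel) < 3L) {
    data_error(sprintf(
      "found %d separable histogram peak(s), need 3 (air, tissue, contrast); supply manual thresholds via threshold_pair()",
      length(sel)))
  }
  pk <- data.frame(bin = sel)
  # refine each peak to the raw-count maximum within the smoothing window
  half <- max(1L, edge)
  refined <- vapply(pk$bin, function(b) {
    lo <- max(1, b - half); hi <- min(length(counts), b + half)
    lo + which.max(counts[lo:hi]) - 1 # which.max: first (lowest) on ties
  }, numeric(1))
  intens <- sort(rng[1] + (refined - 1L) * w + (w - 1) / 2)
  threshold_pair(
    tissue_threshold = (intens[1] + intens[2]) / 2,
    microfil_threshold = (intens[2] + intens[3]) / 2,
    peaks = c(air = intens[1], tissue = intens[2], contrast = intens[3])
  )
}

#' Segment placental tissue and the perfused vascular tree
#'
#' Applies the threshold pair: tissue voxels are those at or above the
#' tissue threshold, vessel voxels those at or above the contrast threshold.
#' By construction the vessel mask is a subset of the tissue mask.
#'
#' @param volume a [volume_image()] or numeric array.
#' @param thresholds a [threshold_pair()].
#' @return list with logical arrays `tissue_mask` and `vessel_mask`.
#' @export
segment_volume <- function(volume, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  vox <- if (inherits(volume, "volume_image")) volume$voxels else volume
  tissue <- vox >= thresholds$tissue_threshold
  vessel <- vox >= thresholds$microfil_threshold
  list(tissue_mask = tissue, vessel_mask = vessel)
}
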