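#' Train the three-class pixel classifier
#'
#' A deterministic nearest-prototype classifier over RGB colour. The three
#' micrograph classes (perfused lumen + background, unperfused lumen,
#' villous tissue) are well separated in colour but internally multimodal -
#' the perfused-plus-background class spans the white background, the pale
#' shrinkage rim and the contrast core - so each class is represented by up
#' to `k` colour prototypes found by k-means on a fixed-seed subsample of
#' its training pixels, and pixels are assigned to the class of the nearest
#' prototype. This replaces an interactively trained segmentation model
#' with a reproducible surrogate; pre-made label images can also be fed
#' directly into the particle analysis.
#'
#' @param images list of H x W x 3 arrays in \[0, 1\].
#' @param labels list of integer matrices (1 = perfused + background,
#'   2 = unperfused, 3 = villous) congruent with `images`.
#' @param k maximum number of colour prototypes per class.
#' @param max_px training pixels subsampled per class.
#' @param seed RNG seed for subsampling and k-means initialisation.
#' @return an object of class `pixel_classifier` (prototype matrix plus
#'   class assignment).
#' @export
train_pixel_classifier <- function(images, labels, k = 3L, max_px = 20000L,
                                   seed = 1L) {
  if (length(images) != length(labels) || length(images) == 0L) {
    config_error("need matching, non-empty image and label lists")
  }
  pix <- vector("list", 3L)
  for (i in seq_along(images)) {
    img <- images[[i]]
    lab <- labels[[i]]
    if (!identical(unname(dim(img)[1:2]), unname(dim(lab)))) {
      config_error("image and label dimensions differ")
    }
    flat <- matrix(img, length(lab), 3L)
    for (cls in 1:3) {
      sel <- which(as.vector(lab) == cls)
      if (length(sel)) pix[[cls]] <- rbind(pix[[cls]], flat[sel, , drop = FALSE])
    }
  }
  if (any(vapply(pix, is.null, TRUE))) {
    config_error("every class must appear in the training labels")
  }
  with_seed(seed, {
    protos <- NULL
    proto_class <- integer(0)
    for (cls in 1:3) {
      p <- pix[[cls]]
      if (nrow(p) > max_px) p <- p[sample(nrow(p), max_px), , drop = FALSE]
      uq <- unique(round(p, 3))
      kk <- min(k, nrow(uq))
      centres <- if (kk < 2L) {
        matrix(colMeans(p), 1L, 3L)
      } else {
        suppressWarnings(kmeans(p, centers = kk, nstart = 5L,
                                iter.max = 200L,
                                algorithm = "Lloyd")$centers)
      }
      protos <- rbind(protos, centres)
      proto_class <- c(proto_class, rep(cls, nrow(centres)))
    }
    colnames(protos) <- c("r", "g", "b")
    structure(list(prototypes = protos, prototype_class = proto_class,
                   classes = c("perfused_bg", "unperfused", "villous")),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier> nearest colour prototype\n")
  df <- as.data.frame(round(x$prototypes, 3))
  df$class <- x$classes[x$prototype_class]
  print(df, row.names = FALSE)
  invisible(x)
}

# classifier trained once per session on two fixed-seed phantom micrographs
the <- new.env(parent = emptyenv())

#' Default pixel classifier
#'
#' Trained (and cached for the session) on two fixed-seed phantom
#' micrographs, so results are reproducible across machines.
#'
#' @return a [train_pixel_classifier()] result.
#' @export
default_pixel_classifier <- function() {
  if (is.null(the$classifier)) {
    phs <- lapply(c(101L, 102L), function(s) {
      generate_micrograph_phantom(random_micrograph_spec(seed = s))
    })
    the$classifier <- train_pixel_classifier(
      lapply(phs, `[[`, "image"), lapply(phs, `[[`, "labels"))
  }
  the$classifier
}

#' Classify micrograph pixels into the three analysis classes
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param classifier a [train_pixel_classifier()] result; default
#'   [default_pixel_classifier()].
#' @return integer matrix of class labels (1 = perfused + background,
#'   2 = unperfused, 3 = villous).
#' @export
classify_pixels <- function(image, classifier = default_pixel_classifier()) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    config_error("image must be an H x W x 3 RGB array")
  }
  npix <- d[1] * d[2]
  flat <- matrix(image, npix, 3)
  pr <- classifier$prototypes
  d2 <- sapply(seq_len(nrow(pr)), function(k) {
    (flat[, 1] - pr[k, 1])^2 + (flat[, 2] - pr[k, 2])^2 +
      (flat[, 3] - pr[k, 3])^2
  })
  matrix(classifier$prototype_class[max.col(-d2, ties.method = "first")],
         d[1], d[2])
}
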