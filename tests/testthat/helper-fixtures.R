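# shared fixtures, generated in code and cached for the session

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# axis-aligned cylinder along z; returns mask and the in-plane axis centre
make_cylinder <- function(r, L, pad = 6L) {
  d <- c(L + 2L * pad, 2L * pad + 2L * r + 1L, 2L * pad + 2L * r + 1L)
  cc <- pad + r + 1L
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  disc <- (yy - cc)^2 + (xx - cc)^2 <= r^2
  m <- array(FALSE, d)
  for (z in (pad + 1L):(pad + L)) m[z, , ] <- disc
  list(mask = m, centre = cc, z_range = c(pad + 1L, pad + L))
}

# cone tapering from r0 at the low-z end to r1 at the high-z end
make_cone <- function(r0, r1, L, pad = 8L) {
  rmax <- max(r0, r1)
  d <- c(L + 2L * pad, 2L * pad + 2L * rmax + 1L, 2L * pad + 2L * rmax + 1L)
  cc <- pad + rmax + 1L
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  m <- array(FALSE, d)
  for (k in seq_len(L)) {
    r <- r0 + (r1 - r0) * (k - 1) / (L - 1)
    m[pad + k, , ] <- (yy - cc)^2 + (xx - cc)^2 <= r^2
  }
  list(mask = m, centre = cc, z_range = c(pad + 1L, pad + L))
}

# capsule renderer for constructed tube phantoms (Y shapes etc.)
add_capsule <- function(mask, p0, p1, r) {
  idx <- placvasc:::capsule_indices(dim(mask), p0, p1, r)
  mask[idx] <- TRUE
  mask
}

make_y_tube <- function() {
  m <- array(FALSE, c(80L, 60L, 30L))
  m <- add_capsule(m, c(5, 30, 15), c(40, 30, 15), 2.5)
  m <- add_capsule(m, c(40, 30, 15), c(70, 15, 15), 2.5)
  m <- add_capsule(m, c(40, 30, 15), c(70, 45, 15), 2.5)
  m
}

disc_mask <- function(n, R, centre = (n + 1) / 2) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  (yy - centre)^2 + (xx - centre)^2 <= R^2
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# neighbour count census of a skeleton (26-connectivity)
skeleton_degrees <- function(skel) {
  coords <- skel$coords
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(key[i], TRUE, envir = idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vapply(seq_len(n), function(i) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    sum(vapply(seq_len(26), function(r) {
      !is.null(idx[[paste(nb[r, 1], nb[r, 2], nb[r, 3])]])
    }, TRUE))
  }, integer(1))
}

# standard small phantom reused across files
default_phantom <- function() {
  cached("ph3d", function() {
    generate_volume_phantom(phantom_spec_3d(seed = 21L, target_density = 0.05))
  })
}

default_micrograph <- function() {
  cached("ph2d", function() {
    generate_micrograph_phantom(random_micrograph_spec(seed = 7L))
  })
}

shared_classifier <- function() {
  cached("classifier", default_pixel_classifier)
}
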