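test_that("maximum intensity projection equals the per-pixel maximum", {
  const <- array(7L, c(4, 5, 6))
  expect_true(all(max_intensity_projection(const) == 7L))

  single <- array(0L, c(4, 5, 6))
  single[3, 2, 4] <- 99L
  mip <- max_intensity_projection(single)
  expect_equal(mip[2, 4], 99L)
  expect_equal(sum(mip), 99L)

  set.seed(3)
  vol <- array(sample.int(1000, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  oracle <- matrix(0L, 6, 5)
  for (y in 1:6) for (x in 1:5) oracle[y, x] <- max(vol[, y, x])
  expect_equal(max_intensity_projection(vol), oracle)
})

test_that("circular mask normalised distances follow 100 r / R", {
  R <- 50
  mask <- disc_mask(121, R)
  g <- compute_distance_map(mask, c(61, 61))
  yy <- matrix(1:121, 121, 121); xx <- t(yy)
  expected <- pmin(100, 100 * sqrt((yy - 61)^2 + (xx - 61)^2) / R)
  err <- abs(g$norm - expected)[mask]
  expect_lt(max(err), 100 * 1 / R) # within one-pixel discretisation
  expect_equal(g$norm[61, 61], 0)  # zero at the cord insertion
})

test_that("edge pixels normalise to exactly 100, also with an off-centre cord", {
  mask <- disc_mask(141, 50, centre = 71)
  g <- compute_distance_map(mask, c(60, 78))
  expect_equal(max(g$norm, na.rm = TRUE), 100)
  # the outermost pixel of every sector window sits exactly at 100
  expect_gt(sum(g$norm == 100, na.rm = TRUE), 90)
  # normalised distance is non-decreasing along rays: spot-check a transect
  row <- g$norm[60, 78:ncol(g$norm)]
  row <- row[!is.na(row)]
  expect_true(all(diff(row) >= 0))
})

test_that("elliptical masks match the analytic edge within 2 units", {
  ny <- 141; nx <- 181; a <- 80; b <- 55
  yy <- matrix(1:ny, ny, nx); xx <- matrix(1:nx, ny, nx, byrow = TRUE)
  mask <- ((yy - 71) / b)^2 + ((xx - 91) / a)^2 <= 1
  g <- compute_distance_map(mask, c(71, 91))
  pix <- which(mask, arr.ind = TRUE)
  r <- sqrt((pix[, 1] - 71)^2 + (pix[, 2] - 91)^2)
  th <- atan2(pix[, 1] - 71, pix[, 2] - 91)
  redge <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_lt(max(abs(g$norm[pix] - pmin(100, 100 * r / redge))), 2)
})

test_that("normalised distances are invariant to uniform scaling", {
  small <- disc_mask(81, 30, centre = 41)
  big <- disc_mask(161, 60, centre = 81)
  gs <- compute_distance_map(small, c(41, 41))
  gb <- compute_distance_map(big, c(81, 81))
  pix <- which(small, arr.ind = TRUE)
  v1 <- gs$norm[pix]
  v2 <- gb$norm[cbind(2 * pix[, 1] - 1, 2 * pix[, 2] - 1)]
  expect_lt(mean(abs(v1 - v2)), 1)
  expect_lt(max(abs(v1 - v2)), 100 / 30) # one pixel at the smaller scale
})

test_that("a convex mask covers every interior decile", {
  g <- compute_distance_map(disc_mask(81, 30, centre = 41), c(41, 41))
  counts <- hist(g$norm[!is.na(g$norm)], breaks = seq(0, 100, 10),
                 plot = FALSE)$counts
  expect_true(all(counts > 0))
})

test_that("degenerate geometry inputs raise data errors", {
  mask <- disc_mask(41, 15)
  expect_error(compute_distance_map(mask, c(2, 2)), "outside")
  lone <- matrix(FALSE, 21, 21); lone[11, 11] <- TRUE
  expect_error(compute_distance_map(lone, c(11, 11)), "zero-length")
})

test_that("normalised block location is the stated ratio", {
  expect_equal(normalise_block_location(0, 85), 0)
  expect_equal(normalise_block_location(85, 85), 100)
  expect_equal(normalise_block_location(42.5, 85), 50)
  expect_equal(normalise_block_location(c(10, 20), c(40, 40)), c(25, 50))
  expect_error(normalise_block_location(50, 40), "lie in")
  expect_error(normalise_block_location(1, 0), "positive")
})
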