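test_that("white-stripe normalization finds the right mode", {
  set.seed(11)
  shape <- c(24, 24, 16)
  brain <- array(TRUE, shape)
  # unimodal Gaussian brain: mode should land within 2 histogram bins of mean
  v <- array(rnorm(prod(shape), mean = 100, sd = 5), shape)
  out <- whitestripe_normalize(v, brain)
  binw <- diff(range(v)) / 128
  expect_lt(abs(attr(out, "ws_mode") - 100), 2 * binw)
  # bimodal with the larger peak on top: upper peak wins
  v2 <- array(c(rnorm(3216, 50, 3), rnorm(6000, 100, 3)), shape)
  out2 <- whitestripe_normalize(v2, brain)
  expect_lt(abs(attr(out2, "ws_mode") - 100), 5)
  # affine idempotence: renormalizing a normalized image is ~identity
  out3 <- whitestripe_normalize(out, brain)
  m <- attr(out3, "ws_mode"); s <- attr(out3, "ws_sd")
  expect_lt(abs(m), 0.2)
  expect_equal(s, 1, tolerance = 0.2)
  expect_equal(as.vector(out3), (as.vector(out) - m) / s, tolerance = 1e-10)
  expect_error(whitestripe_normalize(array(5, shape), brain),
               class = "cicr_data_error")
})

test_that("white-stripe falls back to whole-brain z-score on tiny stripes", {
  set.seed(12)
  shape <- c(10, 10, 4)
  brain <- array(FALSE, shape)
  brain[1:4, 1:4, 1] <- TRUE  # 16 in-brain voxels < 50-voxel stripe minimum
  v <- array(rnorm(prod(shape)), shape)
  expect_warning(out <- whitestripe_normalize(v, brain), "z-score")
  expect_equal(mean(out[brain]), 0, tolerance = 1e-10)
})

test_that("discretize follows the floor rule", {
  roi <- array(TRUE, c(5, 5, 3))
  v <- array(seq(0, 74, length.out = 75), c(5, 5, 3))
  dz <- discretize(v, roi, bin_width = 25)
  expect_equal(dz$ng, 3L)
  expect_equal(sort(unique(as.vector(dz$gray))), 1:3)
  expect_equal(discretize(array(7, c(5, 5, 3)), roi, bin_width = 1)$ng, 1L)
  expect_equal(discretize(v, roi, bin_width = 100)$ng, 1L)
  # only ROI voxels assigned
  roi2 <- roi; roi2[1, , ] <- FALSE
  expect_true(all(is.na(discretize(v, roi2, bin_width = 25)$gray[1, , ])))
  expect_error(discretize(v, array(FALSE, c(5, 5, 3)), bin_width = 1),
               class = "cicr_data_error")
})

test_that("wavelet sub-bands: vanishing detail, Parseval, frequency split", {
  const <- array(3, c(8, 8, 8))
  sb <- wavelet_subbands(const)
  for (nm in setdiff(names(sb), "LLL")) {
    expect_lt(max(abs(sb[[nm]])), 1e-8)
  }
  expect_equal(sd(as.vector(sb$LLL)), 0, tolerance = 1e-10)
  # Parseval on the decimated orthogonal variant
  set.seed(13)
  a <- array(rnorm(16 * 12 * 8), c(16, 12, 8))
  sbd <- wavelet_subbands(a, decimated = TRUE)
  expect_equal(sum(vapply(sbd, function(b) sum(b^2), numeric(1))),
               sum(a^2), tolerance = 1e-8)
  # low-frequency sinusoid along z concentrates in *-L-of-z bands
  z <- array(rep(sin(2 * pi * (1:16) / 16), each = 64), c(8, 8, 16))
  sbz <- wavelet_subbands(z, decimated = TRUE)
  e <- vapply(sbz, function(b) sum(b^2), numeric(1))
  lowz <- sum(e[c("LLL", "LHL", "HLL", "HHL")])
  expect_gt(lowz / sum(e), 0.95)
  expect_error(wavelet_subbands(array(0, c(4, 8, 8))),
               class = "cicr_config_error")
})

test_that("pointwise transforms are monotone, zero-preserving inverses", {
  set.seed(14)
  v <- array(runif(5 * 5 * 3, 0, 10), c(5, 5, 3))
  sq <- pointwise_transform(v, "square")
  back <- pointwise_transform(sq, "squareroot")
  # inverse pair up to the documented rescale: proportional to the input
  expect_equal(cor(as.vector(back), as.vector(v)), 1, tolerance = 1e-12)
  expect_equal(max(abs(back)), max(abs(v)), tolerance = 1e-12)
  for (k in c("square", "squareroot", "logarithm")) {
    expect_true(all(pointwise_transform(array(0, c(5, 5, 3)), k) == 0))
  }
  # ranking preserved by every kind (signed inputs included)
  v2 <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  for (k in c("square", "squareroot", "logarithm", "exponential")) {
    out <- pointwise_transform(v2, k)
    expect_equal(rank(as.vector(out)), rank(as.vector(v2)))
    expect_equal(max(abs(out)), max(abs(v2)), tolerance = 1e-8)
  }
})

test_that("gradient magnitude matches analytic values", {
  expect_true(all(gradient_magnitude(array(7, c(5, 5, 5))) == 0))
  # ramp slope 2 along x, spacing 1: interior value 2
  ramp <- array(rep(2 * (1:6), 36), c(6, 6, 6))
  g <- gradient_magnitude(ramp)
  expect_equal(unname(g[3, 3, 3]), 2)
  expect_equal(unname(g[1, 3, 3]), 2)  # one-sided boundary
  # spacing scales the derivative
  gv <- gradient_magnitude(image_volume(ramp, c(2, 1, 1)))
  expect_equal(unname(gv$values[3, 3, 3]), 1)
  # rotated ramp (45 degrees in xy): same magnitude in the interior
  rot <- outer(1:8, 1:8, function(i, j) (i + j) / sqrt(2))
  rot3 <- array(rep(rot, 4), c(8, 8, 4))
  g2 <- gradient_magnitude(rot3)
  expect_equal(unname(g2[4, 4, 2]), 1, tolerance = 1e-10)
})

test_that("LBP codes: constant, checkerboard, offset invariance", {
  const <- lbp2d(array(5, c(6, 6, 2)))
  expect_equal(length(unique(as.vector(const))), 1L)
  # checkerboard: interior pixels produce exactly two codes
  ck <- array(0, c(10, 10, 1))
  for (i in 1:10) for (j in 1:10) ck[i, j, 1] <- (i + j) %% 2
  codes <- lbp2d(ck)[3:8, 3:8, 1]
  expect_equal(length(unique(as.vector(codes))), 2L)
  # offset invariance
  set.seed(15)
  v <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  expect_equal(lbp2d(v), lbp2d(v + 17.3))
  l3a <- lbp3d(v, radii = 1L)
  l3b <- lbp3d(v + 5, radii = 1L)
  expect_equal(l3a, l3b)
  # constant volume -> constant 3D code
  c3 <- lbp3d(array(1, c(7, 7, 7)), radii = c(1L, 2L, 3L))
  expect_equal(length(c3), 3L)
  for (b in c3) expect_equal(length(unique(as.vector(b))), 1L)
  expect_error(lbp2d(v, radius = 10), class = "cicr_config_error")
  expect_error(lbp3d(v, radii = 5L), class = "cicr_config_error")
})

test_that("transform bank returns named volumes on the input lattice", {
  set.seed(16)
  v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(1, 1, 2))
  bank <- transform_bank(v)
  expect_setequal(names(bank), default_transform_labels())
  for (b in bank) {
    expect_s3_class(b, "image_volume")
    expect_equal(dim(b$values), c(8, 8, 8))
    expect_equal(b$spacing, c(1, 1, 2))
  }
})
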