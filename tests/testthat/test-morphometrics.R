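test_that("segmentation reproduces the reference mask and follows the particle rules", {
  sp <- gen_spheroid_image(spheroid_truth(40), c(128, 128), noise_level = 0)
  got <- segment_spheroid(sp$image)
  expect_identical(got$pixels, sp$mask$pixels)

  # speckles below min_size are excluded
  img <- sp$image
  img[5:6, 5:6] <- 0.9
  img[100:101, 10:11] <- 0.9
  m2 <- segment_spheroid(img, min_size = 50)
  expect_identical(m2$pixels, sp$mask$pixels)

  # largest-component rule: keep the 400 px^2 disc, not the 100 px^2 one
  two <- matrix(0.1, 120, 120)
  two[disc_mask(sqrt(400 / pi), n = 120, center = c(35, 35))] <- 0.9
  small <- disc_mask(sqrt(100 / pi), n = 120, center = c(90, 90))
  two[small] <- 0.9
  seg <- segment_spheroid(two, min_size = 10)
  expect_false(any(seg$pixels & small))
  expect_equal(sum(seg$pixels), sum(disc_mask(sqrt(400 / pi), n = 120,
                                              center = c(35, 35))))

  expect_error(segment_spheroid(matrix(0.5, 50, 50)), "constant")
  expect_error(segment_spheroid(two, min_size = 1e5), "empty segmentation")
})

test_that("area is a pixel count scaled by pixel size", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(measure_area(sq), 100)
  expect_equal(measure_area(binary_mask(sq, pixel_size = 2)), 400)
  d <- disc_mask(50)
  expect_equal(measure_area(d), pi * 50^2, tolerance = 0.01)
  expect_error(binary_mask(matrix(FALSE, 3, 3)), "empty")
})

test_that("sub-pixel perimeter matches closed forms for disc, square and ellipse", {
  d <- disc_mask(50)
  expect_equal(measure_perimeter(d), 2 * pi * 50, tolerance = 0.02)
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(measure_perimeter(sq), 40, tolerance = 0.05)
  px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE
  expect_gt(measure_perimeter(px), 0)
  e <- ellipse_mask(60, 30, theta = pi / 6)
  expect_equal(measure_perimeter(e), ellipse_perimeter_oracle(60, 30),
               tolerance = 0.02)
})

test_that("circularity follows the 4*pi*A/P^2 shape factor, capped at 1", {
  r <- 3; s <- 7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  # 2:1 ellipse from the elliptic-integral oracle
  P <- ellipse_perimeter_oracle(2, 1)
  expect_equal(circularity(2 * pi, P), 0.84, tolerance = 0.01)
  expect_equal(circularity(10, 2), 1)          # cap
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
})

test_that("moment ellipse fit recovers generator truth within 2% and 2 degrees", {
  e <- ellipse_mask(60, 30)
  f <- fit_ellipse(e)
  expect_equal(f$semi_major, 60, tolerance = 0.02)
  expect_equal(f$semi_minor, 30, tolerance = 0.02)
  expect_true(min(f$orientation, pi - f$orientation) < 2 * pi / 180)
  expect_equal(pi * f$semi_major * f$semi_minor, sum(e), tolerance = 1e-10)

  rot <- ellipse_mask(60, 30, theta = 30 * pi / 180)
  fr <- fit_ellipse(rot)
  expect_lt(abs(fr$orientation - 30 * pi / 180), 2 * pi / 180)

  d <- fit_ellipse(disc_mask(40))
  expect_lt(d$semi_major / d$semi_minor, 1.01)

  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(fit_ellipse(line), "collinear")
  expect_error(fit_ellipse(matrix(c(rep(FALSE, 20), TRUE), 21)), ">= 5")
})

test_that("roughness is the symmetric difference against the fitted ellipse", {
  # a rasterized ellipse against its own fit sits at the rasterization floor
  e <- ellipse_mask(60, 30, theta = pi / 7)
  expect_lte(roughness(e)$roughness_norm, 0.02)

  # disc with an attached square bump of area b: the bump is counted once
  # outside the ellipse and once as uncovered ellipse interior, and the
  # area-matched moment fit shifts toward the bump so both terms grow a
  # further ~20% beyond the naive 2b
  R <- 50; n <- 140
  d <- disc_mask(R, n = n)
  bump <- matrix(FALSE, n, n)
  bump[63:78, (70 + R + 1):(70 + R + 16)] <- TRUE   # 16x16 = 256 px^2 outside
  b <- sum(bump & !d)
  mask <- d | bump
  rg <- roughness(mask)
  expect_gte(rg$roughness_raw, 2 * b)
  expect_lte(rg$roughness_raw, 2.5 * b)
  # brute-force oracle: independent point-in-ellipse pixel count of the
  # symmetric difference for the fitted parameters
  f <- fit_ellipse(mask)
  xs <- matrix(seq_len(n), n, n) - f$center[1]
  ys <- matrix(rep(seq_len(n), each = n), n, n) - f$center[2]
  u <- cos(f$orientation) * xs + sin(f$orientation) * ys
  v <- -sin(f$orientation) * xs + cos(f$orientation) * ys
  inside <- (u / f$semi_major)^2 + (v / f$semi_minor)^2 <= 1
  expect_equal(rg$roughness_raw, sum(mask & !inside) + sum(inside & !mask))

  # monotone in harmonic amplitude
  rn <- vapply(c(0, 0.05, 0.1, 0.2), function(a) {
    h <- if (a > 0) data.frame(k = 6, amplitude = a, phase = 0)
         else data.frame(k = integer(0), amplitude = numeric(0), phase = numeric(0))
    roughness(gen_spheroid_image(spheroid_truth(50, harmonics = h),
                                 c(176, 176), noise_level = 0)$mask)$roughness_norm
  }, 0)
  expect_true(all(diff(rn) > 0))
})

test_that("scale and rotation behave covariantly", {
  sp <- gen_spheroid_image(spheroid_truth(45, harmonics =
    data.frame(k = 5, amplitude = 0.08, phase = 1)), c(160, 160),
    noise_level = 0)
  m1 <- morphometrics(sp$mask)
  m2 <- morphometrics(binary_mask(sp$mask$pixels, pixel_size = 2))
  expect_equal(m2$area, 4 * m1$area)
  expect_equal(m2$perimeter, 2 * m1$perimeter)
  expect_equal(m2$roughness_raw, 4 * m1$roughness_raw)
  expect_equal(m2$circularity, m1$circularity)
  expect_equal(m2$roughness_norm, m1$roughness_norm)

  rot <- morphometrics(t(sp$mask$pixels)[ncol(sp$mask$pixels):1, ])  # 90 deg
  expect_equal(rot$area, m1$area)
  expect_lt(abs(rot$circularity - m1$circularity) / m1$circularity, 0.01)
  expect_lt(abs(rot$roughness_norm - m1$roughness_norm) /
            m1$roughness_norm, 0.05)
})

test_that("morphometrics separates smooth BMD-like from rough TMD-like shapes", {
  bmd <- morphometrics(gen_spheroid_image(spheroid_truth(35), c(200, 200),
                                          noise_level = 0.05, seed = 1)$image)
  tmd <- morphometrics(gen_spheroid_image(
    spheroid_truth(55, harmonics = data.frame(k = 6, amplitude = 0.15,
                                              phase = 0)),
    c(200, 200), noise_level = 0.05, seed = 2)$image)
  expect_lt(bmd$area, tmd$area)
  expect_lt(bmd$roughness_norm, tmd$roughness_norm)
  expect_gt(bmd$circularity, tmd$circularity)
  expect_gte(morphometrics(disc_mask(50))$circularity, 0.97)
  expect_error(morphometrics(matrix(0, 50, 50)), "constant")
})
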