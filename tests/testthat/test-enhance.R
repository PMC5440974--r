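rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

test_that("LFT of a constant image is the constant with 0-degree tie-break", {
  img <- matrix(3.5, 20, 20)
  maps <- line_filter_transform(img, enhance_params(radius_r = 3))
  expect_true(all(abs(maps$intensity - 3.5) < 1e-12))
  expect_true(all(maps$orientation == 0))
})

test_that("LFT on a 1-px horizontal line returns the line value at 0 degrees", {
  img <- matrix(0, 21, 40)
  img[11, ] <- 1
  maps <- line_filter_transform(img, enhance_params(radius_r = 3))
  expect_true(all(abs(maps$intensity[11, ] - 1) < 1e-12))
  expect_true(all(maps$orientation[11, ] == 0))
})

test_that("LFT matches the brute-force double loop on random images", {
  set.seed(42)
  for (rep in 1:3) {
    img <- matrix(runif(15 * 15), 15, 15)
    maps <- line_filter_transform(img, enhance_params(radius_r = 2,
                                                      angle_step = 10))
    for (px in list(c(8, 8), c(2, 3), c(14, 12), c(1, 1), c(5, 15))) {
      o <- oracle_lft_pixel(img, px[1], px[2], r = 2, step = 10)
      expect_equal(maps$intensity[px[1], px[2]], o$intensity,
                   tolerance = 1e-10)
      expect_equal(maps$orientation[px[1], px[2]], o$orientation)
    }
  }
})

test_that("LFT intensity dominates the directional mean at every angle", {
  set.seed(7)
  img <- matrix(runif(15 * 15), 15, 15)
  maps <- line_filter_transform(img, enhance_params(radius_r = 2,
                                                    angle_step = 15))
  for (px in list(c(8, 8), c(3, 11), c(12, 4))) {
    for (a in oracle_angle_grid(15)) {
      sn <- sin(a * pi / 180)
      cs <- cos(a * pi / 180)
      vals <- c()
      for (t in -2:2) {
        v <- oracle_bilinear(img, px[1] - t * sn, px[2] + t * cs)
        if (!is.na(v)) vals <- c(vals, v)
      }
      expect_gte(maps$intensity[px[1], px[2]], mean(vals) - 1e-10)
    }
  }
})

test_that("OFT of an aligned constant field sums to (2r+1) rho", {
  r <- 3
  maps <- structure(
    list(intensity = matrix(2, 25, 25), orientation = matrix(30, 25, 25),
         oft = NULL, alpha = NULL,
         params = enhance_params(radius_r = r, angle_step = 5)),
    class = "enhancement_maps"
  )
  maps <- orientation_filter_transform(maps)
  interior <- maps$oft[(r + 2):(25 - r - 1), (r + 2):(25 - r - 1)]
  expect_true(all(abs(interior - (2 * r + 1) * 2) < 1e-9))
  expect_true(all(maps$alpha[12, 12] == 30))
})

test_that("perpendicular neighbor orientations flip the OFT term sign", {
  # cos(2 * 90 deg) = -1: a field whose orientation is everywhere
  # perpendicular to the probe yields -(2r+1) rho at the probe angle
  rho <- matrix(1, 21, 21)
  theta <- matrix(90, 21, 21)  # perpendicular to alpha = 0
  s <- 0
  for (t in -3:3) s <- s + 1 * cos(2 * (90 - 0) * pi / 180)
  expect_equal(s, -7)
  maps <- structure(
    list(intensity = rho, orientation = theta, oft = NULL, alpha = NULL,
         params = enhance_params(radius_r = 3, angle_step = 5)),
    class = "enhancement_maps"
  )
  maps <- orientation_filter_transform(maps)
  # |sum| ties between the aligned probe (alpha = 90, +7) and the
  # perpendicular probe (alpha = 0, -7); the smallest-|alpha| tie-break
  # selects alpha = 0, whose signed sum carries the perpendicularity flip
  expect_equal(maps$oft[11, 11], -7, tolerance = 1e-9)
  expect_equal(maps$alpha[11, 11], 0)
})

test_that("OFT matches the brute-force evaluation on random maps", {
  set.seed(11)
  rho <- matrix(runif(15 * 15), 15, 15)
  theta <- matrix(runif(15 * 15, -85, 90), 15, 15)
  maps <- structure(
    list(intensity = rho, orientation = theta, oft = NULL, alpha = NULL,
         params = enhance_params(radius_r = 3, angle_step = 15)),
    class = "enhancement_maps"
  )
  maps <- orientation_filter_transform(maps)
  for (px in list(c(8, 8), c(5, 10), c(11, 4), c(2, 2))) {
    o <- oracle_oft_pixel(rho, theta, px[1], px[2], r = 3, step = 15)
    expect_equal(maps$oft[px[1], px[2]], o$oft, tolerance = 1e-9)
    expect_equal(maps$alpha[px[1], px[2]], o$alpha)
  }
})

test_that("enhancement is 90-degree-rotation equivariant", {
  set.seed(3)
  img <- matrix(runif(30 * 30), 30, 30)
  p <- enhance_params(radius_r = 3, angle_step = 15)
  a <- enhance(img, p)
  b <- enhance(rot90ccw(img), p)
  expect_equal(b$intensity, rot90ccw(a$intensity), tolerance = 1e-9)
  # orientation argmax ties at corner pixels (degenerate sample sets) are
  # tie-broken per frame and need not commute with rotation; away from the
  # border ring of width r the maps must agree exactly
  keep <- 4:27
  oft_rot <- rot90ccw(a$oft)
  expect_equal(b$oft[keep, keep], oft_rot[keep, keep], tolerance = 1e-9)
  rel <- fibertrace:::wrap_orientation(rot90ccw(a$orientation) + 90)
  expect_equal(b$orientation[keep, keep], rel[keep, keep], tolerance = 1e-9)
  # and even including the border, disagreements are isolated tie pixels
  expect_lt(mean(abs(b$oft - oft_rot) > 1e-9), 0.01)
})

test_that("a blank image yields a constant OFT map", {
  maps <- enhance(matrix(0, 24, 24), enhance_params(radius_r = 3))
  expect_true(all(maps$oft == maps$oft[12, 12]))
})

test_that("enhancement raises on-skeleton contrast on a noisy phantom", {
  # diffuse background fluorescence (constant offset) is what limits the
  # raw-image contrast in practice; the filament/background ratio of the
  # OFT map must beat that of the raw image
  scene <- make_phantom(benchmark_scene_spec(psnr = 30, seed = 2))
  img <- scene$noisy_image + 50
  maps <- enhance(img)
  on <- scene$truth_skeleton == 1
  gain_oft <- mean(maps$oft[on]) / mean(maps$oft[!on])
  gain_raw <- mean(img[on]) / mean(img[!on])
  expect_gt(mean(maps$oft[on]), 2 * mean(maps$oft[!on]))
  expect_gt(gain_oft, gain_raw)
})

test_that("OFT suppresses an isotropic blob relative to a line of equal peak", {
  img_line <- matrix(0, 41, 41)
  img_line[21, 6:36] <- 1
  img_line <- gaussian_blur(img_line, 1)
  img_blob <- matrix(0, 41, 41)
  img_blob[21, 21] <- 1
  img_blob <- gaussian_blur(img_blob, 1)
  img_blob <- img_blob * max(img_line) / max(img_blob)
  p <- enhance_params(radius_r = 6)
  o_line <- enhance(img_line, p)$oft[21, 21]
  o_blob <- enhance(img_blob, p)$oft[21, 21]
  expect_gt(o_line, o_blob)
})

test_that("oversized radius is rejected", {
  expect_error(enhance(matrix(0, 10, 10), enhance_params(radius_r = 6)),
               "radius")
})
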