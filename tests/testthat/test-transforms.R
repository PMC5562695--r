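test_that("zero-coefficient transform is the identity", {
  px <- smooth_phantom(40, 40, seed = 1)
  img <- gray_image(px)
  t0 <- bspline_transform(8, c(40, 40))
  expect_equal(warp_image(img, t0)$pixels, px, tolerance = 1e-9)
  f <- transform_to_field(t0)
  expect_true(all(f$displacements == 0))
})

test_that("uniform coefficients give a constant field (partition of unity)", {
  t1 <- bspline_transform(8, c(40, 40))
  co <- t1$coefficients
  co[, , 1] <- 3
  t1 <- bspline_transform(8, c(40, 40), co)
  f <- transform_to_field(t1)
  expect_equal(max(abs(f$displacements[, , 1] - 3)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f$displacements[, , 2])), 0, tolerance = 1e-9)
})

test_that("a uniform (0,5) field shifts the image by 5 columns", {
  px <- smooth_phantom(48, 48, seed = 2)
  t1 <- bspline_transform(8, c(48, 48))
  co <- t1$coefficients
  co[, , 2] <- 5
  t1 <- bspline_transform(8, c(48, 48), co)
  out <- warp_image(gray_image(px), t1)$pixels
  # backward warp: output(r, c) = input(r, c + 5)
  expect_equal(out[, 1:43], px[, 6:48], tolerance = 1e-6)
})

test_that("field evaluation matches the direct tensor-product oracle", {
  set.seed(8)
  t1 <- random_bspline_transform(c(33, 41), 7, 4, seed = 3)
  f <- transform_to_field(t1)
  for (pt in list(c(0, 0), c(7, 14), c(13, 21), c(32, 40), c(5, 39))) {
    want <- oracle_bspline_point(t1$coefficients, 7, pt[1], pt[2])
    expect_equal(c(f$displacements[pt[1] + 1, pt[2] + 1, ]), want,
                 tolerance = 1e-12)
  }
})

test_that("random transforms are seeded, bounded and border-clamped", {
  t1 <- random_bspline_transform(c(64, 64), 16, 8, seed = 5)
  t2 <- random_bspline_transform(c(64, 64), 16, 8, seed = 5)
  expect_identical(t1$coefficients, t2$coefficients)
  t0 <- random_bspline_transform(c(64, 64), 16, 0, seed = 5)
  expect_true(all(t0$coefficients == 0))
  d <- dim(t1$coefficients)
  expect_true(all(t1$coefficients[1, , ] == 0))
  expect_true(all(t1$coefficients[, d[2], ] == 0))
  # dense-field magnitude never exceeds the spline overshoot bound
  for (s in 1:20) {
    tr <- random_bspline_transform(c(40, 40), 10, 5, seed = s)
    n <- mserg:::field_norms(transform_to_field(tr))
    expect_lte(max(n), 5 * (4 / 3) * 2)
  }
})

test_that("warp_image is linear in the image argument", {
  t1 <- random_bspline_transform(c(32, 32), 8, 3, seed = 9)
  i1 <- matrix(runif(32 * 32), 32, 32)
  i2 <- matrix(runif(32 * 32), 32, 32)
  w12 <- warp_image(gray_image(2 * i1 + 3 * i2), t1)$pixels
  w1 <- warp_image(gray_image(i1), t1)$pixels
  w2 <- warp_image(gray_image(i2), t1)$pixels
  expect_equal(w12, 2 * w1 + 3 * w2, tolerance = 1e-9)
  # constant image stays constant away from the (zero-filled) border
  wc <- warp_image(gray_image(matrix(1, 32, 32)), t1)$pixels
  expect_true(all(abs(wc[9:24, 9:24] - 1) < 1e-9))
})

test_that("tps_warp reduces to the exact affine for translated landmarks", {
  src <- landmark_set(rbind(c(2, 2), c(2, 20), c(20, 9)))
  dst <- landmark_set(src$points + rep(c(2, 1), each = 3))
  img <- gray_image(smooth_phantom(32, 32, seed = 3))
  res <- tps_warp(src, dst, img)
  expect_equal(max(abs(res$field$displacements[, , 1] - (-2))), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(res$field$displacements[, , 2] - (-1))), 0,
               tolerance = 1e-9)
})

test_that("tps_warp reproduces landmarks and rejects degenerate configs", {
  set.seed(6)
  src <- landmark_set(cbind(runif(5, 4, 28), runif(5, 4, 28)))
  dst <- landmark_set(src$points + matrix(rnorm(10, 0, 1.5), 5, 2))
  img <- gray_image(smooth_phantom(32, 32, seed = 7))
  res <- tps_warp(src, dst, img)
  # value at each dst landmark equals source value at the paired src landmark
  for (k in 1:5) {
    dpx <- round(dst$points[k, ]) + 1
    spx <- dst$points[k, ] + res$field$displacements[dpx[1], dpx[2], ]
    expect_equal(unname(c(spx)), unname(src$points[k, ]), tolerance = 0.75)
  }
  # identity when src == dst
  res0 <- tps_warp(src, src, img)
  expect_equal(max(abs(res0$field$displacements)), 0, tolerance = 1e-9)
  expect_equal(res0$image$pixels, img$pixels, tolerance = 1e-9)
  col <- landmark_set(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_error(tps_warp(col, col, img), "singular")
})

test_that("invert_field composes to near-identity for moderate warps", {
  t1 <- random_bspline_transform(c(64, 64), 16, 6, seed = 12)
  u <- transform_to_field(t1)
  v <- invert_field(u)
  # u(p + v(p)) + v(p) ~ 0 on the interior
  H <- 64
  rr <- rep(seq_len(H) - 1, times = H)
  cc <- rep(seq_len(H) - 1, each = H)
  ur <- mserg:::cpp_bilinear(u$displacements[, , 1],
                             rr + as.vector(v$displacements[, , 1]),
                             cc + as.vector(v$displacements[, , 2]))
  resid <- abs(ur + as.vector(v$displacements[, , 1]))
  interior <- rr >= 8 & rr <= 55 & cc >= 8 & cc <= 55
  expect_lt(max(resid[interior]), 0.05)
})
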