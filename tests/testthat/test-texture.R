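test_that("haralick_stack matches the brute-force co-occurrence oracle", {
  set.seed(11)
  px <- matrix(runif(16 * 16), 16, 16)
  img <- gray_image(px)
  for (kappa in c(3, 5)) {
    st <- haralick_stack(img, kappa, levels = 8)
    q <- oracle_quantize(px, 8)
    for (pt in list(c(1, 1), c(3, 7), c(8, 8), c(16, 16), c(2, 15))) {
      want <- oracle_glcm_pixel(q, pt[1], pt[2], kappa, 8)
      got <- st$maps[pt[1], pt[2], ]
      expect_equal(unname(got), unname(want), tolerance = 1e-9,
                   label = sprintf("kappa=%d at (%d,%d)", kappa, pt[1], pt[2]))
    }
  }
})

test_that("constant image gives zero contrast and unit energy everywhere", {
  img <- gray_image(matrix(3.3, 20, 20))
  st <- haralick_stack(img, 5)
  expect_true(all(st$maps[, , "contrast" == st$names] == 0))
  expect_true(all(st$maps[, , "energy" == st$names] == 1))
})

test_that("checkerboard at 0-degree offset has unit contrast", {
  px <- outer(1:9, 1:9, function(r, c) (r + c) %% 2)
  img <- gray_image(px)
  st <- haralick_stack(img, 3, levels = 2, angles = 0)
  expect_equal(st$maps[5, 5, 1], 1)
})

test_that("haralick bounds hold on arbitrary images", {
  set.seed(2)
  img <- gray_image(matrix(rnorm(30 * 30), 30, 30))
  st <- haralick_stack(img, 7)
  ent <- st$maps[, , 4]
  en <- st$maps[, , 3]
  expect_true(all(ent >= 0))
  expect_true(all(en > 0 & en <= 1))
})

test_that("gabor bank is DC-free and orientation-selective", {
  img <- gray_image(matrix(5, 40, 40))
  st <- gabor_stack(img, 9)
  expect_lt(max(abs(st$maps)), 1e-8 * 5)

  # sinusoid varying along columns peaks in the 0-orientation channel
  kappa <- 9
  px <- matrix(rep(sin(2 * pi * (0:47) / kappa), each = 48), 48, 48)
  st <- gabor_stack(gray_image(px), kappa)
  interior <- 15:34
  m <- sapply(1:4, function(i) mean(st$maps[interior, interior, i]))
  expect_equal(which.max(m), 1L)

  # rotating the image by 90 degrees swaps the 0 and 90 channels
  px90 <- t(px)[nrow(px):1, ]
  st90 <- gabor_stack(gray_image(px90), kappa)
  rot <- function(m) t(m)[ncol(m):1, ]   # rotate map by the same 90 degrees
  expect_equal(st90$maps[interior, interior, 3],
               rot(st$maps[, , 1])[interior, interior], tolerance = 1e-6)
  expect_equal(st90$maps[interior, interior, 1],
               rot(st$maps[, , 3])[interior, interior], tolerance = 1e-6)
})

test_that("texture_stack yields nine z-scored maps, deterministically", {
  px <- smooth_phantom(32, 32, seed = 4)
  img <- gray_image(px)
  st <- texture_stack(img, 5)
  expect_equal(dim(st$maps)[3], 9L)
  expect_length(st$names, 9L)
  for (f in 1:9) {
    m <- as.vector(st$maps[, , f])
    if (sd(m) > 0) {
      expect_lt(abs(mean(m)), 1e-9)
      expect_lt(abs(sd(m) - 1), 1e-9)
    }
  }
  st2 <- texture_stack(gray_image(px), 5)
  expect_identical(st$maps, st2$maps)
})

test_that("texture maps are translation-equivariant on interior pixels", {
  px <- smooth_phantom(64, 64, seed = 9)
  h0 <- haralick_stack(gray_image(px), 5)
  g0 <- gabor_stack(gray_image(px), 5)
  for (sh in list(c(1, 0), c(0, 2), c(3, 3))) {
    px_s <- matrix(0, 64, 64)
    px_s[(1 + sh[1]):64, (1 + sh[2]):64] <-
      px[1:(64 - sh[1]), 1:(64 - sh[2])]
    hs <- haralick_stack(gray_image(px_s), 5)
    gs <- gabor_stack(gray_image(px_s), 5)
    int0 <- 12:48   # deep interior: windows never touch the shifted-in border
    expect_equal(hs$maps[int0 + sh[1], int0 + sh[2], ],
                 h0$maps[int0, int0, ], tolerance = 1e-6)
    expect_equal(gs$maps[int0 + sh[1], int0 + sh[2], ],
                 g0$maps[int0, int0, ], tolerance = 1e-6)
  }
})

test_that("kappa validation rejects even or oversized windows", {
  img <- gray_image(matrix(runif(64), 8, 8))
  expect_error(haralick_stack(img, 4), "odd")
  expect_error(haralick_stack(img, 9), "larger")
  expect_error(gabor_stack(img, 2), "odd")
})
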