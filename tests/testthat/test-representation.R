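stack_from_maps <- function(maps, names = NULL) {
  names <- names %||% paste0("f", seq_len(dim(maps)[3]))
  mserg:::feature_stack(5L, maps, names)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ICA recovers independent uniform sources from a known mixture", {
  set.seed(10)
  n <- 40
  s1 <- matrix(runif(n * n), n, n)
  s2 <- matrix(runif(n * n), n, n)
  maps <- array(0, dim = c(n, n, 2))
  maps[, , 1] <- 1.0 * s1 + 0.5 * s2
  maps[, , 2] <- 0.5 * s1 + 1.0 * s2
  ics <- ica_reduce(stack_from_maps(maps), 2, seed = 1)
  for (src in list(s1, s2)) {
    cors <- abs(sapply(1:2, function(j)
      cor(as.vector(src), as.vector(ics$maps[, , j]))))
    expect_gt(max(cors), 0.95)
  }
})

test_that("IC components are pairwise uncorrelated and runs deterministic", {
  set.seed(11)
  img <- gray_image(smooth_phantom(48, 48, seed = 2) +
                    matrix(rnorm(48 * 48, 0, 0.05), 48, 48))
  st <- texture_stack(img, 5)
  ics <- ica_reduce(st, 4, seed = 7)
  S <- matrix(ics$maps, 48 * 48, 4)
  CC <- cor(S)
  expect_lt(max(abs(CC[upper.tri(CC)])), 1e-6)
  ics2 <- ica_reduce(st, 4, seed = 7)
  expect_identical(ics$maps, ics2$maps)
})

test_that("rank-deficient feature stacks trigger a degeneracy error", {
  maps <- array(0, dim = c(10, 10, 3))
  base <- matrix(rnorm(100), 10, 10)
  maps[, , 1] <- base
  maps[, , 2] <- 2 * base       # collinear
  maps[, , 3] <- -base
  expect_error(ica_reduce(stack_from_maps(maps), 3), "rank")
})

test_that("spectral embedding separates two well-separated clusters", {
  n <- 100
  maps <- array(0, dim = c(10, 10, 1))
  maps[, , 1] <- matrix(rep(c(0, 10), each = 50), 10, 10)
  ics <- mserg:::new_ic_stack(5L, maps, matrix(1), 1L)
  se <- spectral_embed(ics, n_vectors = 3, n_anchors = 100, seed = 2)
  v1 <- as.vector(se$vectors[, , 1])
  g0 <- v1[as.vector(maps) == 0]
  g1 <- v1[as.vector(maps) == 10]
  expect_lt(diff(range(g0)), 0.05)
  expect_lt(diff(range(g1)), 0.05)
  expect_gt(abs(mean(g0) - mean(g1)), 0.5)
})

test_that("embedding eigenvalues are ascending within the Laplacian bounds", {
  set.seed(13)
  maps <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3))
  ics <- mserg:::new_ic_stack(5L, maps, diag(3), 1L)
  se <- spectral_embed(ics, 3, n_anchors = 80, seed = 3)
  expect_true(all(diff(se$eigenvalues) >= -1e-12))
  expect_true(all(se$eigenvalues >= -1e-9 & se$eigenvalues <= 2))
  expect_true(all(se$vectors >= 0 & se$vectors <= 1))
})

test_that("Nystrom extension agrees with the dense eigendecomposition", {
  # every pixel is an anchor, so the Nystrom path must reproduce the direct
  # dense eigenvector coordinates exactly (up to the shared post-scaling)
  set.seed(14)
  npix <- 150
  maps <- array(rnorm(npix * 2), dim = c(15, 10, 2))
  ics <- mserg:::new_ic_stack(5L, maps, diag(2), 1L)
  se <- spectral_embed(ics, 3, n_anchors = npix, seed = 5)

  # independent dense construction mirroring the documented graph definition
  X <- matrix(maps, npix, 2)
  for (j in 1:2) {
    q <- quantile(X[, j], c(0.01, 0.99), names = FALSE)
    X[, j] <- pmin(pmax(X[, j], q[1]), q[2])
  }
  gr <- 0.3745672074914381
  w <- sapply(1:2, function(j) (mean(log(cosh(X[, j]))) - gr)^2)
  X <- sweep(X, 2, sqrt(w / max(w)), "*")
  D2 <- as.matrix(dist(X))^2
  off <- D2[upper.tri(D2)]
  s2 <- median(off)
  D2s <- D2; diag(D2s) <- Inf
  s2 <- max(s2, max(apply(D2s, 1, min)) / log(1e6))
  W <- exp(-D2 / s2)
  kd <- rowSums(W); W <- W / outer(kd, kd)
  dg <- rowSums(W)
  S <- W / sqrt(outer(dg, dg))
  eg <- eigen(S, symmetric = TRUE)
  for (j in 1:3) {
    v <- unname(eg$vectors[, j + 1])
    got <- as.vector(se$vectors[, , j])
    # compare after identical sign/clip/minmax post-processing
    sk <- mean(v^3)
    if (sk < -1e-12 || (abs(sk) <= 1e-12 && v[which.max(abs(v))] < 0)) v <- -v
    q <- quantile(v, c(0.005, 0.995), names = FALSE)
    if (q[2] > q[1]) v <- pmin(pmax(v, q[1]), q[2])
    v <- (v - min(v)) / (max(v) - min(v))
    expect_equal(got, v, tolerance = 1e-8)
  }
})

test_that("joint representation of an identical pair is symmetric", {
  px <- smooth_phantom(40, 40, seed = 6)
  pair <- preprocess_pair(gray_image(px), gray_image(px))
  cfg <- reg_config(n_anchors = 300, seed = 21)
  reps <- build_scale_representation(pair, 5, cfg)
  expect_equal(reps$fixed$vectors, reps$moving$vectors, tolerance = 1e-10)
  expect_equal(dim(reps$fixed$vectors), c(40, 40, 3))
  # shared value scale across the two halves
  both <- c(reps$fixed$vectors, reps$moving$vectors)
  expect_equal(min(both), 0)
  expect_equal(max(both), 1)
  # determinism
  reps2 <- build_scale_representation(pair, 5, cfg)
  expect_identical(reps$fixed$vectors, reps2$fixed$vectors)
})
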