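# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Per-window co-occurrence features by direct enumeration. `q` is the
# quantized image (0-based levels), reflect padding is applied here by index
# mirroring (half-sample symmetric, same convention as the package).
oracle_glcm_pixel <- function(q, r, c, kappa, levels,
                              offsets = list(c(0, 1), c(-1, 1),
                                             c(-1, 0), c(-1, -1))) {
  h <- kappa %/% 2
  H <- nrow(q); W <- ncol(q)
  mirror <- function(i, n) {
    # reflect with edge duplication: ... 2 1 | 1 2 ... n | n n-1 ...
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  rows <- mirror((r - h):(r + h), H)
  cols <- mirror((c - h):(c + h), W)
  win <- q[rows, cols, drop = FALSE]
  feats <- matrix(NA_real_, length(offsets), 5)
  used <- logical(length(offsets))
  for (oi in seq_along(offsets)) {
    dr <- offsets[[oi]][1]; dc <- offsets[[oi]][2]
    P <- matrix(0, levels, levels)
    for (wr in seq_len(kappa)) {
      for (wc in seq_len(kappa)) {
        r2 <- wr + dr; c2 <- wc + dc
        if (r2 >= 1 && r2 <= kappa && c2 >= 1 && c2 <= kappa) {
          a <- win[wr, wc] + 1; b <- win[r2, c2] + 1
          P[a, b] <- P[a, b] + 1
          P[b, a] <- P[b, a] + 1
        }
      }
    }
    if (sum(P) == 0) next
    used[oi] <- TRUE
    P <- P / sum(P)
    iv <- row(P) - 1; jv <- col(P) - 1
    contrast <- sum(P * (iv - jv)^2)
    mu_i <- sum(iv * P); mu_j <- sum(jv * P)
    var_i <- sum((iv - mu_i)^2 * P); var_j <- sum((jv - mu_j)^2 * P)
    corr <- if (sqrt(var_i * var_j) > 1e-12)
      (sum(iv * jv * P) - mu_i * mu_j) / sqrt(var_i * var_j) else 0
    energy <- sum(P^2)
    pz <- P[P > 0]
    entropy <- -sum(pz * log2(pz))
    homog <- sum(P / (1 + abs(iv - jv)))
    feats[oi, ] <- c(contrast, corr, energy, entropy, homog)
  }
  if (!any(used)) return(c(0, 0, 1, 0, 0))
  colMeans(feats[used, , drop = FALSE])
}

# Direct quantization matching the package convention.
oracle_quantize <- function(x, levels) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- floor((x - lo) / (hi - lo) * levels)
  matrix(as.integer(pmin(pmax(q, 0), levels - 1)), nrow(x), ncol(x))
}

# Naive per-pixel loop metrics.
oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  2 * inter / (na + nb)
}

oracle_rmsd <- function(p0, p1) {
  s <- 0
  for (k in seq_len(nrow(p0)))
    s <- s + sum((p0[k, ] - p1[k, ])^2)
  sqrt(s / nrow(p0))
}

oracle_mdd <- function(u0, u1) {
  H <- dim(u0)[1]; W <- dim(u0)[2]
  s <- 0
  for (r in seq_len(H))
    for (c in seq_len(W))
      s <- s + sqrt((u0[r, c, 1] - u1[r, c, 1])^2 +
                    (u0[r, c, 2] - u1[r, c, 2])^2)
  s / (H * W)
}

# Direct tensor-product cubic B-spline displacement at one 0-based point.
oracle_bspline_point <- function(coef, spacing, r, c) {
  B <- function(m, t) switch(m + 1,
    (1 - t)^3 / 6,
    (3 * t^3 - 6 * t^2 + 4) / 6,
    (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
    t^3 / 6)
  sr <- r / spacing; sc <- c / spacing
  i0 <- floor(sr); j0 <- floor(sc)
  tr <- sr - i0; tc <- sc - j0
  out <- c(0, 0)
  for (mi in 0:3) {
    for (mj in 0:3) {
      gi <- i0 + mi + 1; gj <- j0 + mj + 1
      if (gi >= 1 && gi <= dim(coef)[1] && gj >= 1 && gj <= dim(coef)[2])
        out <- out + B(mi, tr) * B(mj, tc) * coef[gi, gj, ]
    }
  }
  out
}

# Small smooth test image with structure at several scales.
smooth_phantom <- function(H = 64, W = 64, seed = 1) {
  set.seed(seed)
  r <- seq(0, 1, length.out = H); c <- seq(0, 1, length.out = W)
  R <- matrix(rep(r, times = W), H, W); C <- matrix(rep(c, each = H), H, W)
  img <- exp(-((R - 0.4)^2 + (C - 0.5)^2) / 0.05) +
    0.5 * exp(-((R - 0.7)^2 + (C - 0.3)^2) / 0.01) +
    0.2 * sin(6 * pi * R) * cos(4 * pi * C)
  (img - min(img)) / (max(img) - min(img))
}
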