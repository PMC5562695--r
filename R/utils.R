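# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a deterministic child seed (< 2^31) from a base seed and tags.
sub_seed <- function(seed, a, b = 0L) {
  s <- (as.double(seed) %% 1000003) * 1009 + as.double(a) * 131 + as.double(b)
  as.integer(s %% 2147483647)
}

# Linear rescale to [0, 1]; a constant input maps to all zeros.
rescale01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi)) stop("non-finite values in rescale01")
  if (hi - lo <= 0) return(x * 0)
  (x - lo) / (hi - lo)
}

# Reflect-pad a matrix by hr rows / hc cols (half-sample symmetric: the edge
# pixel is duplicated).
pad_reflect <- function(m, hr, hc = hr) {
  H <- nrow(m); W <- ncol(m)
  if (hr >= H || hc >= W) stop("padding exceeds image size")
  ri <- c(rev(seq_len(hr)), seq_len(H), H + 1 - seq_len(hr))
  ci <- c(rev(seq_len(hc)), seq_len(W), W + 1 - seq_len(hc))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing with reflect padding; sigma in pixels.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- pad_reflect(m, h, h)
  tmp <- cpp_conv2_valid(p, matrix(g, ncol = 1))       # rows smoothed
  cpp_conv2_valid(tmp, matrix(g, nrow = 1))            # then cols
}

# Bilinear resize of a matrix to (H2, W2), pixel-center aligned.
resize_bilinear <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  rr <- (seq_len(H2) - 0.5) * H / H2 - 0.5
  cc <- (seq_len(W2) - 0.5) * W / W2 - 0.5
  rr <- pmin(pmax(rr, 0), H - 1)
  cc <- pmin(pmax(cc, 0), W - 1)
  grid_r <- rep(rr, times = W2)
  grid_c <- rep(cc, each = H2)
  matrix(cpp_bilinear(m, grid_r, grid_c), H2, W2)
}

# Nearest-neighbour resize (for masks).
resize_nearest <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(round((seq_len(H2) - 0.5) * H / H2 + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(W2) - 0.5) * W / W2 + 0.5), 1), W)
  m[ri, ci, drop = FALSE]
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
}
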