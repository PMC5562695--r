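#' Independent-component stack
#'
#' Result of reducing a [texture_stack()] with ICA: per-pixel independent
#' component values (unit variance, mutually uncorrelated over the mask), the
#' mixing summary and the seed used.
#'
#' @name ic_stack
#' @keywords internal
NULL

new_ic_stack <- function(scale, maps, mixing, seed, mask = NULL, spacing = 1) {
  structure(list(scale = scale, maps = maps, mixing = mixing, seed = seed,
                 mask = mask, spacing = spacing),
            class = "ic_stack")
}

#' @export
print.ic_stack <- function(x, ...) {
  cat(sprintf("<ic_stack> kappa = %d, %d components of %d x %d (seed %d)\n",
              x$scale, dim(x$maps)[3], dim(x$maps)[1], dim(x$maps)[2], x$seed))
  invisible(x)
}

# Deterministic sign convention: positive skewness; when skewness is
# numerically zero, the entry of largest magnitude is made positive.
fix_sign <- function(v, tol = 1e-12) {
  sk <- mean(v^3)
  if (sk < -tol) return(-v)
  if (sk > tol) return(v)
  if (v[which.max(abs(v))] < 0) -v else v
}

#' Reduce a texture stack with seeded ICA
#'
#' Per-pixel feature vectors over the mask are centred and whitened; a
#' deflationary fixed-point ICA (logcosh contrast) then extracts
#' `n_components` components maximizing non-Gaussianity. The run is fully
#' deterministic given `seed`. Component signs follow the positive-skewness
#' convention so repeated runs cannot flip.
#'
#' @param stack a [texture_stack()] result (`feature_stack`).
#' @param n_components number of ICs, `2 <= n_components <= F`.
#' @param seed integer seed for the random initial unmixing directions.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an `ic_stack`: `maps` (H x W x C, zeros outside the mask),
#'   `mixing` (C x F), `scale`, `seed`.
#' @export
ica_reduce <- function(stack, n_components, seed = 1L, max_iter = 200,
                       tol = 1e-9) {
  stopifnot(inherits(stack, "feature_stack"))
  d <- dim(stack$maps)
  F_ <- d[3]
  if (n_components < 2 || n_components > F_)
    stop("n_components must be in [2, F]")
  sel <- if (is.null(stack$mask)) rep(TRUE, d[1] * d[2]) else as.vector(stack$mask)
  X <- matrix(stack$maps, d[1] * d[2], F_)[sel, , drop = FALSE]
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  CV <- crossprod(Xc) / n
  eg <- eigen(CV, symmetric = TRUE)
  lam <- eg$values
  rank <- sum(lam > max(lam[1], 1e-300) * 1e-10)
  if (rank < n_components)
    stop(sprintf("feature covariance rank %d < %d requested components",
                 rank, n_components))
  idx <- seq_len(n_components)
  K <- t(eg$vectors[, idx, drop = FALSE]) / sqrt(lam[idx])  # C x F whitening
  Z <- Xc %*% t(K)                                          # n x C, cov = I
  C <- n_components
  Wm <- matrix(0, C, C)
  Winit <- with_seed(seed, matrix(rnorm(C * C), C, C))
  for (i in seq_len(C)) {
    w <- Winit[i, ]
    if (i > 1) {
      prev <- Wm[seq_len(i - 1), , drop = FALSE]
      w <- w - as.vector(t(prev) %*% (prev %*% w))
    }
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- Z %*% w
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- as.vector(crossprod(Z, g)) / n - mean(gp) * w
      if (i > 1) {
        prev <- Wm[seq_len(i - 1), , drop = FALSE]
        w_new <- w_new - as.vector(t(prev) %*% (prev %*% w_new))
      }
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-300) stop("ICA direction collapsed; deficient input")
      w_new <- w_new / nw
      conv <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- w_new
      if (conv) break
    }
    Wm[i, ] <- w
  }
  S <- Z %*% t(Wm)                                          # n x C sources
  for (i in seq_len(C)) {
    s2 <- fix_sign(S[, i])
    if (!identical(s2, S[, i])) {
      S[, i] <- s2
      Wm[i, ] <- -Wm[i, ]
    }
  }
  maps <- array(0, dim = c(d[1], d[2], C))
  flat <- matrix(0, d[1] * d[2], C)
  flat[sel, ] <- S
  maps[] <- flat
  new_ic_stack(stack$scale, maps, Wm %*% K, as.integer(seed),
               stack$mask, stack$spacing)
}
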