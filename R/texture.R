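#' Per-scale texture feature stack
#'
#' @param scale odd window side \eqn{\kappa} in pixels.
#' @param maps H x W x F numeric array of feature responses.
#' @param names character vector of F feature identifiers.
#' @return object of class `feature_stack` (fields `scale`, `maps`, `names`,
#'   and the source image's `mask`/`spacing`).
#' @keywords internal
feature_stack <- function(scale, maps, names, mask = NULL, spacing = 1) {
  d <- dim(maps)
  if (length(d) != 3L) stop("maps must be H x W x F")
  if (length(names) != d[3]) stop("names length must equal F")
  stopifnot_finite(maps, "feature maps")
  structure(list(scale = scale, maps = maps, names = names,
                 mask = mask, spacing = spacing),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> kappa = %d, %d maps of %d x %d: %s\n",
              x$scale, dim(x$maps)[3], dim(x$maps)[1], dim(x$maps)[2],
              paste(x$names, collapse = ", ")))
  invisible(x)
}

check_kappa <- function(kappa, H, W) {
  if (kappa %% 2 != 1 || kappa < 3) stop("kappa must be odd and >= 3")
  if (kappa > min(H, W)) stop("kappa larger than image")
}

# Quantize intensities into `levels` equal-width bins (0..levels-1); the bin
# range is taken over mask pixels when a mask is present.
quantize_gray <- function(img, levels, mask = NULL) {
  x <- img
  ref <- if (is.null(mask)) x else x[mask]
  lo <- min(ref); hi <- max(ref)
  if (hi - lo <= 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- floor((x - lo) / (hi - lo) * levels)
  q <- pmin(pmax(q, 0), levels - 1)
  matrix(as.integer(q), nrow(x), ncol(x))
}

.haralick_names <- c("contrast", "correlation", "energy", "entropy",
                     "homogeneity")

offset_table <- function(angles) {
  tab <- rbind("0" = c(0L, 1L), "45" = c(-1L, 1L),
               "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  key <- as.character(angles)
  if (!all(key %in% rownames(tab))) stop("angles must be in {0,45,90,135}")
  tab[key, , drop = FALSE]
}

haralick_maps_raw <- function(pixels, kappa, levels, angles, mask = NULL) {
  H <- nrow(pixels); W <- ncol(pixels)
  check_kappa(kappa, H, W)
  if (levels < 2) stop("levels must be >= 2")
  q <- quantize_gray(pixels, levels, mask)
  h <- kappa %/% 2
  qp <- pad_reflect(q, h, h)
  storage.mode(qp) <- "integer"
  res <- cpp_glcm_maps(qp, H, W, kappa, levels, offset_table(angles))
  array(res, dim = c(H, W, 5))
}

#' Haralick (co-occurrence) texture maps at scale kappa
#'
#' For every pixel a symmetric gray-level co-occurrence matrix is accumulated
#' over the \eqn{\kappa \times \kappa} window at distance 1 for the offsets
#' 0/45/90/135 degrees (reflect padding at borders), normalized per offset and
#' averaged. Five features are returned: contrast, correlation, energy,
#' entropy (bits), homogeneity.
#'
#' @param img a [gray_image()].
#' @param kappa odd window side, `3 <= kappa <= min(H, W)`.
#' @param levels gray-level quantization bins (default 16, computed over the
#'   mask when present).
#' @param angles subset of `c(0, 45, 90, 135)`.
#' @param split_column optional seam column of a concatenated image; windows
#'   are then computed per half (each half reflect-padded on its own) so no
#'   window straddles the seam.
#' @return a `feature_stack` with 5 maps.
#' @export
haralick_stack <- function(img, kappa, levels = 16, angles = c(0, 45, 90, 135),
                           split_column = NULL) {
  stopifnot(inherits(img, "gray_image"))
  maps <- per_half(img, split_column, function(px, mk)
    haralick_maps_raw(px, kappa, levels, angles, mk))
  feature_stack(kappa, maps, .haralick_names, img$mask, img$spacing)
}

gabor_kernels <- function(kappa) {
  sigma <- kappa / 3
  lambda <- kappa
  h <- kappa %/% 2
  x <- seq(-h, h)
  thetas <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  lapply(thetas, function(th) {
    # wave vector at angle th from the column axis; (row, col) grid
    C <- matrix(rep(x, each = kappa), kappa, kappa)      # col offsets
    R <- matrix(rep(x, times = kappa), kappa, kappa)     # row offsets
    xp <- C * cos(th) + R * sin(th)
    yp <- -C * sin(th) + R * cos(th)
    env <- exp(-(xp^2 + yp^2) / (2 * sigma^2))
    even <- env * cos(2 * pi * xp / lambda)
    odd <- env * sin(2 * pi * xp / lambda)
    even <- even - env * (sum(even) / sum(env))   # remove the DC response
    list(even = even, odd = odd)
  })
}

gabor_maps_raw <- function(pixels, kappa) {
  H <- nrow(pixels); W <- ncol(pixels)
  check_kappa(kappa, H, W)
  h <- kappa %/% 2
  p <- pad_reflect(pixels, h, h)
  ks <- gabor_kernels(kappa)
  maps <- array(0, dim = c(H, W, length(ks)))
  for (i in seq_along(ks)) {
    re <- cpp_conv2_valid(p, ks[[i]]$even)
    im <- cpp_conv2_valid(p, ks[[i]]$odd)
    maps[, , i] <- sqrt(re^2 + im^2)
  }
  maps
}

#' Gabor texture maps at scale kappa
#'
#' A quadrature Gabor bank with 4 orientations (0, 45, 90, 135 degrees,
#' measured from the column axis), wavelength \eqn{\lambda = \kappa}, Gaussian
#' envelope \eqn{\sigma = \kappa/3}, kernels truncated to
#' \eqn{\kappa \times \kappa} and made DC-free. The 4 response magnitudes are
#' returned.
#'
#' @inheritParams haralick_stack
#' @return a `feature_stack` with 4 maps (`gabor_0` .. `gabor_135`).
#' @export
gabor_stack <- function(img, kappa, split_column = NULL) {
  stopifnot(inherits(img, "gray_image"))
  maps <- per_half(img, split_column, function(px, mk) gabor_maps_raw(px, kappa))
  feature_stack(kappa, maps, paste0("gabor_", c(0, 45, 90, 135)),
                img$mask, img$spacing)
}

# Apply a (pixels, mask) -> H x W x F map function per half of a concatenated
# image (or to the whole image when split_column is NULL).
per_half <- function(img, split_column, fn) {
  px <- img$pixels
  if (is.null(split_column)) return(fn(px, img$mask))
  halves <- split_representation(px, split_column)
  masks <- if (is.null(img$mask)) list(fixed = NULL, moving = NULL)
           else split_representation(img$mask, split_column)
  a <- fn(halves$fixed, masks$fixed)
  b <- fn(halves$moving, masks$moving)
  out <- array(0, dim = c(dim(px)[1], dim(px)[2], dim(a)[3]))
  out[, seq_len(split_column), ] <- a
  out[, (split_column + 1):dim(px)[2], ] <- b
  out
}

#' Combined z-scored texture stack (5 Haralick + 4 Gabor maps)
#'
#' Concatenates [haralick_stack()] and [gabor_stack()] and z-scores every map
#' (zero mean, unit sd over mask pixels; constant maps are left at zero).
#'
#' @inheritParams haralick_stack
#' @return a `feature_stack` with F = 9 maps.
#' @export
texture_stack <- function(img, kappa, levels = 16, split_column = NULL) {
  h <- haralick_stack(img, kappa, levels, split_column = split_column)
  g <- gabor_stack(img, kappa, split_column = split_column)
  d <- dim(h$maps)
  maps <- array(0, dim = c(d[1], d[2], 9))
  maps[, , 1:5] <- h$maps
  maps[, , 6:9] <- g$maps
  mask <- img$mask
  sel <- if (is.null(mask)) TRUE else mask
  for (f in 1:9) {
    m <- maps[, , f]
    v <- if (isTRUE(sel)) as.vector(m) else m[sel]
    s <- sd(v)
    if (s <= 1e-300 || !is.finite(s)) {
      maps[, , f] <- 0
    } else {
      maps[, , f] <- (m - mean(v)) / s
    }
  }
  feature_stack(kappa, maps, c(h$names, g$names), mask, img$spacing)
}
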