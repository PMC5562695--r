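#' Fixed/moving image pair
#'
#' Plain container tying a fixed and a moving [gray_image()] together. After
#' [preprocess_pair()] both members have identical shape and spacing.
#'
#' @param fixed,moving [gray_image()] objects.
#' @return object of class `image_pair`.
#' @export
image_pair <- function(fixed, moving) {
  stopifnot(inherits(fixed, "gray_image"), inherits(moving, "gray_image"))
  structure(list(fixed = fixed, moving = moving), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat("<image_pair>\n  fixed:  ")
  print(x$fixed)
  cat("  moving: ")
  print(x$moving)
  invisible(x)
}

resample_to_spacing <- function(img, new_spacing) {
  if (new_spacing <= 0) stop("spacing must be positive")
  ratio <- img$spacing / new_spacing
  H2 <- max(1L, as.integer(round(nrow(img$pixels) * ratio)))
  W2 <- max(1L, as.integer(round(ncol(img$pixels) * ratio)))
  if (H2 == nrow(img$pixels) && W2 == ncol(img$pixels))
    return(gray_image(img$pixels, new_spacing, img$mask))
  px <- resize_bilinear(img$pixels, H2, W2)
  mk <- if (is.null(img$mask)) NULL else resize_nearest(img$mask, H2, W2)
  gray_image(px, new_spacing, mk)
}

pad_to <- function(img, H, W) {
  h0 <- nrow(img$pixels); w0 <- ncol(img$pixels)
  if (h0 == H && w0 == W) return(img)
  top <- (H - h0) %/% 2; left <- (W - w0) %/% 2
  px <- matrix(0, H, W)
  px[top + seq_len(h0), left + seq_len(w0)] <- img$pixels
  mk <- NULL
  if (!is.null(img$mask)) {
    mk <- matrix(FALSE, H, W)
    mk[top + seq_len(h0), left + seq_len(w0)] <- img$mask
  }
  gray_image(px, img$spacing, mk)
}

#' Match resolution and extent of a fixed/moving pair
#'
#' The moving image is resampled (bilinear; masks nearest-neighbour) so its
#' pixel spacing equals the fixed image's, then both images are zero-padded
#' symmetrically to a common shape. The operation is idempotent.
#'
#' @param fixed,moving [gray_image()] objects.
#' @return an [image_pair()] whose members share shape and spacing.
#' @export
preprocess_pair <- function(fixed, moving) {
  stopifnot(inherits(fixed, "gray_image"), inherits(moving, "gray_image"))
  if (fixed$spacing <= 0 || moving$spacing <= 0)
    stop("spacings must be positive")
  moving <- resample_to_spacing(moving, fixed$spacing)
  H <- max(nrow(fixed$pixels), nrow(moving$pixels))
  W <- max(ncol(fixed$pixels), ncol(moving$pixels))
  image_pair(pad_to(fixed, H, W), pad_to(moving, H, W))
}

#' Spatially concatenate a preprocessed pair
#'
#' Each half is linearly rescaled to \[0, 1\] (a constant half maps to zeros)
#' and the two are placed side by side, fixed left of moving, so that texture
#' features, ICA and the spectral embedding can be computed jointly on one
#' image and therefore share one basis across modalities.
#'
#' @param pair an [image_pair()] with members of identical shape.
#' @return object of class `concatenated_image` with fields `pixels`,
#'   `split_column`, `spacing`, `mask`.
#' @export
concatenate_pair <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  f <- pair$fixed; m <- pair$moving
  if (!identical(dim(f$pixels), dim(m$pixels)))
    stop("fixed and moving must have identical shapes (run preprocess_pair)")
  px <- cbind(rescale01(f$pixels), rescale01(m$pixels))
  mask <- NULL
  if (!is.null(f$mask) || !is.null(m$mask)) {
    fm <- if (is.null(f$mask)) matrix(TRUE, nrow(f$pixels), ncol(f$pixels)) else f$mask
    mm <- if (is.null(m$mask)) matrix(TRUE, nrow(m$pixels), ncol(m$pixels)) else m$mask
    mask <- cbind(fm, mm)
  }
  structure(list(pixels = px, split_column = ncol(f$pixels),
                 spacing = f$spacing, mask = mask),
            class = "concatenated_image")
}

#' @export
print.concatenated_image <- function(x, ...) {
  cat(sprintf("<concatenated_image> %d x %d px, split at column %d\n",
              nrow(x$pixels), ncol(x$pixels), x$split_column))
  invisible(x)
}

#' Split a grid computed on a concatenated image back into its halves
#'
#' Works on 2-D matrices and on 3-D arrays (channels preserved).
#'
#' @param grid matrix or 3-D array aligned with a concatenated image.
#' @param split_column column index separating fixed (left) from moving.
#' @return list with elements `fixed` and `moving`.
#' @export
split_representation <- function(grid, split_column) {
  d <- dim(grid)
  if (split_column <= 0 || split_column >= d[2])
    stop("split_column out of range")
  if (length(d) == 2L) {
    list(fixed = grid[, seq_len(split_column), drop = FALSE],
         moving = grid[, (split_column + 1):d[2], drop = FALSE])
  } else if (length(d) == 3L) {
    list(fixed = grid[, seq_len(split_column), , drop = FALSE],
         moving = grid[, (split_column + 1):d[2], , drop = FALSE])
  } else stop("grid must be 2-D or 3-D")
}
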