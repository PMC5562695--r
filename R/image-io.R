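#' Grayscale image with pixel spacing
#'
#' The package's basic image container: a numeric matrix of intensities, an
#' isotropic pixel spacing in millimetres and an optional binary mask marking
#' the region of interest (e.g. a prostate segmentation).
#'
#' @param pixels numeric matrix of intensities (finite).
#' @param spacing isotropic pixel size in mm (positive scalar).
#' @param mask optional logical matrix of the same shape; `TRUE` = inside.
#' @return An object of class `gray_image` with fields `pixels`, `spacing`,
#'   `mask`.
#' @export
gray_image <- function(pixels, spacing = 1, mask = NULL) {
  pixels <- as.matrix(pixels)
  pixels <- matrix(as.double(pixels), nrow(pixels), ncol(pixels))
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  stopifnot_finite(pixels, "pixels")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) stop("spacing must be a positive scalar (mm)")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels)))
      stop("mask shape must match pixels")
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
  structure(list(pixels = pixels, spacing = spacing, mask = mask),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing %g mm, range [%g, %g]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels),
              if (is.null(x$mask)) "" else
                sprintf(", mask %d px", sum(x$mask))))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# ITU-R BT.601 luminance weights used for RGB -> gray conversion,
# normalized to sum exactly to one so that white maps to full scale.
.luma_weights <- c(0.2989, 0.5870, 0.1140) / sum(c(0.2989, 0.5870, 0.1140))

rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1])
  if (nc >= 3L)
    return(.luma_weights[1] * arr[, , 1] + .luma_weights[2] * arr[, , 2] +
           .luma_weights[3] * arr[, , 3])
  stop("unsupported channel count: ", nc)
}

#' Read a grayscale image from PNG, TIFF or NIfTI
#'
#' RGB rasters are converted to gray with ITU-R BT.601 luminance weights
#' (0.2989, 0.5870, 0.1140). PNG and integer TIFF intensities are returned on
#' the conventional 0--255 scale; floating-point TIFF values are stored
#' pre-divided by 255 by [write_gray_image()] and are scaled back on read.
#' NIfTI volumes require a `slice` index when they have more than two
#' dimensions; values are kept as stored.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param spacing pixel size in mm attached to the result.
#' @param slice slice index along the third axis for 3-D NIfTI input.
#' @return A [gray_image()].
#' @export
load_gray_image <- function(path, spacing = 1, slice = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(sub(".*\\.(?=[a-zA-Z0-9]+$)", "", basename(path), perl = TRUE))
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) > 2L) {
      extra <- dim(a)[-(1:2)]
      if (all(extra == 1L)) {
        a <- array(a, dim = dim(a)[1:2])
      } else if (is.null(slice)) {
        stop("volume has >2 spatial dims; supply a slice index")
      } else {
        a <- a[, , slice, drop = TRUE]
        if (length(dim(a)) != 2L) a <- array(a, dim = dim(a)[1:2])
      }
    }
    return(gray_image(a, spacing))
  }
  if (ext == "png") {
    a <- png::readPNG(path)
    return(gray_image(rgb_to_gray(a) * 255, spacing))
  }
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(a)
    a <- rgb_to_gray(unclass(a))
    # the tiff reader scales both integer and float samples into [0, 1]
    return(gray_image(a * 255, spacing))
  }
  stop("unsupported image format: ", ext)
}

#' Write a grayscale image as 32-bit float TIFF
#'
#' Intensities are stored divided by 255 (the reader multiplies back), so a
#' round trip preserves values to single-float precision.
#'
#' @param img a [gray_image()].
#' @param path output `.tif` path.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  v <- img$pixels / 255
  if (min(v) < 0 || max(v) > 1)
    stop("pixel values outside [0, 255] cannot be serialized")
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read / write a binary mask image
#'
#' Any nonzero pixel counts as inside.
#'
#' @param path image path (PNG/TIFF/NIfTI).
#' @param slice optional NIfTI slice index.
#' @return logical matrix.
#' @export
load_mask <- function(path, slice = NULL) {
  img <- load_gray_image(path, spacing = 1, slice = slice)
  img$pixels != 0
}

#' Ordered landmark set
#'
#' Landmarks are (row, col) coordinates in millimetres, 0-based, pixel-center
#' convention. Two corresponding sets must have equal length and identical
#' ordering; correspondence is by list position.
#'
#' @param points K x 2 numeric matrix of (row_mm, col_mm).
#' @param labels optional character vector of length K.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be K x 2 (row_mm, col_mm)")
  if (nrow(points) < 1L) stop("need at least one landmark")
  stopifnot_finite(points, "landmarks")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("labels length must match number of points")
  colnames(points) <- c("row_mm", "col_mm")
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (mm)\n", nrow(x$points)))
  invisible(x)
}

#' Read landmarks from CSV (`label,row_mm,col_mm`)
#'
#' @param path CSV file path with header `label,row_mm,col_mm`.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "row_mm", "col_mm")
  if (!all(need %in% names(d))) stop("landmark CSV needs columns ",
                                     paste(need, collapse = ","))
  landmark_set(cbind(d$row_mm, d$col_mm), labels = as.character(d$label))
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()] to write.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  labels <- if (is.null(lm$labels)) seq_len(nrow(lm$points)) else lm$labels
  write.csv(data.frame(label = labels, row_mm = lm$points[, 1],
                       col_mm = lm$points[, 2]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
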