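#' Cubic B-spline free-form deformation
#'
#' A dense displacement parameterized by control-point displacements on a
#' uniform grid of spacing `grid_spacing` pixels, interpolated with the cubic
#' B-spline tensor-product basis. The grid covers the image domain with one
#' extra ring of control points on each side; zero coefficients give the
#' identity map. Coordinates are 0-based (row, col) pixel centers and
#' displacements are in pixels.
#'
#' @param grid_spacing control-point spacing in px (> 0).
#' @param domain image shape `c(H, W)` the transform covers.
#' @param coefficients optional `Gr x Gc x 2` array of (drow, dcol) control
#'   displacements; defaults to zeros (identity).
#' @return object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_spacing, domain, coefficients = NULL) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  H <- domain[1]; W <- domain[2]
  Gr <- floor((H - 1) / grid_spacing) + 4L
  Gc <- floor((W - 1) / grid_spacing) + 4L
  if (is.null(coefficients)) coefficients <- array(0, dim = c(Gr, Gc, 2))
  d <- dim(coefficients)
  if (length(d) != 3L || d[1] != Gr || d[2] != Gc || d[3] != 2L)
    stop(sprintf("coefficients must be %d x %d x 2 for this domain", Gr, Gc))
  stopifnot_finite(coefficients, "coefficients")
  structure(list(grid_spacing = grid_spacing, coefficients = coefficients,
                 domain = as.integer(domain[1:2])),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf(
    "<bspline_transform> %d x %d control grid, spacing %g px, domain %d x %d, max |coef| %.3g px\n",
    d[1], d[2], x$grid_spacing, x$domain[1], x$domain[2],
    max(abs(x$coefficients))))
  invisible(x)
}

# Displacements at 0-based positions (rows, cols); returns N x 2 (drow, dcol).
bspline_disp_at <- function(t, rows, cols) {
  cpp_bspline_disp(t$coefficients[, , 1], t$coefficients[, , 2],
                   as.numeric(rows), as.numeric(cols), t$grid_spacing)
}

#' Dense displacement field
#'
#' @param displacements H x W x 2 array of (drow, dcol) in pixels.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(displacements) {
  d <- dim(displacements)
  if (length(d) != 3L || d[3] != 2L) stop("displacements must be H x W x 2")
  stopifnot_finite(displacements, "displacements")
  structure(list(displacements = displacements), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  n <- sqrt(x$displacements[, , 1]^2 + x$displacements[, , 2]^2)
  cat(sprintf("<deformation_field> %d x %d px, |u| mean %.3g, max %.3g\n",
              dim(n)[1], dim(n)[2], mean(n), max(n)))
  invisible(x)
}

field_norms <- function(f) {
  u <- if (inherits(f, "deformation_field")) f$displacements else f
  sqrt(u[, , 1]^2 + u[, , 2]^2)
}

#' Evaluate a B-spline transform as a dense deformation field
#'
#' @param t a [bspline_transform()].
#' @return a [deformation_field()] over the transform's domain.
#' @export
transform_to_field <- function(t) {
  stopifnot(inherits(t, "bspline_transform"))
  H <- t$domain[1]; W <- t$domain[2]
  rr <- rep(seq_len(H) - 1, times = W)
  cc <- rep(seq_len(W) - 1, each = H)
  u <- bspline_disp_at(t, rr, cc)
  out <- array(0, dim = c(H, W, 2))
  out[, , 1] <- matrix(u[, 1], H, W)
  out[, , 2] <- matrix(u[, 2], H, W)
  deformation_field(out)
}

warp_matrix_with_disp <- function(px, ur, uc) {
  H <- nrow(px); W <- ncol(px)
  rr <- rep(seq_len(H) - 1, times = W) + ur
  cc <- rep(seq_len(W) - 1, each = H) + uc
  matrix(cpp_bilinear(px, rr, cc), H, W)
}

#' Warp an image with a B-spline transform (backward warping)
#'
#' `output(p) = input(p + u(p))` with bilinear intensity interpolation;
#' samples falling outside the domain are set to 0. A mask, when present, is
#' warped with nearest-neighbour interpolation.
#'
#' @param img a [gray_image()] whose shape equals the transform domain.
#' @param t a [bspline_transform()] (or a [deformation_field()]).
#' @return the warped [gray_image()].
#' @export
warp_image <- function(img, t) {
  stopifnot(inherits(img, "gray_image"))
  if (inherits(t, "bspline_transform")) {
    if (!identical(dim(img$pixels), as.integer(t$domain)))
      stop("transform domain does not match image shape")
    f <- transform_to_field(t)
  } else if (inherits(t, "deformation_field")) {
    f <- t
    if (!identical(dim(img$pixels), dim(f$displacements)[1:2]))
      stop("field shape does not match image shape")
  } else stop("t must be a bspline_transform or deformation_field")
  ur <- as.vector(f$displacements[, , 1])
  uc <- as.vector(f$displacements[, , 2])
  px <- warp_matrix_with_disp(img$pixels, ur, uc)
  mk <- if (is.null(img$mask)) NULL else warp_mask_with_disp(img$mask, ur, uc)
  gray_image(px, img$spacing, mk)
}

warp_mask_with_disp <- function(mask, ur, uc) {
  H <- nrow(mask); W <- ncol(mask)
  rr <- round(rep(seq_len(H) - 1, times = W) + ur)
  cc <- round(rep(seq_len(W) - 1, each = H) + uc)
  ok <- rr >= 0 & rr <= H - 1 & cc >= 0 & cc <= W - 1
  out <- logical(H * W)
  out[ok] <- mask[cbind(rr[ok] + 1, cc[ok] + 1)]
  matrix(out, H, W)
}

#' Warp a binary mask with a transform or field (nearest neighbour)
#' @param mask logical matrix.
#' @inheritParams warp_image
#' @return warped logical matrix.
#' @export
warp_mask <- function(mask, t) {
  f <- if (inherits(t, "bspline_transform")) transform_to_field(t) else t
  warp_mask_with_disp(mask, as.vector(f$displacements[, , 1]),
                      as.vector(f$displacements[, , 2]))
}

#' Draw a random B-spline transform (synthetic deformations)
#'
#' Control displacements are drawn i.i.d. uniform from
#' `[-max_disp, max_disp]` per component; the outermost ring of control
#' points is clamped to zero so the image border stays (nearly) fixed.
#'
#' @param domain image shape `c(H, W)`.
#' @param grid_spacing control spacing in px.
#' @param max_disp maximum control displacement in px (>= 0).
#' @param seed integer seed.
#' @return a [bspline_transform()].
#' @export
random_bspline_transform <- function(domain, grid_spacing, max_disp,
                                     seed = 1L) {
  if (max_disp < 0) stop("max_disp must be >= 0")
  t0 <- bspline_transform(grid_spacing, domain)
  d <- dim(t0$coefficients)
  coef <- with_seed(seed,
    array(runif(prod(d), -max_disp, max_disp), dim = d))
  coef[1, , ] <- 0; coef[d[1], , ] <- 0
  coef[, 1, ] <- 0; coef[, d[2], ] <- 0
  bspline_transform(grid_spacing, domain, coef)
}

#' Thin-plate-spline landmark warp (manual ground-truth tool)
#'
#' Standard 2-D TPS interpolant (\eqn{U(r) = r^2 \log r}, affine part
#' included) mapping the destination landmarks onto the source landmarks,
#' applied by backward warping so the landmark correspondences are reproduced
#' exactly. Landmarks are in mm and converted to pixels via the image spacing.
#'
#' @param src_landmarks,dst_landmarks [landmark_set()]s of equal size K >= 3;
#'   `dst` landmarks must not be collinear.
#' @param img the [gray_image()] to warp (the source image).
#' @return list with the warped [gray_image()] and the dense
#'   [deformation_field()] (px).
#' @export
tps_warp <- function(src_landmarks, dst_landmarks, img) {
  stopifnot(inherits(src_landmarks, "landmark_set"),
            inherits(dst_landmarks, "landmark_set"),
            inherits(img, "gray_image"))
  S <- src_landmarks$points / img$spacing   # px, 0-based
  D <- dst_landmarks$points / img$spacing
  K <- nrow(S)
  if (nrow(D) != K) stop("landmark sets must have equal K")
  if (K < 3) stop("need at least 3 landmarks")
  U <- function(r2) ifelse(r2 <= 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  R2 <- cpp_cross_dist2(D, D)
  P <- cbind(1, D)
  L <- rbind(cbind(U(R2), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(S, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (collinear or duplicate landmarks)"))
  Wt <- sol[seq_len(K), , drop = FALSE]
  At <- sol[K + 1:3, , drop = FALSE]
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  rr <- rep(seq_len(H) - 1, times = W)
  cc <- rep(seq_len(W) - 1, each = H)
  G2 <- cpp_cross_dist2(cbind(rr, cc), D)
  maps <- U(G2) %*% Wt + cbind(1, rr, cc) %*% At   # f(p): target -> source px
  ur <- maps[, 1] - rr
  uc <- maps[, 2] - cc
  field <- array(0, dim = c(H, W, 2))
  field[, , 1] <- matrix(ur, H, W)
  field[, , 2] <- matrix(uc, H, W)
  px <- warp_matrix_with_disp(img$pixels, ur, uc)
  list(image = gray_image(px, img$spacing),
       field = deformation_field(field))
}

#' Invert a dense deformation field by fixed-point iteration
#'
#' Solves `v(p) = -u(p + v(p))`, the displacement of the inverse map, by
#' damped fixed-point iteration with bilinear sampling of `u`.
#'
#' @param field a [deformation_field()].
#' @param iters iteration count.
#' @return the inverse [deformation_field()].
#' @export
invert_field <- function(field, iters = 50) {
  stopifnot(inherits(field, "deformation_field"))
  u <- field$displacements
  H <- dim(u)[1]; W <- dim(u)[2]
  ur <- u[, , 1]; uc <- u[, , 2]
  rr <- rep(seq_len(H) - 1, times = W)
  cc <- rep(seq_len(W) - 1, each = H)
  vr <- numeric(H * W); vc <- numeric(H * W)
  for (i in seq_len(iters)) {
    pr <- pmin(pmax(rr + vr, 0), H - 1)
    pc <- pmin(pmax(cc + vc, 0), W - 1)
    vr <- -cpp_bilinear(ur, pr, pc)
    vc <- -cpp_bilinear(uc, pr, pc)
  }
  out <- array(0, dim = c(H, W, 2))
  out[, , 1] <- matrix(vr, H, W)
  out[, , 2] <- matrix(vc, H, W)
  deformation_field(out)
}
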