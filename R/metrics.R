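as_region <- function(x) {
  if (is.list(x) && !is.null(x$region)) x <- x$region
  x <- as.matrix(x)
  matrix(as.logical(x), nrow(x), ncol(x))
}

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}, the region-overlap accuracy of two
#' binary ROIs.
#'
#' @param a,b logical matrices of identical shape (or lists with a `region`
#'   field).
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  if (!identical(dim(a), dim(b))) stop("shapes must match")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("DSC undefined: both masks empty")
  2 * sum(a & b) / (na + nb)
}

#' Root mean squared distance between corresponding landmarks
#'
#' \eqn{RMSD = \sqrt{(1/K)\sum_k \|\beta_{0k} - \beta_{1k}\|^2}} in mm;
#' correspondence is by list order.
#'
#' @param l0,l1 [landmark_set()]s (or K x 2 matrices in mm) of equal K.
#' @return RMSD in mm.
#' @export
rmsd <- function(l0, l1) {
  p0 <- if (inherits(l0, "landmark_set")) l0$points else as.matrix(l0)
  p1 <- if (inherits(l1, "landmark_set")) l1$points else as.matrix(l1)
  if (nrow(p0) != nrow(p1)) stop("landmark sets differ in K")
  sqrt(mean(rowSums((p0 - p1)^2)))
}

as_disp <- function(x) {
  if (inherits(x, "deformation_field")) x$displacements
  else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 2L) x
  else stop("expected a deformation_field or H x W x 2 array")
}

#' Mean deformation difference between two dense fields
#'
#' Mean over all pixels of the Euclidean norm of the per-pixel displacement
#' difference (px). This is the scalar deformation-error reading of the
#' ground-truth-vs-result comparison; the literal signed vector mean (in
#' which opposite errors cancel) is available as [mdd_signed()].
#'
#' @param d0,d1 [deformation_field()]s (or H x W x 2 arrays) of equal shape.
#' @return mean displacement difference in px.
#' @export
mdd <- function(d0, d1) {
  u0 <- as_disp(d0); u1 <- as_disp(d1)
  if (!identical(dim(u0), dim(u1))) stop("field shapes must match")
  mean(sqrt((u0[, , 1] - u1[, , 1])^2 + (u0[, , 2] - u1[, , 2])^2))
}

#' @rdname mdd
#' @return `mdd_signed`: the component-wise signed mean difference,
#'   `c(row, col)` in px.
#' @export
mdd_signed <- function(d0, d1) {
  u0 <- as_disp(d0); u1 <- as_disp(d1)
  if (!identical(dim(u0), dim(u1))) stop("field shapes must match")
  c(row = mean(u0[, , 1] - u1[, , 1]), col = mean(u0[, , 2] - u1[, , 2]))
}
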