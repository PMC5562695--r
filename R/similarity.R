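grid_values <- function(x) {
  if (inherits(x, "gray_image")) x$pixels else as.matrix(x)
}

#' Histogram mutual information and normalized mutual information
#'
#' Joint histogram with `bins` equal-width bins on each marginal's range
#' (over `mask` when given). MI is \eqn{H(A)+H(B)-H(A,B)} in bits; NMI is
#' Studholme's \eqn{(H(A)+H(B))/H(A,B)}, equal to 1 for independent and 2 for
#' bijectively related images.
#'
#' @param a,b matrices (or [gray_image()]s) of identical shape.
#' @param bins number of histogram bins per marginal (>= 2).
#' @param mask optional logical matrix restricting the histogram.
#' @return list with elements `mi` and `nmi` (bits / ratio).
#' @export
histogram_nmi <- function(a, b, bins = 32, mask = NULL) {
  a <- grid_values(a); b <- grid_values(b)
  if (!identical(dim(a), dim(b))) stop("shapes must match")
  if (bins < 2) stop("bins must be >= 2")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  a <- as.vector(a); b <- as.vector(b)
  ra <- range(a); rb <- range(b)
  if (diff(ra) <= 0 || diff(rb) <= 0)
    stop("NMI undefined for a constant image")
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins), 0), bins - 1)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins), 0), bins - 1)
  joint <- tabulate(ia * bins + ib + 1, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- p[p > 0]
  pa <- rowSums(matrix(p, bins, bins, byrow = TRUE))   # marginal of a
  pb <- colSums(matrix(p, bins, bins, byrow = TRUE))
  ha <- -sum(pa[pa > 0] * log2(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log2(pb[pb > 0]))
  hab <- -sum(pj * log2(pj))
  list(mi = ha + hb - hab, nmi = (ha + hb) / hab)
}

#' Mean pairwise NMI of two SE representations
#'
#' Average of [histogram_nmi()] over the 3 corresponding embedding vector
#' pairs; the Fig.-3-style similarity readout for one length scale.
#'
#' @param rep_f,rep_m `se_representation` objects of equal scale and shape.
#' @param bins histogram bins.
#' @return numeric scalar.
#' @export
mean_pairwise_nmi <- function(rep_f, rep_m, bins = 32) {
  stopifnot(inherits(rep_f, "se_representation"),
            inherits(rep_m, "se_representation"))
  if (rep_f$scale != rep_m$scale) stop("representations differ in scale")
  if (!identical(dim(rep_f$vectors), dim(rep_m$vectors)))
    stop("representation shapes differ")
  vals <- vapply(seq_len(dim(rep_f$vectors)[3]), function(j)
    histogram_nmi(rep_f$vectors[, , j], rep_m$vectors[, , j], bins)$nmi,
    numeric(1))
  mean(vals)
}

zscore_cols <- function(X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    s <- sd(X[, j])
    X[, j] <- if (is.finite(s) && s > 1e-300) (X[, j] - mean(X[, j])) / s else 0
  }
  X
}

#' kNN entropic-graph alpha-mutual-information estimator
#'
#' High-dimensional similarity measure used to drive multi-channel
#' registration,
#' \deqn{\hat{MI}_\alpha = \frac{1}{\alpha-1}\log\Big[\frac{1}{N}\sum_i
#'   \frac{1}{k}\sum_{j \in kNN(i)}\Big(\frac{d^{joint}(i,j)}
#'   {\sqrt{d^f(i,j)\, d^m(i,j)}}\Big)^{2\gamma}\Big]}
#' with \eqn{\gamma = d(1-\alpha)} and d the per-image channel count.
#'
#' Two neighbourhood constructions are provided. `"marginal"` (default, the
#' classical three-graph form) builds separate kNN graphs in the
#' fixed-channel, moving-channel and joint spaces and compares the j-th
#' smallest distances; it responds smoothly to the strength of dependence in
#' low dimensions. `"joint"` builds one kNN graph in the joint space and
#' evaluates all three distances on the same site pair; the per-edge ratio is
#' then bounded below by \eqn{\sqrt 2} (reached under perfect dependence) and
#' the form is robust to marginal-entropy changes of a warped sample, which
#' is why the registration driver uses it. Channels are z-scored before
#' distances. Larger values indicate stronger dependence; only differences
#' matter during optimization. Zero distances (duplicate sites) are floored
#' at 1e-12 and counted in a warning.
#'
#' @param joint_f,joint_m N x d matrices (or vectors) of channel samples at
#'   the same N sites.
#' @param alpha Renyi order in (0, 1); default 0.99.
#' @param k number of nearest neighbours (default 20, must be < N).
#' @param neighbours `"marginal"` (three kNN graphs) or `"joint"` (one joint
#'   graph, distances per edge).
#' @return numeric scalar similarity.
#' @export
alpha_mi_knn <- function(joint_f, joint_m, alpha = 0.99, k = 20,
                         neighbours = c("marginal", "joint")) {
  neighbours <- match.arg(neighbours)
  F_ <- zscore_cols(joint_f)
  M_ <- zscore_cols(joint_m)
  if (nrow(F_) != nrow(M_)) stop("samples must share N")
  N <- nrow(F_)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (k >= N) stop("k must be smaller than N")
  J <- cbind(F_, M_)
  if (neighbours == "joint") {
    idx <- cpp_knn_idx(J, k)
    dj <- cpp_pair_dist(J, idx)
    df <- cpp_pair_dist(F_, idx)
    dm <- cpp_pair_dist(M_, idx)
  } else {
    dj <- cpp_knn_dist(J, k)
    df <- cpp_knn_dist(F_, k)
    dm <- cpp_knn_dist(M_, k)
  }
  eps <- 1e-12
  nfloor <- sum(df < eps) + sum(dm < eps) + sum(dj < eps)
  if (nfloor > 0)
    warning(sprintf("%d zero kNN distances floored at %g", nfloor, eps))
  df[df < eps] <- eps; dm[dm < eps] <- eps; dj[dj < eps] <- eps
  d_img <- (ncol(F_) + ncol(M_)) / 2
  gam <- d_img * (1 - alpha)
  ratio <- dj / sqrt(df * dm)
  val <- mean(ratio^(2 * gam))
  log(val) / (alpha - 1)
}

# Parzen-windowed (linearly interpolated) joint-histogram MI in bits.
# Each sample spreads triangular-kernel weight over the 2x2 neighbouring
# bins, so the estimate is continuous and almost-everywhere differentiable in
# the sample values — a requirement for finite-difference optimization, where
# hard-binned MI is a staircase. Ranges are fixed by the caller so that
# perturbed evaluations share one binning.
parzen_mi <- function(a, b, bins, ra = range(a), rb = range(b)) {
  if (diff(ra) <= 0 || diff(rb) <= 0) return(0)
  fa <- (a - ra[1]) / diff(ra) * (bins - 1)
  fb <- (b - rb[1]) / diff(rb) * (bins - 1)
  fa <- pmin(pmax(fa, 0), bins - 1)
  fb <- pmin(pmax(fb, 0), bins - 1)
  ia <- pmin(floor(fa), bins - 2); wa <- fa - ia
  ib <- pmin(floor(fb), bins - 2); wb <- fb - ib
  idx <- function(i, j) i * bins + j + 1
  w <- c((1 - wa) * (1 - wb), wa * (1 - wb), (1 - wa) * wb, wa * wb)
  li <- c(idx(ia, ib), idx(ia + 1, ib), idx(ia, ib + 1), idx(ia + 1, ib + 1))
  P <- matrix(0, bins, bins)
  acc <- rowsum(w, li)
  P[as.integer(rownames(acc))] <- acc
  P <- P / sum(P)
  pa <- rowSums(P); pb <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log2(P[nz])) - sum(pa[pa > 0] * log2(pa[pa > 0])) -
    sum(pb[pb > 0] * log2(pb[pb > 0]))
}

#' Seeded uniform pixel-site sample from a mask
#'
#' Uniform sample without replacement of `n` mask pixels, returned as a
#' two-column (row, col) matrix of 1-based indices sorted row-major, so a
#' given seed always yields the identical site list.
#'
#' @param mask logical matrix.
#' @param n sample size (`<=` number of `TRUE` pixels).
#' @param seed integer seed.
#' @return n x 2 integer matrix with columns `row`, `col`.
#' @export
sample_sites <- function(mask, n, seed = 1L) {
  idx <- which(mask)
  if (n > length(idx)) stop("mask has fewer than n pixels")
  take <- with_seed(seed, sample(idx, n))
  H <- nrow(mask)
  r <- ((take - 1L) %% H) + 1L
  c <- ((take - 1L) %/% H) + 1L
  o <- order(r, c)
  cbind(row = r[o], col = c[o])
}
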