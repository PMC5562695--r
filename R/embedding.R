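#' Spectral-embedding representation
#'
#' Three ordered embedding coordinate images for one length scale, produced
#' jointly for a fixed/moving pair (one shared eigenbasis). Vectors are
#' min-max rescaled to \[0, 1\] over the whole (concatenated) domain.
#'
#' @name se_representation
#' @keywords internal
NULL

new_se_representation <- function(scale, vectors, eigenvalues, anchor_index,
                                  seed, mask = NULL, spacing = 1) {
  if (any(diff(eigenvalues) < -1e-12)) stop("eigenvalues must be ascending")
  if (any(eigenvalues < -1e-9)) stop("negative Laplacian eigenvalue")
  structure(list(scale = scale, vectors = vectors, eigenvalues = eigenvalues,
                 anchor_index = anchor_index, seed = seed, mask = mask,
                 spacing = spacing),
            class = "se_representation")
}

#' @export
print.se_representation <- function(x, ...) {
  cat(sprintf(
    "<se_representation> kappa = %d, %d x %d x 3, eigenvalues %s (seed %d)\n",
    x$scale, dim(x$vectors)[1], dim(x$vectors)[2],
    paste(signif(x$eigenvalues, 4), collapse = ", "), x$seed))
  invisible(x)
}

#' Spectrally embed an IC stack (Laplacian eigenmaps + Nystrom extension)
#'
#' `n_anchors` mask pixels are sampled (seeded, without replacement); a
#' Gaussian affinity \eqn{W_{ij} = \exp(-\|f_i-f_j\|^2/\sigma^2)} is built on
#' their IC vectors with \eqn{\sigma^2} the median squared pairwise distance
#' (floored so every anchor keeps at least one neighbour at affinity 1e-6);
#' eigenvectors 2..4 of the symmetric normalized graph Laplacian (ascending
#' eigenvalues, skipping the trivial constant one) give the 3 embedding
#' coordinates, extended to all pixels by the Nystrom out-of-sample formula.
#' Each vector is sign-fixed (positive skewness), clipped at its 0.5/99.5
#' percentiles and min-max rescaled to \[0, 1\] over the mask.
#'
#' Three robustness measures keep the eigenvectors from localizing on outlier
#' pixels instead of the shared structure: ICs are winsorized at their 1/99
#' percentiles, each IC is weighted by a logcosh negentropy proxy (the same
#' non-Gaussianity measure ICA maximizes, so noise-like components do not
#' dominate the Euclidean metric), and the affinity is density-normalized as
#' in diffusion maps.
#'
#' @param ics an `ic_stack` from [ica_reduce()].
#' @param n_vectors number of embedding vectors (3).
#' @param n_anchors anchor sample size (capped at the mask pixel count).
#' @param seed integer seed for the anchor sample.
#' @param sigma2 optional kernel bandwidth override.
#' @return an `se_representation`.
#' @export
spectral_embed <- function(ics, n_vectors = 3, n_anchors = 2000, seed = 1L,
                           sigma2 = NULL) {
  stopifnot(inherits(ics, "ic_stack"))
  d <- dim(ics$maps)
  C <- d[3]
  sel <- if (is.null(ics$mask)) rep(TRUE, d[1] * d[2]) else as.vector(ics$mask)
  Fall <- matrix(ics$maps, d[1] * d[2], C)[sel, , drop = FALSE]
  # winsorize each component: IC maps of noisy textures are heavy-tailed, and
  # without clipping the leading Laplacian eigenvectors localize on a handful
  # of outlier pixels instead of the shared structure
  for (j in seq_len(C)) {
    q <- quantile(Fall[, j], c(0.01, 0.99), names = FALSE)
    Fall[, j] <- pmin(pmax(Fall[, j], q[1]), q[2])
  }
  # salience weighting: whitened ICs all carry unit variance, so Euclidean
  # distances would let noise-like components drown the structured ones; each
  # component is scaled by its negentropy (logcosh proxy), the same
  # non-Gaussianity measure ICA maximizes
  gauss_ref <- 0.3745672074914381  # E[log cosh Z], Z ~ N(0,1)
  wts <- vapply(seq_len(C), function(j)
    (mean(log(cosh(Fall[, j]))) - gauss_ref)^2, numeric(1))
  if (max(wts) > 0) {
    wts <- wts / max(wts)
    Fall <- sweep(Fall, 2, sqrt(wts), "*")
  }
  npix <- nrow(Fall)
  n_anchors <- min(n_anchors, npix)
  if (n_anchors < n_vectors + 2)
    stop("n_anchors must be at least n_vectors + 2")
  anchors <- sort(with_seed(seed, sample.int(npix, n_anchors)))
  A <- Fall[anchors, , drop = FALSE]
  D2 <- cpp_cross_dist2(A, A)
  if (is.null(sigma2)) {
    off <- D2[upper.tri(D2)]
    sigma2 <- median(off)
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- max(mean(off), 1e-12)
    # connectivity floor: keep every anchor's nearest neighbour at affinity
    # >= 1e-6 so a single remote anchor cannot sever the graph numerically
    D2self <- D2; diag(D2self) <- Inf
    maxmin <- max(apply(D2self, 1, min))
    sigma2 <- max(sigma2, maxmin / log(1e6))
  }
  W <- exp(-D2 / sigma2)
  if (any(rowSums(W) - diag(W) < 1e-12))
    stop("disconnected affinity graph: an anchor has no neighbours")
  # density-invariant (diffusion-map) normalization: dividing the affinity by
  # the kernel density estimates stops the leading eigenvectors from simply
  # tracking sampling density / tight outlier clusters
  kd <- rowSums(W)
  W <- W / outer(kd, kd)
  deg <- rowSums(W)
  S <- W / sqrt(outer(deg, deg))
  eg <- eigen(S, symmetric = TRUE)                 # eigenvalues descending
  mu <- eg$values[2:(n_vectors + 1)]               # skip the trivial vector
  V <- eg$vectors[, 2:(n_vectors + 1), drop = FALSE]
  lam <- 1 - mu                                    # normalized-Laplacian eigs
  # a spectral value mu ~ 0 (Laplacian eigenvalue ~ 1) marks a degenerate
  # direction, e.g. duplicate anchors; its extension is defined as the zero
  # vector rather than an unstable 1/mu blow-up
  degen <- abs(mu) < 1e-12
  mu_safe <- ifelse(degen, 1, mu)
  # Nystrom extension to every mask pixel, in blocks
  Vs <- sweep(V, 1, sqrt(deg), "/")                # v_j / sqrt(d_j)
  emb <- matrix(0, npix, n_vectors)
  bs <- 4096L
  for (start in seq(1L, npix, by = bs)) {
    end <- min(start + bs - 1L, npix)
    Wx <- exp(-cpp_cross_dist2(Fall[start:end, , drop = FALSE], A) / sigma2)
    dx <- rowSums(Wx)
    if (any(dx <= 1e-300)) stop("pixel disconnected from all anchors")
    Wx <- Wx / outer(dx, kd)                       # density normalization
    dx1 <- rowSums(Wx)
    E <- (Wx %*% Vs) / sqrt(dx1)
    emb[start:end, ] <- sweep(E, 2, mu_safe, "/")
  }
  emb[, degen] <- 0
  # robust [0, 1] rescale: the Nystrom extension can spike at pixels far from
  # every anchor; clipping at the 0.5/99.5 percentiles keeps one stray pixel
  # from compressing the whole vector's dynamic range
  for (j in seq_len(n_vectors)) {
    v <- fix_sign(emb[, j])
    q <- quantile(v, c(0.005, 0.995), names = FALSE)
    if (q[2] > q[1]) v <- pmin(pmax(v, q[1]), q[2])
    emb[, j] <- rescale01(v)
  }
  vecs <- array(0, dim = c(d[1], d[2], n_vectors))
  flat <- matrix(0, d[1] * d[2], n_vectors)
  flat[sel, ] <- emb
  vecs[] <- flat
  new_se_representation(ics$scale, vecs, lam, anchors, as.integer(seed),
                        ics$mask, ics$spacing)
}

#' Build the joint SE representation of a pair at one length scale
#'
#' Runs the full per-scale representation pipeline: spatial concatenation,
#' texture features at scale `kappa` (windows kept within each half), ICA,
#' spectral embedding, and the split back into the two halves. Because the
#' embedding is computed once on the concatenated stack, the fixed and moving
#' representations share one eigenbasis and one \[0, 1\] value scale.
#'
#' @param pair a preprocessed [image_pair()].
#' @param kappa odd length scale.
#' @param cfg a [reg_config()] (uses `n_ics`, `n_anchors`, `glcm_levels`,
#'   `seed`).
#' @return list with `fixed` and `moving` `se_representation` objects.
#' @export
build_scale_representation <- function(pair, kappa, cfg = reg_config()) {
  stopifnot(inherits(pair, "image_pair"))
  cc <- concatenate_pair(pair)
  img <- gray_image(cc$pixels, cc$spacing, cc$mask)
  ts <- texture_stack(img, kappa, levels = cfg$glcm_levels,
                      split_column = cc$split_column)
  ics <- ica_reduce(ts, cfg$n_ics, seed = sub_seed(cfg$seed, kappa, 1L))
  se <- spectral_embed(ics, 3, cfg$n_anchors,
                       seed = sub_seed(cfg$seed, kappa, 2L))
  halves <- split_representation(se$vectors, cc$split_column)
  masks <- if (is.null(cc$mask)) list(fixed = NULL, moving = NULL)
           else split_representation(cc$mask, cc$split_column)
  list(fixed = new_se_representation(kappa, halves$fixed, se$eigenvalues,
                                     se$anchor_index, se$seed, masks$fixed,
                                     cc$spacing),
       moving = new_se_representation(kappa, halves$moving, se$eigenvalues,
                                      se$anchor_index, se$seed, masks$moving,
                                      cc$spacing))
}
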