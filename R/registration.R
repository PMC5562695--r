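#' Registration configuration
#'
#' Collects every tunable of the registration drivers. Defaults follow the
#' method's reference settings: \eqn{\alpha = 0.99}, k = 20 neighbours,
#' resolution schedule \eqn{\eta = 4, 2, 1} with 100 iterations per level
#' (the intensity baseline defaults to 1000), multi-scale set
#' \eqn{\kappa \in \{5, 7, 17\}}.
#'
#' @param alpha Renyi order of the alpha-MI similarity, in (0, 1).
#' @param knn neighbour count of the entropic-graph estimator.
#' @param resolution_levels strictly decreasing downsampling factors ending
#'   at 1.
#' @param iterations_per_level iterations per pyramid level; `NULL` lets each
#'   driver fill its own default (100, or 1000 for the intensity baseline).
#' @param scales length scales \eqn{\kappa} combined by MSERg.
#' @param n_ics independent components kept from the 9 texture maps.
#' @param n_anchors anchor pixels for the Nystrom spectral embedding.
#' @param sites_per_iter pixel sites sampled per iteration for the
#'   similarity.
#' @param grid_spacing B-spline control spacing in px (full resolution).
#' @param step_size optional base step unit (px) replacing `fd_step` as the
#'   ladder scale.
#' @param seed integer seed governing every random draw.
#' @param bins histogram bins (intensity MI and NMI readouts).
#' @param glcm_levels gray levels for co-occurrence quantization.
#' @param cp_per_iter control points perturbed per iteration for the
#'   finite-difference gradient.
#' @param fd_step central-difference step in px.
#' @param bending_weight weight of the control-lattice bending-energy
#'   penalty subtracted from the similarity; 0 disables regularization.
#' @return object of class `mserg_config`.
#' @export
reg_config <- function(alpha = 0.99, knn = 20, resolution_levels = c(4, 2, 1),
                       iterations_per_level = NULL, scales = c(5, 7, 17),
                       n_ics = 6, n_anchors = 2000, sites_per_iter = 2000,
                       grid_spacing = 16, step_size = NULL, seed = 1L,
                       bins = 32, glcm_levels = 16, cp_per_iter = 10,
                       fd_step = 1, bending_weight = 0.02) {
  if (bending_weight < 0) stop("bending_weight must be >= 0")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (knn < 1) stop("knn must be >= 1")
  if (length(resolution_levels) < 1 ||
      any(diff(resolution_levels) >= 0) ||
      resolution_levels[length(resolution_levels)] != 1)
    stop("resolution_levels must be strictly decreasing and end at 1")
  counts <- c(n_ics, n_anchors, sites_per_iter, grid_spacing, bins,
              glcm_levels, cp_per_iter)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (!is.null(iterations_per_level) && iterations_per_level <= 0)
    stop("iterations_per_level must be positive")
  if (any(scales %% 2 != 1 | scales < 3)) stop("scales must be odd and >= 3")
  structure(list(alpha = alpha, knn = knn,
                 resolution_levels = resolution_levels,
                 iterations_per_level = iterations_per_level,
                 scales = scales, n_ics = n_ics, n_anchors = n_anchors,
                 sites_per_iter = sites_per_iter, grid_spacing = grid_spacing,
                 step_size = step_size, seed = as.integer(seed), bins = bins,
                 glcm_levels = glcm_levels, cp_per_iter = cp_per_iter,
                 fd_step = fd_step, bending_weight = bending_weight),
            class = "mserg_config")
}

#' @export
print.mserg_config <- function(x, ...) {
  cat(sprintf(
    "<mserg_config> alpha %.3g, k %d, levels %s, iters/level %s, scales %s, seed %d\n",
    x$alpha, x$knn, paste(x$resolution_levels, collapse = "/"),
    if (is.null(x$iterations_per_level)) "driver default"
    else x$iterations_per_level,
    paste(x$scales, collapse = ","), x$seed))
  invisible(x)
}

as_channels <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("channels must be H x W x d")
  x
}

new_registration <- function(transform, trace, level_lengths, cfg, method,
                             similarity, warped_moving = NULL, scales = NULL) {
  field <- transform_to_field(transform)
  attr(trace, "level_lengths") <- level_lengths
  structure(list(transform = transform, field = field,
                 similarity_trace = trace, config_echo = cfg,
                 warped_moving = warped_moving, method = method,
                 similarity = similarity, scales = scales),
            class = "mserg_registration")
}

# Discrete bending energy of the control lattice: mean squared second
# difference of the coefficient grids (both components, both axes and the
# mixed term). A cheap convex proxy for the thin-plate bending integral that
# suppresses the spurious fold-inducing optima mutual information admits.
lattice_bending <- function(cR, cC) {
  be <- 0
  for (M in list(cR, cC)) {
    if (nrow(M) >= 3) be <- be + mean(diff(M, differences = 2)^2)
    if (ncol(M) >= 3) be <- be + mean(t(diff(t(M), differences = 2))^2)
    if (nrow(M) >= 2 && ncol(M) >= 2)
      be <- be + 2 * mean(diff(t(diff(M)))^2)
  }
  be
}

#' Multi-resolution multi-channel deformable registration
#'
#' Gradient-ascent optimization of a cubic B-spline free-form deformation
#' under a site-sampled similarity, over a Gaussian pyramid with downsampling
#' factors `cfg$resolution_levels` (channels smoothed with
#' \eqn{\sigma = \eta/2} before subsampling). One control grid, defined in
#' full-resolution pixel units, is optimized at every level. Gradients are
#' central finite differences on a seeded random subset of active control
#' points: each selected point is probed over a level-scaled step ladder
#' (4, 2, 1, 0.5 times `fd_step`, both signs, central differences) and moved
#' greedily to its best improving position; a control-lattice bending-energy
#' penalty (`bending_weight`) regularizes the warp. Fully deterministic
#' given `cfg$seed`.
#'
#' @param fixed_channels,moving_channels H x W x d arrays (a matrix is
#'   treated as d = 1).
#' @param cfg a [reg_config()].
#' @param similarity `"alpha_mi"` (any d) or `"histogram_mi"` (d = 1 only).
#' @param mask optional logical matrix restricting site sampling (fixed-image
#'   ROI).
#' @param iterations override of the per-level iteration count.
#' @param verbose print per-level progress to stderr.
#' @return object of class `mserg_registration`: `transform`, `field`,
#'   `similarity_trace` (one value per iteration actually run),
#'   `config_echo`, `warped_moving`, `method`.
#' @export
register_multichannel <- function(fixed_channels, moving_channels,
                                  cfg = reg_config(),
                                  similarity = c("alpha_mi", "histogram_mi"),
                                  mask = NULL, iterations = NULL,
                                  verbose = FALSE) {
  similarity <- match.arg(similarity)
  Fc <- as_channels(fixed_channels)
  Mc <- as_channels(moving_channels)
  if (!identical(dim(Fc), dim(Mc))) stop("channel stacks must match in shape")
  H <- dim(Fc)[1]; W <- dim(Fc)[2]; d <- dim(Fc)[3]
  if (similarity == "histogram_mi" && d != 1L)
    stop("histogram_mi similarity requires a single channel")
  iters <- iterations %||% cfg$iterations_per_level %||% 100L
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  t0 <- bspline_transform(cfg$grid_spacing, c(H, W))
  coefR <- t0$coefficients[, , 1]
  coefC <- t0$coefficients[, , 2]
  Gr <- nrow(coefR); Gc <- ncol(coefR)
  delta <- cfg$grid_spacing
  trace <- numeric(0)
  level_lengths <- integer(0)

  for (li in seq_along(cfg$resolution_levels)) {
    eta <- cfg$resolution_levels[li]
    Hl <- max(8L, as.integer(floor(H / eta)))
    Wl <- max(8L, as.integer(floor(W / eta)))
    Fl <- array(0, dim = c(Hl, Wl, d))
    Ml <- array(0, dim = c(Hl, Wl, d))
    for (ch in seq_len(d)) {
      fs <- if (eta > 1) gauss_smooth(Fc[, , ch], eta / 2) else Fc[, , ch]
      ms <- if (eta > 1) gauss_smooth(Mc[, , ch], eta / 2) else Mc[, , ch]
      Fl[, , ch] <- resize_bilinear(fs, Hl, Wl)
      Ml[, , ch] <- resize_bilinear(ms, Hl, Wl)
    }
    if (similarity == "alpha_mi") {
      # fixed per-channel standardization from the static images: re-scaling
      # per warped sample would couple the distance metric to the warp (a
      # smoother aligned sample gets its fluctuations amplified), biasing the
      # similarity toward the identity
      for (ch in seq_len(d)) {
        sf <- sd(Fl[, , ch]); sm <- sd(Ml[, , ch])
        if (sf > 1e-12) Fl[, , ch] <- (Fl[, , ch] - mean(Fl[, , ch])) / sf
        if (sm > 1e-12) Ml[, , ch] <- (Ml[, , ch] - mean(Ml[, , ch])) / sm
      }
    }
    mask_l <- resize_nearest(mask, Hl, Wl)
    if (!any(mask_l)) mask_l <- matrix(TRUE, Hl, Wl)
    rangeM <- range(Ml)
    n_run <- 0L
    stall <- 0L
    h <- (cfg$step_size %||% cfg$fd_step) * max(1, eta / 2)  # step unit, full-res px

    for (it in seq_len(iters) - 1L) {
      seed_it <- sub_seed(cfg$seed, li * 100003L, it)
      nsites <- min(cfg$sites_per_iter, sum(mask_l))
      sites <- sample_sites(mask_l, nsites, seed_it)
      # 0-based full-resolution coordinates, jittered off the pixel grid so
      # the exactly-on-grid identity pose holds no interpolation advantage
      jit <- with_seed(sub_seed(seed_it, 3L),
                       matrix(runif(2 * nsites, -0.5, 0.5), nsites, 2))
      fr <- (sites[, 1] - 0.5 + jit[, 1]) * H / Hl - 0.5
      fc <- (sites[, 2] - 0.5 + jit[, 2]) * W / Wl - 0.5
      fr <- pmin(pmax(fr, 0), H - 1)
      fc <- pmin(pmax(fc, 0), W - 1)
      flr <- (fr + 0.5) * Hl / H - 0.5
      flc <- (fc + 0.5) * Wl / W - 0.5
      Fmat <- matrix(0, nsites, d)
      for (ch in seq_len(d)) Fmat[, ch] <- cpp_bilinear(Fl[, , ch], flr, flc)
      rangeF <- range(Fmat)
      kuse <- min(cfg$knn, nsites - 1L)
      if (similarity == "alpha_mi") {
        # tiny seeded dither breaks the exact ties that flat regions of the
        # SE vectors produce; without it duplicate feature vectors give
        # degenerate kNN distances
        dither <- with_seed(sub_seed(seed_it, 13L),
                            matrix(rnorm(nsites * 2 * d, 0, 1e-5),
                                   nsites, 2 * d))
        Fz <- Fmat + dither[, seq_len(d), drop = FALSE]
        gam2 <- 2 * d * (1 - cfg$alpha)
      }

      moving_at <- function(cR, cC) {
        u <- cpp_bspline_disp(cR, cC, fr, fc, delta)
        lr <- (fr + u[, 1] + 0.5) * Hl / H - 0.5
        lc <- (fc + u[, 2] + 0.5) * Wl / W - 0.5
        Mmat <- matrix(0, nsites, d)
        for (ch in seq_len(d)) Mmat[, ch] <- cpp_bilinear(Ml[, , ch], lr, lc)
        Mmat
      }
      eval_sim <- function(cR, cC) {
        pen <- if (cfg$bending_weight > 0)
          cfg$bending_weight * lattice_bending(cR, cC) else 0
        Mmat <- moving_at(cR, cC)
        -pen + if (similarity == "alpha_mi") {
          Mz <- Mmat + dither[, d + seq_len(d), drop = FALSE]
          cpp_alpha_mi_joint(Fz, Mz, kuse, cfg$alpha, gam2)
        } else {
          parzen_mi(Fmat[, 1], Mmat[, 1], cfg$bins, ra = rangeF, rb = rangeM)
        }
      }

      S0 <- eval_sim(coefR, coefC)
      if (!is.finite(S0)) {
        cond <- simpleError("optimizer abort: non-finite similarity")
        cond$trace <- trace
        stop(cond)
      }
      trace <- c(trace, S0)
      n_run <- n_run + 1L

      # active control cells: those supporting at least one site
      i0 <- floor(fr / delta); j0 <- floor(fc / delta)
      ii <- pmin(pmax(outer(i0, 0:3, "+"), 0), Gr - 1)
      jj <- pmin(pmax(outer(j0, 0:3, "+"), 0), Gc - 1)
      cells <- unique(cbind(
        as.vector(ii[, rep(1:4, times = 4)]),
        as.vector(jj[, rep(1:4, each = 4)])))
      ncell <- nrow(cells)
      pick <- with_seed(sub_seed(seed_it, 7L),
                        sample.int(ncell, min(cfg$cp_per_iter, ncell)))
      cells <- cells[pick, , drop = FALSE]
      # greedy coordinate ascent: every selected control point is probed by
      # central differences over a level-scaled step ladder and moved to the
      # best improving position; common site samples make the comparisons
      # noise-free within an iteration, fresh sites next iteration undo any
      # overfit to this sample
      ladder <- if (similarity == "alpha_mi") h * c(2, 1)
                else h * c(4, 2, 1, 0.5)
      Scur <- S0
      moved <- FALSE
      # bulk move first: shifting every control point together is free of
      # bending penalty and captures the translational component that
      # single-point moves would each have to pay for
      for (comp in 1:2) {
        best_gain <- 0
        best_delta <- 0
        for (sz in ladder) {
          for (sgn in c(1, -1)) {
            cR2 <- coefR; cC2 <- coefC
            if (comp == 1) cR2 <- cR2 + sgn * sz else cC2 <- cC2 + sgn * sz
            v <- eval_sim(cR2, cC2)
            if (is.finite(v) && v - Scur > best_gain) {
              best_gain <- v - Scur
              best_delta <- sgn * sz
            }
          }
          if (best_delta != 0) break
        }
        if (best_delta != 0) {
          if (comp == 1) coefR <- coefR + best_delta
          else coefC <- coefC + best_delta
          Scur <- Scur + best_gain
          moved <- TRUE
        }
      }
      for (ci in seq_len(nrow(cells))) {
        gi <- cells[ci, 1] + 1L; gj <- cells[ci, 2] + 1L
        for (comp in 1:2) {
          best_gain <- 0
          best_delta <- 0
          for (sz in ladder) {
            for (sgn in c(1, -1)) {
              cR2 <- coefR; cC2 <- coefC
              if (comp == 1) cR2[gi, gj] <- cR2[gi, gj] + sgn * sz
              else cC2[gi, gj] <- cC2[gi, gj] + sgn * sz
              v <- eval_sim(cR2, cC2)
              if (is.finite(v) && v - Scur > best_gain) {
                best_gain <- v - Scur
                best_delta <- sgn * sz
              }
            }
            if (best_delta != 0) break   # refine no further once improving
          }
          if (best_delta != 0) {
            if (comp == 1) coefR[gi, gj] <- coefR[gi, gj] + best_delta
            else coefC[gi, gj] <- coefC[gi, gj] + best_delta
            Scur <- Scur + best_gain
            moved <- TRUE
          }
        }
      }
      if (moved) stall <- 0L else stall <- stall + 1L
      if (stall >= 5L) break  # five move-free sweeps: the level has settled
    }
    level_lengths <- c(level_lengths, n_run)
    if (verbose)
      message(sprintf("level eta=%g done: %d iters, similarity %.6g -> %.6g",
                      eta, n_run, trace[length(trace) - n_run + 1L],
                      trace[length(trace)]))
  }

  coef <- array(0, dim = c(Gr, Gc, 2))
  coef[, , 1] <- coefR
  coef[, , 2] <- coefC
  transform <- bspline_transform(cfg$grid_spacing, c(H, W), coef)
  cfg_echo <- cfg
  cfg_echo$iterations_per_level <- iters
  warped <- warp_image(gray_image(Mc[, , 1]), transform)
  new_registration(transform, trace, level_lengths, cfg_echo,
                   "multichannel", similarity, warped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intensity-based baseline registration (histogram MI)
#'
#' Registers the raw intensity pair with histogram mutual information as the
#' similarity; defaults to 1000 iterations per resolution level.
#'
#' @param pair a preprocessed [image_pair()].
#' @param cfg a [reg_config()].
#' @return an `mserg_registration`.
#' @export
register_intensity <- function(pair, cfg = reg_config(), verbose = FALSE) {
  stopifnot(inherits(pair, "image_pair"))
  iters <- cfg$iterations_per_level %||% 1000L
  res <- register_multichannel(rescale01(pair$fixed$pixels),
                               rescale01(pair$moving$pixels),
                               cfg, similarity = "histogram_mi",
                               mask = pair$fixed$mask, iterations = iters,
                               verbose = verbose)
  res$method <- "intensity"
  res$warped_moving <- warp_image(pair$moving, res$transform)
  res
}

#' Spectral-embedding representation registration (SSERg / MSERg)
#'
#' Builds the joint SE representation of the pair at every requested length
#' scale, stacks the `3 * length(scales)` embedding channels, and registers
#' them under the kNN entropic-graph alpha-MI similarity. One scale gives
#' SSERg, several (default \eqn{\kappa \in \{5, 7, 17\}}) give MSERg.
#'
#' @param pair a preprocessed [image_pair()].
#' @param scales odd length scales; defaults to `cfg$scales`.
#' @param cfg a [reg_config()].
#' @return an `mserg_registration` (with a `scales` field).
#' @export
register_serg <- function(pair, scales = NULL, cfg = reg_config(), verbose = FALSE) {
  stopifnot(inherits(pair, "image_pair"))
  scales <- scales %||% cfg$scales
  if (length(scales) < 1) stop("need at least one scale")
  H <- nrow(pair$fixed$pixels); W <- ncol(pair$fixed$pixels)
  d <- 3L * length(scales)
  Fc <- array(0, dim = c(H, W, d))
  Mc <- array(0, dim = c(H, W, d))
  for (si in seq_along(scales)) {
    rep2 <- build_scale_representation(pair, scales[si], cfg)
    Fc[, , (si - 1) * 3 + 1:3] <- rep2$fixed$vectors
    Mc[, , (si - 1) * 3 + 1:3] <- rep2$moving$vectors
  }
  iters <- cfg$iterations_per_level %||% 100L
  res <- register_multichannel(Fc, Mc, cfg, similarity = "alpha_mi",
                               mask = pair$fixed$mask, iterations = iters,
                               verbose = verbose)
  res$method <- if (length(scales) == 1L) "sserg" else "mserg"
  res$scales <- scales
  res$warped_moving <- warp_image(pair$moving, res$transform)
  res
}

#' Register a fixed/moving image pair (front door)
#'
#' Preprocesses the pair (resolution matching, padding) and dispatches to the
#' requested driver.
#'
#' @param fixed,moving [gray_image()]s.
#' @param method `"mserg"` (multi-scale SE), `"sserg"` (single scale) or
#'   `"intensity"` (histogram-MI baseline).
#' @param scales length scales for the SE drivers; defaults to `cfg$scales`
#'   (`"sserg"` uses the first element).
#' @param cfg a [reg_config()].
#' @return an `mserg_registration`.
#' @export
mserg_register <- function(fixed, moving,
                           method = c("mserg", "sserg", "intensity"),
                           scales = NULL, cfg = reg_config()) {
  method <- match.arg(method)
  pair <- preprocess_pair(fixed, moving)
  switch(method,
         intensity = register_intensity(pair, cfg),
         sserg = register_serg(pair, (scales %||% cfg$scales)[1], cfg),
         mserg = register_serg(pair, scales %||% cfg$scales, cfg))
}

#' Learning-set length-scale selection
#'
#' Runs single-scale SE registration for every candidate scale on every
#' learning pair, scores each scale by mean Dice (ROI ground truth) or mean
#' negative mean-deformation-difference (field ground truth), and returns the
#' candidates ranked by mean score with the top `top` marked selected. Ties
#' break toward the smaller scale.
#'
#' @param learning_pairs list of entries, each a list with `pair` (an
#'   [image_pair()]) and `truth`: either a [deformation_field()] or a list
#'   with logical `fixed_roi` and `moving_roi` masks. Ground-truth types may
#'   not be mixed.
#' @param candidates candidate odd scales (length >= `top`).
#' @param cfg a [reg_config()].
#' @param top number of scales to select.
#' @param score_fun optional override `function(entry, kappa, cfg)` returning
#'   a score (larger is better); used by tests to stub the scoring.
#' @return data.frame with columns `kappa`, `score`, `rank`, `selected`,
#'   ordered best first.
#' @export
select_scales <- function(learning_pairs, candidates, cfg = reg_config(),
                          top = 3, score_fun = NULL) {
  if (length(learning_pairs) < 1) stop("need at least one learning pair")
  if (length(candidates) < top) stop("need at least `top` candidate scales")
  types <- vapply(learning_pairs, function(e) {
    if (is.null(score_fun) && is.null(e$truth)) stop("entry lacks truth")
    if (inherits(e$truth, "deformation_field")) "field"
    else if (is.list(e$truth) && !is.null(e$truth$fixed_roi)) "roi"
    else "other"
  }, character(1))
  if (is.null(score_fun)) {
    if (length(unique(types)) != 1L || types[1] == "other")
      stop("mixed or unknown ground-truth types in the learning set")
  }
  score_one <- score_fun %||% function(entry, kappa, cfg) {
    res <- register_serg(entry$pair, kappa, cfg)
    if (inherits(entry$truth, "deformation_field")) {
      -mdd(entry$truth, res$field)
    } else {
      warped <- warp_mask(entry$truth$moving_roi, res$transform)
      dice(entry$truth$fixed_roi, warped)
    }
  }
  scores <- vapply(candidates, function(kap)
    mean(vapply(learning_pairs, score_one, numeric(1), kappa = kap,
                cfg = cfg)),
    numeric(1))
  o <- order(-scores, candidates)
  data.frame(kappa = candidates[o], score = scores[o],
             rank = seq_along(candidates),
             selected = seq_along(candidates) <= top)
}
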