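#' Specification of a synthetic multimodal phantom
#'
#' The generator emulates a pair of images of one shared anatomy rendered
#' under two different modalities: smooth random blobs inside a capsule-like
#' boundary with a small dark interior structure (the urethra analogue),
#' rendered as modality A (fine grain) and as a nonlinear intensity remap of
#' the same anatomy with coarser grain as modality B. The `bands` remap is
#' many-to-one and deliberately destroys the intensity relationship that
#' histogram MI relies on.
#'
#' @param size image shape `c(H, W)`, each >= 32.
#' @param n_blobs number of smooth anatomy components.
#' @param texture_strength grain amplitude per modality (length 1 or 2).
#' @param noise_sd Gaussian noise sd per modality (length 1 or 2, >= 0).
#' @param remap modality-B intensity mapping: `"invert"`, `"gamma"` or
#'   `"bands"`.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128, 128), n_blobs = 6,
                         texture_strength = c(0.08, 0.22),
                         noise_sd = 0.05,
                         remap = c("bands", "invert", "gamma"),
                         seed = 1L) {
  remap <- match.arg(remap)
  if (any(size < 32)) stop("phantom must be at least 32 x 32")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  texture_strength <- rep(texture_strength, length.out = 2)
  noise_sd <- rep(noise_sd, length.out = 2)
  structure(list(size = as.integer(size[1:2]), n_blobs = n_blobs,
                 texture_strength = texture_strength, noise_sd = noise_sd,
                 remap = remap, seed = as.integer(seed)),
            class = "phantom_spec")
}

remap_intensity <- function(x, kind) {
  switch(kind,
         invert = 1 - x,
         gamma = x^2.2,
         bands = 0.5 * (1 - cos(2 * pi * 3 * x)),
         stop("unknown remap: ", kind))
}

# Band-pass grain: difference of Gaussian-smoothed white noise, unit sd.
make_grain <- function(H, W, sigma_fine, sigma_coarse) {
  n <- matrix(rnorm(H * W), H, W)
  g <- gauss_smooth(n, sigma_fine) - gauss_smooth(n, sigma_coarse)
  s <- sd(as.vector(g))
  if (s > 0) g / s else g
}

#' Generate a seeded multimodal phantom pair with ROI ground truth
#'
#' @param spec a [phantom_spec()].
#' @return object of class `mserg_phantom`: `pair` (an [image_pair()], both
#'   modalities in \[0, 1\]), `rois` (logical `capsule` and `interior`
#'   masks), `anatomy` (the shared noiseless anatomy) and `spec`.
#' @export
make_multimodal_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  out <- with_seed(spec$seed, {
    rg <- seq(0, 1, length.out = H)
    cg <- seq(0, 1, length.out = W)
    R <- matrix(rep(rg, times = W), H, W)
    C <- matrix(rep(cg, each = H), H, W)
    # smooth random blobs
    anat <- matrix(0, H, W)
    for (i in seq_len(spec$n_blobs)) {
      cr <- runif(1, 0.2, 0.8); cc <- runif(1, 0.2, 0.8)
      s <- runif(1, 0.06, 0.18); a <- runif(1, 0.4, 1)
      anat <- anat + a * exp(-((R - cr)^2 + (C - cc)^2) / (2 * s^2))
    }
    # capsule: elliptical organ boundary with a soft edge; its position and
    # axes vary across seeds so two independent phantoms share little layout
    kr <- runif(1, 0.40, 0.60); kc <- runif(1, 0.40, 0.60)
    ar <- runif(1, 0.22, 0.38); ac <- runif(1, 0.22, 0.38)
    e <- ((R - kr) / ar)^2 + ((C - kc) / ac)^2
    capsule <- e <= 1
    edge <- 1 / (1 + exp((e - 1) / 0.08))
    anat <- 0.25 + 0.5 * rescale01(anat) * edge + 0.25 * edge
    # interior structure (urethra analogue): small dark disc near the center
    ur <- kr + runif(1, -0.08, 0.08); uc <- kc + runif(1, -0.08, 0.08)
    rad <- runif(1, 0.035, 0.05)
    interior <- ((R - ur)^2 + (C - uc)^2) <= rad^2
    anat[interior] <- anat[interior] - 0.3
    anat <- rescale01(anat)
    A <- anat
    B <- remap_intensity(anat, spec$remap)
    # modality-specific grain patterns (independent draws), but with local
    # amplitude modulated by the shared anatomy: in real tissue the texture
    # statistics follow the tissue type, which is exactly the structural cue
    # fine-scale texture features are meant to pick up in either modality
    tex_mod <- 0.25 + 0.75 * anat
    if (spec$texture_strength[1] > 0)
      A <- A + spec$texture_strength[1] * tex_mod * make_grain(H, W, 0.8, 1.6)
    if (spec$texture_strength[2] > 0)
      B <- B + spec$texture_strength[2] * tex_mod * make_grain(H, W, 2.0, 4.0)
    if (spec$noise_sd[1] > 0) A <- A + matrix(rnorm(H * W, 0, spec$noise_sd[1]), H, W)
    if (spec$noise_sd[2] > 0) B <- B + matrix(rnorm(H * W, 0, spec$noise_sd[2]), H, W)
    A <- pmin(pmax(A, 0), 1)
    B <- pmin(pmax(B, 0), 1)
    list(A = A, B = B, anatomy = anat,
         rois = list(capsule = capsule, interior = interior))
  })
  structure(list(pair = image_pair(gray_image(out$A, 1),
                                   gray_image(out$B, 1)),
                 rois = out$rois, anatomy = out$anatomy, spec = spec),
            class = "mserg_phantom")
}

#' @export
print.mserg_phantom <- function(x, ...) {
  cat(sprintf("<mserg_phantom> %d x %d, remap '%s', noise sd %s (seed %d)\n",
              x$spec$size[1], x$spec$size[2], x$spec$remap,
              paste(x$spec$noise_sd, collapse = "/"), x$spec$seed))
  invisible(x)
}

#' Deform modality B of a phantom with a known B-spline warp
#'
#' Draws a seeded [random_bspline_transform()], warps modality B and its ROIs
#' with it, and returns modality A as the fixed image, warped B as the moving
#' image, and the ground-truth deformation `truth`: the dense field a perfect
#' registration of moving onto fixed would recover (the inverse of the
#' applied displacement, obtained by fixed-point iteration). The raw applied
#' field is returned as `induced_field`.
#'
#' @param x an `mserg_phantom` (or an [image_pair()]).
#' @param grid_spacing control spacing of the induced warp in px.
#' @param max_disp maximum control displacement in px.
#' @param seed integer seed.
#' @return list with `fixed`, `moving` ([gray_image()]s), `truth`
#'   ([deformation_field()]), `rois` (`fixed` and `moving` ROI lists),
#'   `transform` and `induced_field`.
#' @export
make_deformed_case <- function(x, grid_spacing = 32, max_disp = 8, seed = 1L) {
  if (inherits(x, "mserg_phantom")) {
    pair <- x$pair; rois <- x$rois
  } else if (inherits(x, "image_pair")) {
    pair <- x; rois <- NULL
  } else stop("x must be an mserg_phantom or image_pair")
  fixed <- pair$fixed
  B <- pair$moving
  t <- random_bspline_transform(dim(B$pixels), grid_spacing, max_disp, seed)
  induced <- transform_to_field(t)
  moving <- warp_image(B, t)
  truth <- if (max_disp > 0) invert_field(induced)
           else deformation_field(induced$displacements)
  rois_out <- NULL
  if (!is.null(rois)) {
    ur <- as.vector(induced$displacements[, , 1])
    uc <- as.vector(induced$displacements[, , 2])
    rois_out <- list(fixed = rois,
                     moving = lapply(rois, warp_mask_with_disp, ur = ur, uc = uc))
  }
  list(fixed = fixed, moving = moving, truth = truth, rois = rois_out,
       transform = t, induced_field = induced)
}
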