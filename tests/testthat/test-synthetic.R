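test_that("pure invert remap without texture or noise gives B = 1 - A", {
  sp <- phantom_spec(size = c(64, 64), texture_strength = 0, noise_sd = 0,
                     remap = "invert", seed = 3)
  ph <- make_multimodal_phantom(sp)
  expect_equal(ph$pair$moving$pixels, 1 - ph$pair$fixed$pixels)
  expect_true(all(ph$pair$fixed$pixels >= 0 & ph$pair$fixed$pixels <= 1))
})

test_that("phantoms are seeded and carry ROI masks", {
  p1 <- make_multimodal_phantom(phantom_spec(seed = 9))
  p2 <- make_multimodal_phantom(phantom_spec(seed = 9))
  expect_identical(p1$pair$fixed$pixels, p2$pair$fixed$pixels)
  expect_identical(p1$pair$moving$pixels, p2$pair$moving$pixels)
  expect_gt(sum(p1$rois$capsule), 0)
  expect_gt(sum(p1$rois$interior), 0)
  expect_true(all(p1$rois$interior | !p1$rois$interior))
  p3 <- make_multimodal_phantom(phantom_spec(seed = 10))
  expect_false(identical(p1$pair$fixed$pixels, p3$pair$fixed$pixels))
})

test_that("bands remap destroys more intensity information than invert", {
  vals <- sapply(1:6, function(s) {
    nb <- histogram_nmi(
      make_multimodal_phantom(phantom_spec(seed = s, remap = "bands",
                                           noise_sd = 0.05))$pair$fixed$pixels,
      make_multimodal_phantom(phantom_spec(seed = s, remap = "bands",
                                           noise_sd = 0.05))$pair$moving$pixels)$mi
    ni <- histogram_nmi(
      make_multimodal_phantom(phantom_spec(seed = s, remap = "invert",
                                           noise_sd = 0.05))$pair$fixed$pixels,
      make_multimodal_phantom(phantom_spec(seed = s, remap = "invert",
                                           noise_sd = 0.05))$pair$moving$pixels)$mi
    c(nb, ni)
  })
  expect_true(all(vals[1, ] < vals[2, ]))
})

test_that("deformed cases expose the recovery target and warped ROIs", {
  ph <- make_multimodal_phantom(phantom_spec(seed = 4))
  case0 <- make_deformed_case(ph, grid_spacing = 32, max_disp = 0, seed = 1)
  expect_true(all(case0$truth$displacements == 0))
  expect_equal(case0$moving$pixels, ph$pair$moving$pixels)

  case <- make_deformed_case(ph, grid_spacing = 32, max_disp = 8, seed = 1)
  zero <- deformation_field(array(0, dim = dim(case$truth$displacements)))
  expect_gt(mdd(case$truth, zero), 0)
  expect_identical(case$fixed$pixels, ph$pair$fixed$pixels)
  # warped ROI overlap with the unwarped ROI shrinks as max_disp grows
  dscs <- sapply(c(2, 4, 8), function(md) {
    cs <- make_deformed_case(ph, grid_spacing = 32, max_disp = md, seed = 6)
    dice(cs$rois$fixed$capsule, cs$rois$moving$capsule)
  })
  expect_true(all(diff(dscs) < 0))
})

test_that("truth field inverts the induced warp (round-trip ROI overlap)", {
  ph <- make_multimodal_phantom(phantom_spec(seed = 5))
  case <- make_deformed_case(ph, grid_spacing = 32, max_disp = 8, seed = 2)
  roi <- case$rois$fixed$capsule
  warped <- case$rois$moving$capsule                 # roi warped by induced
  back <- warp_mask(warped, case$truth)              # un-warp with truth
  expect_gt(dice(roi, back), 0.99)
})

test_that("generator calibration: deformed bands pair is as uninformative as
           an independent phantom for intensity MI", {
  mis <- sapply(1:10, function(s) {
    ph <- make_multimodal_phantom(phantom_spec(seed = s))
    case <- make_deformed_case(ph, 32, 8, seed = s + 100)
    ind <- make_multimodal_phantom(phantom_spec(seed = s + 500))
    c(def = histogram_nmi(case$fixed$pixels, case$moving$pixels)$mi,
      indep = histogram_nmi(ph$pair$fixed$pixels, ind$pair$fixed$pixels)$mi)
  })
  ratio <- mean(mis["def", ]) / mean(mis["indep", ])
  expect_lt(abs(ratio - 1), 0.1)
})
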