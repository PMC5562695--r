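fast_cfg <- function(seed = 1, iterations_per_level = 10) {
  reg_config(iterations_per_level = iterations_per_level,
             sites_per_iter = 200, cp_per_iter = 6, n_anchors = 200,
             seed = seed)
}

test_that("reg_config validates its invariants", {
  expect_error(reg_config(alpha = 1), "alpha")
  expect_error(reg_config(resolution_levels = c(2, 4, 1)), "decreasing")
  expect_error(reg_config(resolution_levels = c(4, 2)), "decreasing")
  expect_error(reg_config(knn = 0), "knn")
  expect_error(reg_config(scales = c(4, 7)), "odd")
  cfg <- reg_config()
  expect_equal(cfg$alpha, 0.99)
  expect_equal(cfg$knn, 20)
  expect_equal(cfg$resolution_levels, c(4, 2, 1))
  expect_equal(cfg$scales, c(5, 7, 17))
})

test_that("registering an identical pair stays at the identity", {
  px <- smooth_phantom(48, 48, seed = 3)
  cfg <- fast_cfg(seed = 5)
  r <- register_multichannel(px, px, cfg, similarity = "histogram_mi")
  expect_lt(mean(mserg:::field_norms(r$field)), 0.5)
  expect_s3_class(r, "mserg_registration")
  expect_length(r$similarity_trace, sum(attr(r$similarity_trace,
                                             "level_lengths")))
})

test_that("intensity driver defaults to 1000 iterations per level", {
  px <- matrix(2, 8, 8)   # degenerate similarity: optimizer idles cheaply
  pair <- image_pair(gray_image(px), gray_image(px))
  cfg <- reg_config(resolution_levels = c(1), sites_per_iter = 30,
                    cp_per_iter = 1, n_anchors = 50)
  r <- register_intensity(pair, cfg)
  expect_equal(r$config_echo$iterations_per_level, 1000)
  # the degenerate constant pair stalls immediately, so few iterations run;
  # the trace still matches the iterations actually executed
  expect_length(r$similarity_trace,
                sum(attr(r$similarity_trace, "level_lengths")))
  expect_equal(r$method, "intensity")
})

test_that("drivers are deterministic given the seed", {
  px <- smooth_phantom(48, 48, seed = 7)
  mv <- matrix(0, 48, 48)
  mv[, 3:48] <- px[, 1:46]
  cfg <- fast_cfg(seed = 11, iterations_per_level = 5)
  r1 <- register_multichannel(px, mv, cfg, similarity = "histogram_mi")
  r2 <- register_multichannel(px, mv, cfg, similarity = "histogram_mi")
  expect_identical(r1$transform$coefficients, r2$transform$coefficients)
  expect_identical(r1$similarity_trace, r2$similarity_trace)
})

test_that("SE drivers stack 3 channels per scale and label the method", {
  set.seed(21)
  px <- smooth_phantom(48, 48, seed = 9) +
    matrix(rnorm(48 * 48, 0, 0.03), 48, 48)
  pair <- preprocess_pair(gray_image(px),
                          gray_image(1 - px))
  cfg <- fast_cfg(seed = 3, iterations_per_level = 2)
  r1 <- register_serg(pair, scales = 5, cfg)
  expect_equal(r1$method, "sserg")
  expect_equal(r1$scales, 5)
  r2 <- register_serg(pair, scales = c(3, 5), cfg)
  expect_equal(r2$method, "mserg")
  expect_equal(r2$scales, c(3, 5))
  expect_s3_class(r2$warped_moving, "gray_image")
})

test_that("registration results expose the fitted-model interface", {
  px <- smooth_phantom(40, 40, seed = 12)
  cfg <- fast_cfg(seed = 2, iterations_per_level = 3)
  r <- register_multichannel(px, px, cfg, similarity = "histogram_mi")
  expect_equal(dim(coef(r)), dim(r$transform$coefficients))
  pr <- predict(r, gray_image(px))
  expect_s3_class(pr, "gray_image")
  expect_output(print(r), "mserg_registration")
  s <- summary(r)
  expect_s3_class(s, "summary.mserg_registration")
  expect_output(print(s), "Registration method")
})

test_that("select_scales ranks by injected scores with small-kappa ties", {
  entries <- list(list(pair = NULL, truth = NULL))
  scores <- c(`3` = 0.9, `5` = 0.8, `7` = 0.7, `9` = 0.1, `11` = 0.1,
              `13` = 0.1, `15` = 0.1, `17` = 0.1)
  sf <- function(entry, kappa, cfg) unname(scores[as.character(kappa)])
  sel <- select_scales(entries, c(3, 5, 7, 9, 11, 13, 15, 17),
                       reg_config(), top = 3, score_fun = sf)
  expect_equal(sel$kappa[sel$selected], c(3, 5, 7))
  expect_equal(sel$rank, 1:8)
  # equal scores: the three smallest scales win
  sf0 <- function(entry, kappa, cfg) 1
  sel0 <- select_scales(entries, c(17, 3, 9, 5), reg_config(), top = 3,
                        score_fun = sf0)
  expect_equal(sel0$kappa[sel0$selected], c(3, 5, 9))
  # deterministic reruns
  sel1 <- select_scales(entries, c(3, 5, 7, 9), reg_config(), top = 2,
                        score_fun = sf)
  sel2 <- select_scales(entries, c(3, 5, 7, 9), reg_config(), top = 2,
                        score_fun = sf)
  expect_identical(sel1, sel2)
})

test_that("select_scales scores real pairs by ROI dice or field mdd", {
  ph <- make_multimodal_phantom(phantom_spec(size = c(64, 64), seed = 31))
  case <- make_deformed_case(ph, grid_spacing = 32, max_disp = 4, seed = 32)
  pair <- preprocess_pair(case$fixed, case$moving)
  cfg <- fast_cfg(seed = 4, iterations_per_level = 2)
  entries <- list(list(pair = pair, truth = case$truth))
  sel <- select_scales(entries, c(3, 5, 7), cfg, top = 2)
  expect_equal(nrow(sel), 3)
  expect_true(all(sel$score <= 0))    # negative mdd scoring
  expect_equal(sum(sel$selected), 2)
  # mixed truth types are rejected
  entries2 <- list(
    list(pair = pair, truth = case$truth),
    list(pair = pair, truth = list(fixed_roi = case$rois$fixed$capsule,
                                   moving_roi = case$rois$moving$capsule)))
  expect_error(select_scales(entries2, c(3, 5, 7), cfg), "mixed")
})

test_that("mserg_register front door dispatches and preprocesses", {
  ph <- make_multimodal_phantom(phantom_spec(size = c(64, 64), seed = 41))
  cfg <- fast_cfg(seed = 6, iterations_per_level = 2)
  r <- mserg_register(ph$pair$fixed, ph$pair$moving, method = "sserg",
                      scales = 5, cfg = cfg)
  expect_equal(r$method, "sserg")
  r2 <- mserg_register(ph$pair$fixed, ph$pair$moving, method = "intensity",
                       cfg = fast_cfg(seed = 6, iterations_per_level = 3))
  expect_equal(r2$method, "intensity")
})
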