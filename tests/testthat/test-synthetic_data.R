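test_that("phantoms render the spec intensities and are reproducible", {
  # zero noise, no bias, no texture: exactly n_classes foreground levels
  spec <- phantom_spec(shape = c(48, 48), noise_sd = c(0, 0), bias_amp = 0,
                       texture_amp = c(0, 0))
  ph <- make_phantom(spec, seed = 3)
  fg <- ph$A$pixels[ph$A$mask]
  expect_lte(length(unique(fg)), spec$n_classes)
  expect_true(all(ph$A$pixels[!ph$A$mask] == 0))
  # same seed, identical phantom
  ph2 <- make_phantom(spec, seed = 3)
  expect_identical(ph$A$pixels, ph2$A$pixels)
  expect_identical(ph$B$pixels, ph2$B$pixels)
  # 8-bit quantisation
  expect_true(all(ph$A$pixels == round(ph$A$pixels)))
  expect_true(max(ph$A$pixels) <= 255 && min(ph$A$pixels) >= 0)
  # the modalities correlate only through the label map: per-class rank
  # order follows the spec in each modality independently
  specn <- phantom_spec(shape = c(48, 48), noise_sd = c(2, 2),
                        bias_amp = 0, texture_amp = c(0, 0))
  phn <- make_phantom(specn, seed = 4)
  mean_a <- vapply(1:3, function(k) mean(phn$A$pixels[phn$labels == k]),
                   numeric(1))
  mean_b <- vapply(1:3, function(k) mean(phn$B$pixels[phn$labels == k]),
                   numeric(1))
  expect_equal(order(mean_a), order(specn$int_a))
  expect_equal(order(mean_b), order(specn$int_b))
  # non-monotone class mapping: A and B are not affinely related
  expect_lt(abs(cor(phn$A$pixels[phn$A$mask], phn$B$pixels[phn$B$mask])),
            0.9)
})

test_that("synthetic pairs are reproducible and internally consistent", {
  spec <- small_phantom_spec(48)
  pr <- make_pair(spec, sigma_v = 10, seed = 5, n_landmarks = 5)
  pr2 <- make_pair(spec, sigma_v = 10, seed = 5, n_landmarks = 5)
  expect_identical(pr$M$pixels, pr2$M$pixels)
  expect_identical(pr$field_true$dx, pr2$field_true$dx)
  expect_identical(pr$landmarks$mri, pr2$landmarks$mri)
  # re-warp oracle: applying the stored field to the pristine modality B
  # reproduces the stored deformed image within quantisation (2 gray levels)
  rew <- warp_image(pr$B_orig, pr$field_applied)
  expect_lt(max(abs(rew$pixels - pr$M$pixels)), 2)
  # the nonlinear part is diffeomorphic
  vel <- sample_velocity(spec$shape, spec$spacing, 10, 5,
                         seed = derive_seed(5, 2))
  expect_true(all(jacobian_determinant(integrate_velocity(vel)) > 0))
  # near-zero noise and identity similarity give a near-zero field
  pr0 <- make_pair(spec, sigma_v = 1e-3, seed = 6, similarity = FALSE)
  expect_lt(max(abs(pr0$field_true$dx)), 1e-2)
  expect_lt(max(abs(pr0$M$pixels - pr0$B_orig$pixels)), 1 + 1e-9)
  # stored true field inverts the applied warp at the landmarks (sigma_k ~ 0)
  prl <- make_pair(spec, sigma_v = 10, seed = 7, n_landmarks = 5,
                   sigma_k = 1e-9)
  le <- landmark_error(prl$field_true, prl$landmarks)
  expect_lt(le$max_error_mm, 1e-6)
})

test_that("landmark simulation is spread, noisy as specified, and well-ordered", {
  spec <- phantom_spec(shape = c(96, 96))
  ph <- make_phantom(spec, seed = 8)
  u <- zero_field(96)
  expect_equal(length(make_landmarks(ph$A, u, 0, seed = 1)), 0)
  lm <- make_landmarks(ph$A, u, 10, sigma_k = 0.5, seed = 2)
  expect_equal(length(lm), 10)
  # all pairwise distances positive (suppression prevents duplicates)
  d <- as.matrix(dist(lm$hist))
  expect_gt(min(d[upper.tri(d)]), 0)
  # spread: every image quadrant holds at least one of 10 landmarks
  quad <- paste(lm$hist[, 1] > 47.5, lm$hist[, 2] > 47.5)
  expect_equal(length(unique(quad)), 4)
  # with a zero truth field, offsets are pure placement noise ~ N(0, sigma_k)
  offs <- lm$mri - lm$hist
  expect_lt(max(abs(offs)), 4 * 0.5)
  # empirical noise std over many draws approaches sigma_k
  all_offs <- unlist(lapply(1:20, function(s) {
    l <- make_landmarks(ph$A, u, 6, sigma_k = 0.5, seed = s)
    l$mri - l$hist
  }))
  expect_lt(abs(sd(all_offs) - 0.5) / 0.5, 0.25)
  # sigma_k = 0: pairs exactly consistent with the truth field
  lm0 <- make_landmarks(ph$A, u, 5, sigma_k = 0, seed = 3)
  expect_equal(lm0$mri, lm0$hist)
})

test_that("artefact injection masks exactly the corrupted pixels", {
  img <- random_image(48, seed = 12, lo = 50, hi = 200)
  none <- add_artefacts(img, n_cracks = 0, n_holes = 0, seed = 1)
  expect_identical(none$image$pixels, img$pixels)
  expect_false(any(none$mask))
  one <- add_artefacts(img, n_cracks = 1, crack_width_px = 2, seed = 2)
  expect_gt(sum(one$mask), 0)
  expect_true(all(one$image$pixels[one$mask] == 0))
  expect_identical(one$image$pixels[!one$mask], img$pixels[!one$mask])
  holes <- add_artefacts(img, n_cracks = 0, n_holes = 2,
                         hole_radius_px = 3, seed = 3)
  expect_gt(sum(holes$mask), 10)
})

test_that("synthetic pairs can be written to and reloaded from disk", {
  tmp <- withr::local_tempdir()
  spec <- small_phantom_spec(32)
  pr <- make_pair(spec, sigma_v = 10, seed = 9, n_landmarks = 3)
  write_pair(pr, tmp)
  expect_true(all(file.exists(file.path(tmp,
    c("imageA.png", "imageB.png", "field_true.nii.gz",
      "field_applied.nii.gz", "landmarks.csv", "spec.yaml")))))
  ut <- read_field(file.path(tmp, "field_true.nii.gz"))
  expect_lt(max(abs(ut$dx - pr$field_true$dx)), 1e-6)
  lm <- read_landmarks(file.path(tmp, "landmarks.csv"))
  expect_equal(length(lm), 3)
})
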