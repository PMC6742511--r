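test_that("the discrete energy is built term by term", {
  n <- 8
  M <- random_image(n, seed = 31)
  lab <- label_set(1, 1)
  izero <- which(lab$deltas[, 1] == 0 & lab$deltas[, 2] == 0)
  cfg <- reg_config()
  # M == mu everywhere: unary minimised at zero displacement (beta1 term)
  maps0 <- structure(list(mu = M$pixels, var = matrix(25, n, n)),
                     class = "prediction_maps")
  en <- build_energy(M, maps0, NULL, lab, cfg)
  # interior pixels (no out-of-bounds labels): zero label is the argmin
  interior <- as.vector(matrix(seq_len(n * n), n, n)[3:6, 3:6])
  expect_true(all(max.col(-en$unary[interior, ]) == izero))
  # doubling the variance halves the image part of the unary
  mapsA <- random_maps(n, seed = 32, var_lo = 10, var_hi = 10)
  mapsB <- mapsA; mapsB$var <- mapsA$var * 2
  cfg0 <- reg_config(beta1 = 0)
  eA <- build_energy(M, mapsA, NULL, lab, cfg0)
  eB <- build_energy(M, mapsB, NULL, lab, cfg0)
  expect_equal(eB$unary[interior, ], eA$unary[interior, ] / 2)
  # a tight landmark dominates its pixel's unary
  lm <- landmark_set(mri = matrix(c(3, 4), 1), hist = matrix(c(4, 4), 1),
                     sigma_k = 1e-3)
  el <- build_energy(M, maps0, lm, lab, cfg)
  p <- 4 * n + 4 + 1
  best <- which.min(el$unary[p, ])
  expect_equal(unname(lab$deltas[best, ]), c(-1, 0))  # nearest to k - k^h
})

test_that("alpha-expansion reaches the exhaustive optimum on small instances", {
  # oracle sanity: DP equals full enumeration on a 3x3 grid, 4 labels
  set.seed(33)
  lab4 <- structure(list(deltas = cbind(dx = c(0, 1, 0, 1),
                                        dy = c(0, 0, 1, 1)),
                         radius = 1, step = 1), class = "label_set")
  en <- structure(list(unary = matrix(runif(9 * 4), 9, 4), beta2 = 0.5,
                       labels = lab4, shape = c(3, 3), spacing = 1),
                  class = "discrete_energy")
  states <- as.matrix(expand.grid(rep(list(1:4), 9)))
  brute <- min(apply(states, 1, function(s) labeling_energy(en, s)))
  expect_equal(exact_grid_min(en), brute, tolerance = 1e-10)
  # graph-cut exactness on instances with pairwise coupling around the
  # model default (beta2 = 0.02): the move-making minimiser should reach
  # the exact optimum in >= 95% of trials and never undercut it
  lab9 <- label_set(1, 1)
  n_exact <- 0
  n_inst <- 30
  for (i in seq_len(n_inst)) {
    set.seed(200 + i)
    en <- structure(list(unary = matrix(runif(16 * 9, 0, 5), 16, 9),
                         beta2 = runif(1, 0.01, 0.05), labels = lab9,
                         shape = c(4, 4), spacing = 1),
                    class = "discrete_energy")
    opt <- exact_grid_min(en)
    gc_res <- minimize_graphcut(en)
    expect_gte(gc_res$energy, opt - 1e-9)
    expect_equal(labeling_energy(en, gc_res$labels), gc_res$energy,
                 tolerance = 1e-9)
    if (gc_res$energy < opt + 1e-9) n_exact <- n_exact + 1
    # the energy trace never increases (moves accepted on strict decrease)
    expect_true(all(diff(gc_res$trace) <= 1e-12))
  }
  expect_gte(n_exact / n_inst, 0.95)
})

test_that("identical images with matching prediction give the zero field", {
  n <- 10
  M <- random_image(n, seed = 34)
  maps <- structure(list(mu = M$pixels, var = matrix(4, n, n)),
                    class = "prediction_maps")
  lab <- label_set(1, 1)
  en <- build_energy(M, maps, NULL, lab, reg_config())
  gc_res <- minimize_graphcut(en)
  expect_true(all(gc_res$field$dx == 0))
  expect_true(all(gc_res$field$dy == 0))
})

test_that("inflating the predictive variance downweights a region's image term", {
  n <- 8
  M <- random_image(n, seed = 35)
  maps <- random_maps(n, seed = 36, var_lo = 10, var_hi = 10)
  lab <- label_set(1, 1)
  cfg <- reg_config(beta1 = 0)
  en1 <- build_energy(M, maps, NULL, lab, cfg)
  region <- 1:20
  maps10 <- maps
  maps10$var[region] <- maps10$var[region] * 10
  en10 <- build_energy(M, maps10, NULL, lab, cfg)
  interior <- intersect(region, which(rowSums(warp_cache(M, lab)$oob) == 0))
  expect_equal(en10$unary[interior, ], en1$unary[interior, ] / 10)
})

test_that("expected displacement and entropy maps behave at the extremes", {
  lab <- label_set(1, 1)
  S <- length(lab)
  q <- init_beliefs(16, S)
  ed <- expected_displacement(q, lab, c(4, 4), 1)
  expect_true(all(abs(ed$field$dx) < 1e-12))  # symmetric label set
  expect_equal(ed$entropy, rep(log(S), 16))
  # point mass
  qp <- matrix(0, 16, S); qp[, 3] <- 1
  edp <- expected_displacement(qp, lab, c(4, 4), 1)
  expect_true(all(edp$field$dx == lab$deltas[3, 1]))
  expect_true(all(edp$field$dy == lab$deltas[3, 2]))
  expect_equal(edp$entropy, rep(0, 16))
})

test_that("B-spline data term equals 1 when residuals are three standard deviations", {
  n <- 20
  set.seed(37)
  sig <- matrix(runif(n * n, 1, 10), n, n)
  maps <- structure(list(mu = matrix(runif(n * n, 50, 200), n, n),
                         var = sig^2), class = "prediction_maps")
  M <- image2d(maps$mu + 3 * sig, 1)
  basis <- bspline_basis(c(n, n), 1, 6)
  obj <- bspline_objective(rep(0, 2 * basis$ncp), basis, M, maps, NULL,
                           reg_config())
  expect_equal(unname(obj$parts["image"]), 1, tolerance = 1e-12)
})

test_that("B-spline refinement descends and strong bending weight flattens the field", {
  spec <- small_phantom_spec(48)
  pr <- make_pair(spec, sigma_v = 10, seed = 61, n_landmarks = 4)
  lab <- label_set(4, 1)
  feats <- extract_features(pr$H)
  cfg <- fast_config()
  q <- init_beliefs(48^2, length(lab))
  model <- fit_synthesis(list(list(features = feats, M = pr$M, q = q)),
                         lab, cfg, seed = 1)
  maps <- predict_synthesis(model, feats)
  ref <- refine_bspline(pr$M, maps, pr$landmarks, NULL, cfg,
                        cp_spacing = 8, maxit = 60)
  # objective trace: final value no worse than the first
  expect_lte(tail(ref$trace, 1), ref$trace[1] + 1e-9)
  expect_true(is.finite(ref$value))
  # bending energy of an affine (here: fitted near-linear) field is ~ 0;
  # with a huge bending weight the result is driven to near-zero bending
  cfgb <- fast_config(beta_b = 1e6)
  refb <- refine_bspline(pr$M, maps, pr$landmarks, NULL, cfgb,
                         cp_spacing = 8, maxit = 80)
  expect_lt(unname(refb$parts["bending"]), 1e-4)
})

test_that("mutual information estimator matches analytic limits", {
  set.seed(38)
  # MI(X, X) for an 8-level image equals its entropy
  x <- sample(0:7, 4096, replace = TRUE)
  p <- table(x) / length(x)
  expect_equal(mutual_information(x, x, bins = 64),
               -sum(p * log(p)), tolerance = 1e-12)
  # independent uniform noise: MI ~ 0 (within estimation bias ~ bins^2/2n)
  a <- runif(too <- 100000); b <- runif(too)
  expect_lt(mutual_information(a, b, bins = 64), 0.05)
  # constant image: defined as 0
  expect_equal(mutual_information(rep(1, 100), runif(100)), 0)
})

test_that("negative MI is minimised at the true shift of a translated image", {
  set.seed(39)
  base <- gaussian_smooth(matrix(runif(64 * 64), 64, 64), 2)
  img <- image2d(rescale_intensities(base), 1)
  shifted <- warp_image(img, const_field(64, 2, 0))  # samples M(x + 2)
  mis <- vapply(-4:4, function(s) {
    w <- warp_image(img, const_field(64, s, 0))
    ok <- w$mask & shifted$mask
    mutual_information(w$pixels[ok], shifted$pixels[ok], bins = 32)
  }, numeric(1))
  expect_equal(c(-4:4)[which.max(mis)], 2)
})

test_that("with an accurate synthesis the joint pipeline surpasses the MI baseline", {
  # oracle-belief experiment: beliefs set to a point mass at the nearest
  # label to the true displacement; the fitted synthesis is then nearly
  # exact and the discrete + B-spline chain should beat MI at 18 mm
  spec <- phantom_spec(shape = c(64, 64))
  pr <- make_pair(spec, sigma_v = 10, seed = 77, n_landmarks = 10)
  cfg <- reg_config(n_trees = 30, label_radius = 10, label_step = 1)
  lab <- label_set(cfg$label_radius, cfg$label_step)
  npix <- 64^2
  d <- lab$deltas
  idx <- apply(cbind(as.vector(pr$field_true$dx),
                     as.vector(pr$field_true$dy)), 1, function(u)
                       which.min((d[, 1] - u[1])^2 + (d[, 2] - u[2])^2))
  q <- matrix(0, npix, length(lab))
  q[cbind(seq_len(npix), idx)] <- 1
  feats <- extract_features(pr$H)
  model <- fit_synthesis(list(list(features = feats, M = pr$M, q = q)),
                         lab, cfg, seed = 5)
  maps <- predict_synthesis(model, feats)
  m <- pr$mask
  expect_gt(cor(maps$mu[m], pr$B_orig$pixels[m]), 0.9)
  en <- build_energy(pr$M, maps, pr$landmarks, lab, cfg)
  gc_res <- minimize_graphcut(en)
  ref <- refine_bspline(pr$M, maps, pr$landmarks, gc_res$field, cfg,
                        maxit = 500)
  mi <- register_mi(pr$M, pr$H, pr$landmarks, cfg)
  emask <- erode_mask(pr$mask, 10)
  e_prop <- field_error(ref$field, pr$field_true, emask)$mean_error_mm
  e_mi <- field_error(mi$field, pr$field_true, emask)$mean_error_mm
  expect_lt(e_prop, e_mi)
  expect_lt(e_prop, 1)
})
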