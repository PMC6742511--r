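test_that("uniform belief initialisation is a maximum-entropy distribution", {
  q <- init_beliefs(25, 9)
  expect_true(all(q == 1 / 9))
  expect_equal(rowSums(q), rep(1, 25))
  expect_equal(belief_entropy(q), rep(log(9), 25))
})

test_that("the E-step with beta2 = 0 matches the brute-force closed form", {
  M <- random_image(16, seed = 21)
  lab <- label_set(2, 0.5)  # S = 81
  maps <- random_maps(16, seed = 22)
  cfg <- reg_config(beta2 = 0)
  q0 <- init_beliefs(256, length(lab))
  t0 <- Sys.time()
  es <- estep_update(q0, maps, M, NULL, lab, cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  oracle <- bruteforce_beliefs(M, maps, lab, cfg$beta1)
  expect_lt(max(abs(es$q - oracle)), 1e-12)
  expect_lt(elapsed, 1)
})

test_that("beliefs stay normalised and a flat likelihood leaves them uniform", {
  # constant image with matching constant prediction: all factors flat
  M <- image2d(matrix(100, 12, 12), 1)
  maps <- structure(list(mu = matrix(100, 12, 12), var = matrix(25, 12, 12)),
                    class = "prediction_maps")
  lab <- label_set(2, 1)
  cfg <- reg_config(beta1 = 0, beta2 = 0)
  es <- estep_update(init_beliefs(144, length(lab)), maps, M, NULL, lab, cfg)
  expect_true(all(abs(es$q - 1 / length(lab)) < 1e-12))
  # with coupling and priors the result is still a distribution
  cfg2 <- reg_config()
  M2 <- random_image(12, seed = 23)
  maps2 <- random_maps(12, seed = 24)
  es2 <- estep_update(init_beliefs(144, length(lab)), maps2, M2, NULL,
                      lab, cfg2)
  expect_true(all(es2$q >= 0))
  expect_equal(rowSums(es2$q), rep(1, 144), tolerance = 1e-12)
})

test_that("a dominant landmark factor pins the belief at its pixel", {
  M <- image2d(matrix(100, 16, 16), 1)
  maps <- structure(list(mu = matrix(100, 16, 16), var = matrix(25, 16, 16)),
                    class = "prediction_maps")
  lab <- label_set(3, 1)
  # histology landmark at pixel (8, 8) mm, MRI partner displaced by (-2, 0):
  # k - k^h = (-2, 0) so the residual ||k^h - k + Delta|| vanishes at (-2, 0)
  lm <- landmark_set(mri = matrix(c(6, 8), 1), hist = matrix(c(8, 8), 1),
                     sigma_k = 0.05)
  cfg <- reg_config(beta1 = 0, beta2 = 0)
  es <- estep_update(init_beliefs(256, length(lab)), maps, M, lm, lab, cfg)
  p <- 8 * 16 + 8 + 1  # column-major index of pixel (row 8, col 8)
  s_hat <- which.max(es$q[p, ])
  expect_equal(unname(lab$deltas[s_hat, ]), c(-2, 0))
})

test_that("landmarks reduce belief entropy non-locally through the MRF", {
  set.seed(25)
  spec <- small_phantom_spec(48)
  pr <- make_pair(spec, sigma_v = 10, seed = 31, n_landmarks = 0)
  cfg <- fast_config()
  lab <- label_set(cfg$label_radius, cfg$label_step)
  feats <- extract_features(pr$H)
  wc <- warp_cache(pr$M, lab)
  model <- fit_synthesis(list(list(features = feats, M = pr$M,
                                   q = init_beliefs(48^2, length(lab)),
                                   warp_cache = wc)), lab, cfg, seed = 1)
  maps <- predict_synthesis(model, feats)
  lm <- make_landmarks(pr$H, pr$field_true, 6, sigma_k = 0.5, seed = 2)
  q0 <- init_beliefs(48^2, length(lab))
  es_no <- estep_update(q0, maps, pr$M, NULL, lab, cfg, warp = wc)
  es_lm <- estep_update(q0, maps, pr$M, lm, lab, cfg, warp = wc)
  ent_no <- belief_entropy(es_no$q)
  ent_lm <- belief_entropy(es_lm$q)
  # entropy drops at the landmark pixels and at their 4-neighbourhoods
  cc <- round(lm$hist[, 1]); rr <- round(lm$hist[, 2])
  pix <- cc * 48 + rr + 1
  nbrs <- unique(c(pix + 1, pix - 1, pix + 48, pix - 48))
  nbrs <- setdiff(nbrs[nbrs >= 1 & nbrs <= 48^2], pix)
  expect_lt(mean(ent_lm[pix]), mean(ent_no[pix]))
  expect_lt(mean(ent_lm[nbrs]), mean(ent_no[nbrs]))
})

test_that("the variational bound is non-decreasing over inner sweeps at fixed model", {
  M <- random_image(20, seed = 26)
  maps <- random_maps(20, seed = 27, var_lo = 9, var_hi = 64)
  lab <- label_set(2, 1)
  cfg <- reg_config(max_inner = 15)
  es <- estep_update(init_beliefs(400, length(lab)), maps, M, NULL, lab,
                     cfg, track_bound = TRUE)
  tr <- es$bound_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) > -1e-6))
})

test_that("the VEM loop records history and improves the synthesis on a phantom", {
  spec <- small_phantom_spec(48)
  pr <- make_pair(spec, sigma_v = 10, seed = 41, n_landmarks = 6)
  cfg <- fast_config()
  st <- suppressWarnings(
    run_vem(list(list(M = pr$M, H = pr$H, landmarks = pr$landmarks)),
            cfg, seed = 7))
  expect_s3_class(st, "vem_state")
  expect_equal(nrow(st$history), st$iterations)
  expect_true(all(c("mu_change", "var_change", "mean_entropy") %in%
                    names(st$history)))
  # belief entropy decreases from the uniform maximum
  expect_lt(tail(st$history$mean_entropy, 1),
            log(length(st$labels)) - 0.2)
  # beliefs remain distributions
  expect_equal(rowSums(st$beliefs[[1]]), rep(1, 48^2), tolerance = 1e-9)
  # prediction maps have the variance floor respected
  floor_v <- 2 * cfg$b / (2 * cfg$a + cfg$n_trees)
  expect_true(all(st$maps[[1]]$var >= floor_v - 1e-12))
})

test_that("M-step under truthful beliefs beats the uniform-belief fit", {
  spec <- small_phantom_spec(48)
  pr <- make_pair(spec, sigma_v = 10, seed = 51, n_landmarks = 0,
                  similarity = FALSE)
  cfg <- fast_config()
  lab <- label_set(cfg$label_radius, cfg$label_step)
  S <- length(lab)
  npix <- 48^2
  feats <- extract_features(pr$H)
  d <- lab$deltas
  idx <- apply(cbind(as.vector(pr$field_true$dx),
                     as.vector(pr$field_true$dy)), 1, function(u)
                       which.min((d[, 1] - u[1])^2 + (d[, 2] - u[2])^2))
  q_true <- matrix(0, npix, S); q_true[cbind(seq_len(npix), idx)] <- 1
  pairs_t <- list(list(features = feats, M = pr$M, q = q_true))
  pairs_u <- list(list(features = feats, M = pr$M,
                       q = init_beliefs(npix, S)))
  fit_t <- mstep_update(pairs_t, lab, cfg, seed = 3)
  fit_u <- mstep_update(pairs_u, lab, cfg, seed = 3)
  m <- pr$mask
  rmse <- function(maps) sqrt(mean((maps$mu[m] - pr$B_orig$pixels[m])^2))
  expect_lt(rmse(fit_t$maps[[1]]), rmse(fit_u$maps[[1]]))
})
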