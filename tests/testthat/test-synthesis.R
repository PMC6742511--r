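test_that("feature extraction produces the 32-feature stack with analytic values", {
  img <- random_image(24, seed = 5)
  X <- extract_features(img)
  expect_equal(ncol(X), 32)
  expect_equal(nrow(X), 24 * 24)
  # constant image: all derivative features 0, order-0 features equal it
  cst <- image2d(matrix(42, 16, 16), 1)
  Xc <- extract_features(cst)
  expect_true(all(abs(Xc[, grep("^s\\d+_g$", colnames(Xc))] - 42) < 1e-9))
  dcols <- setdiff(grep("^s", colnames(Xc)), grep("^s\\d+_g$", colnames(Xc)))
  expect_true(all(abs(Xc[, dcols]) < 1e-9))
  # ramp f(x) = x: first x-derivative ~ 1/mm at all scales, higher orders
  # ~ 0 (interior kept clear of the 4 mm kernel's boundary support)
  rp <- ramp_image(64, spacing = 1)
  Xr <- extract_features(rp)
  interior <- as.vector(matrix(seq_len(64 * 64), 64, 64)[25:40, 25:40])
  for (sc in c(0, 2, 4)) {
    expect_true(all(abs(Xr[interior, paste0("s", sc, "_gx")] - 1) < 1e-6))
    expect_true(all(abs(Xr[interior, paste0("s", sc, "_gxx")]) < 1e-6))
    expect_true(all(abs(Xr[interior, paste0("s", sc, "_gy")]) < 1e-6))
  }
  # location features are in mm
  img2 <- random_image(8, spacing = 2, seed = 6)
  X2 <- extract_features(img2)
  expect_equal(max(X2[, "loc_x"]), 14)  # (8-1) * 2 mm
})

test_that("forest training recovers a deterministic contrast map under point-mass beliefs", {
  set.seed(8)
  n <- 32
  H <- image2d(matrix(runif(n * n, 0, 255), n, n), 1)
  M <- image2d(200 - 0.7 * H$pixels, 1)  # deterministic mapping, aligned
  lab <- label_set(2, 1)
  S <- length(lab)
  izero <- which(lab$deltas[, 1] == 0 & lab$deltas[, 2] == 0)
  q <- matrix(0, n * n, S); q[, izero] <- 1
  feats <- extract_features(H)
  cfg <- reg_config(n_trees = 10)
  model <- fit_synthesis(list(list(features = feats, M = M, q = q)),
                         lab, cfg, seed = 1)
  maps <- predict_synthesis(model, feats)
  expect_lt(sqrt(mean((maps$mu - M$pixels)^2)), 12)
  expect_gt(cor(as.vector(maps$mu), as.vector(M$pixels)), 0.98)
  # uniform beliefs on a constant target: all predictions equal the constant
  Mc <- image2d(matrix(77, n, n), 1)
  qu <- matrix(1 / S, n * n, S)
  mc <- fit_synthesis(list(list(features = feats, M = Mc, q = qu)),
                      lab, cfg, seed = 1)
  pc <- predict_synthesis(mc, feats)
  expect_true(all(abs(pc$mu - 77) < 1e-9))
  expect_true(all(abs(pc$var - 2 * cfg$b / (2 * cfg$a + cfg$n_trees)) < 1e-9))
})

test_that("trees differ across seeds and training is seed-reproducible", {
  set.seed(9)
  n <- 24
  H <- random_image(n, seed = 9)
  M <- image2d(H$pixels * 0.5 + 20, 1)
  lab <- label_set(1, 1)
  q <- matrix(1 / 9, n * n, 9)
  feats <- extract_features(H)
  cfg <- reg_config(n_trees = 2)
  pairs <- list(list(features = feats, M = M, q = q))
  m1 <- fit_synthesis(pairs, lab, cfg, seed = 1)
  m2 <- fit_synthesis(pairs, lab, cfg, seed = 1)
  m3 <- fit_synthesis(pairs, lab, cfg, seed = 2)
  p1 <- predict_synthesis(m1, feats)
  p2 <- predict_synthesis(m2, feats)
  p3 <- predict_synthesis(m3, feats)
  expect_identical(p1$mu, p2$mu)      # same seed, same forest
  expect_false(identical(p1$mu, p3$mu))  # bagging injects randomness
  # the two trees within one forest generally disagree somewhere
  g1 <- predict(m1$trees[[1]], data = feats, num.threads = 1)$predictions
  g2 <- predict(m1$trees[[2]], data = feats, num.threads = 1)$predictions
  expect_gt(max(abs(g1 - g2)), 0)
})

test_that("predictive variance follows the Inverse-Gamma pooling formula", {
  # hand-computed: unanimous trees at the prior floor
  a <- 2; b <- 50
  agree <- rep(120, 100)
  mu <- mean(agree)
  v <- (2 * b + sum((agree - mu)^2)) / (2 * a + 100)
  expect_equal(mu, 120)
  expect_equal(v, 100 / 104)
  # two trees guessing {0, 2}
  g <- c(0, 2)
  v2 <- (2 * b + sum((g - mean(g))^2)) / (2 * a + 2)
  expect_equal(mean(g), 1)
  expect_equal(v2, 102 / 6)  # = 17
  # lower bound holds for arbitrary guesses
  set.seed(10)
  for (i in 1:20) {
    g <- runif(30, 0, 255)
    v <- (2 * b + sum((g - mean(g))^2)) / (2 * a + 30)
    expect_gte(v, 2 * b / (2 * a + 30))
  }
})

test_that("predict_synthesis validates features and applies the variance floor", {
  n <- 16
  H <- random_image(n, seed = 11)
  M <- image2d(H$pixels, 1)
  lab <- label_set(1, 1)
  q <- matrix(1 / 9, n * n, 9)
  feats <- extract_features(H)
  cfg <- reg_config(n_trees = 5)
  model <- fit_synthesis(list(list(features = feats, M = M, q = q)),
                         lab, cfg, seed = 1)
  maps <- predict_synthesis(model, feats)
  floor_v <- 2 * cfg$b / (2 * cfg$a + cfg$n_trees)
  expect_true(all(maps$var >= floor_v - 1e-12))
  expect_error(predict_synthesis(model, feats[, 1:10]), "mismatch")
})
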