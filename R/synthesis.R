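# ---------------------------------------------------------------------------
# Contrast synthesis: Gaussian-derivative features and the regression-forest
# intensity model with conjugate Inverse-Gamma variance prior.
# ---------------------------------------------------------------------------

# central differences (per mm) with replicate boundaries
deriv_x <- function(m, sp) {
  W <- ncol(m)
  if (W == 1) return(m * 0)
  cbind(m[, 2] - m[, 1],
        (m[, -(1:2), drop = FALSE] - m[, 1:(W - 2), drop = FALSE]) / 2,
        m[, W] - m[, W - 1]) / sp
}

deriv_y <- function(m, sp) {
  H <- nrow(m)
  if (H == 1) return(m * 0)
  rbind(m[2, ] - m[1, ],
        (m[-(1:2), , drop = FALSE] - m[1:(H - 2), , drop = FALSE]) / 2,
        m[H, ] - m[H - 1, ]) / sp
}

#' Per-pixel synthesis features
#'
#' Gaussian derivatives of the histology image of orders 0 to 3 at scales
#' 0, 2 and 4 mm (all axis-aligned partial derivatives of each order:
#' 1 + 2 + 3 + 4 = 10 per scale), plus the 2D pixel location in mm, for a
#' total of 32 features. Scale 0 means no pre-smoothing; derivatives are
#' computed by central finite differences (per mm).
#'
#' @param img an [image2d] with known spacing.
#' @param scales_mm smoothing scales in mm (default `c(0, 2, 4)`).
#' @return A numeric matrix with one row per pixel (column-major pixel
#'   order) and 32 named columns, with attributes `shape` and `spacing`.
#' @export
extract_features <- function(img, scales_mm = c(0, 2, 4)) {
  stopifnot(inherits(img, "image2d"))
  sp <- img$spacing
  d <- dim(img$pixels)
  feats <- list()
  for (sc in scales_mm) {
    base <- if (sc > 0) gaussian_smooth(img$pixels, sc / sp) else img$pixels
    gx <- deriv_x(base, sp);  gy <- deriv_y(base, sp)
    gxx <- deriv_x(gx, sp);   gxy <- deriv_y(gx, sp);  gyy <- deriv_y(gy, sp)
    gxxx <- deriv_x(gxx, sp); gxxy <- deriv_y(gxx, sp)
    gxyy <- deriv_y(gxy, sp); gyyy <- deriv_y(gyy, sp)
    blk <- list(base, gx, gy, gxx, gxy, gyy, gxxx, gxxy, gxyy, gyyy)
    names(blk) <- paste0("s", sc, "_",
                         c("g", "gx", "gy", "gxx", "gxy", "gyy",
                           "gxxx", "gxxy", "gxyy", "gyyy"))
    feats <- c(feats, blk)
  }
  X <- vapply(feats, as.vector, numeric(prod(d)))
  X <- cbind(X,
             loc_x = rep(0:(d[2] - 1), each = d[1]) * sp,
             loc_y = rep(0:(d[1] - 1), times = d[2]) * sp)
  attr(X, "shape") <- d
  attr(X, "spacing") <- sp
  X
}

# draw one label index for each listed pixel row of q, inverse CDF
sample_labels <- function(q, rows, u) {
  cpp_sample_labels(q, as.integer(rows), u)
}

#' Fit the synthesis forest
#'
#' Trains `n_trees` independent regression trees. Each tree draws its own
#' bootstrap: when several image pairs are given, 66% of the pairs and a
#' total of 25,000 pixels across them; with a single pair, 66% of its
#' pixels. For every chosen pixel, one displacement label is sampled from
#' the pixel's current belief `q` and the target intensity is the MRI value
#' at the displaced location (bilinear; out-of-bounds samples are dropped).
#' Splits consider `n_split_features` randomly chosen features and leaves
#' keep at least `min_leaf` samples; the per-tree prediction is the leaf
#' mean. Sampling one displacement per pixel per tree is a stochastic
#' optimiser of the weighted training objective, because the beliefs are
#' proper probability distributions.
#'
#' @param pairs list of pairs; each element is a list with `features`
#'   (matrix from [extract_features]), `M` (the [image2d] being
#'   predicted) and `q` (npix x S belief matrix).
#' @param labels a [label_set].
#' @param config a [reg_config] (uses `n_trees`, `min_leaf`,
#'   `n_split_features`, `a`, `b`).
#' @param seed integer seed; each tree derives its own child seed.
#' @param n_pixel_cap total training pixels when `length(pairs) > 1`.
#' @return An object of class `synthesis_model`.
#' @export
fit_synthesis <- function(pairs, labels, config = reg_config(), seed = 1,
                          n_pixel_cap = 25000) {
  N <- length(pairs)
  if (N < 1) stop("empty training set")
  S <- length(labels)
  # per-pair warp cache: M(x + Delta_s) for all pixels and labels
  for (n in seq_len(N)) {
    if (is.null(pairs[[n]]$warp_cache))
      pairs[[n]]$warp_cache <- warp_cache(pairs[[n]]$M, labels)
  }
  trees <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    st <- derive_seed(seed, t)
    sel_pairs <- if (N > 1) {
      with_seed(st, sample(N, max(1L, ceiling(0.66 * N))))
    } else 1L
    Xs <- list(); ys <- list()
    for (j in seq_along(sel_pairs)) {
      n <- sel_pairs[j]
      npix <- nrow(pairs[[n]]$features)
      n_take <- if (N > 1) {
        min(npix, ceiling(n_pixel_cap / length(sel_pairs)))
      } else ceiling(0.66 * npix)
      sj <- derive_seed(st, j)
      draw <- with_seed(sj, {
        idx <- sample(npix, n_take)
        u <- runif(n_take)
        list(idx = idx, u = u)
      })
      idx <- draw$idx
      s_lab <- sample_labels(pairs[[n]]$q, idx, draw$u)
      wc <- pairs[[n]]$warp_cache
      tgt <- wc$value[cbind(idx, s_lab)]
      ok <- !wc$oob[cbind(idx, s_lab)]
      if (any(ok)) {
        Xs[[length(Xs) + 1L]] <- pairs[[n]]$features[idx[ok], , drop = FALSE]
        ys[[length(ys) + 1L]] <- tgt[ok]
      }
    }
    if (!length(ys)) stop("all training targets fell out of bounds")
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    trees[[t]] <- ranger::ranger(
      x = X, y = y, num.trees = 1,
      mtry = min(config$n_split_features, ncol(X)),
      min.bucket = config$min_leaf,
      replace = FALSE, sample.fraction = 1,
      num.threads = 1, seed = derive_seed(st, 99991))
  }
  structure(list(trees = trees,
                 hyper = list(a = config$a, b = config$b,
                              n_trees = config$n_trees,
                              min_leaf = config$min_leaf,
                              n_split_features = config$n_split_features),
                 n_features = ncol(pairs[[1]]$features)),
            class = "synthesis_model")
}

#' Precompute displaced intensity lookups
#'
#' npix x S matrix of `M(x + Delta_s)` (bilinear) for every pixel and
#' displacement label, with an out-of-bounds indicator. Shared by the
#' E-step, the M-step sampling and the discrete energy.
#'
#' @param M an [image2d].
#' @param labels a [label_set].
#' @return A list with matrices `value` and `oob`.
#' @export
warp_cache <- function(M, labels) {
  stopifnot(inherits(M, "image2d"), inherits(labels, "label_set"))
  sp <- M$spacing
  cpp_warp_matrix(M$pixels, labels$deltas[, 1] / sp, labels$deltas[, 2] / sp)
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf("<synthesis_model> %d trees, a = %g, b = %g\n",
              length(x$trees), x$hyper$a, x$hyper$b))
  invisible(x)
}

#' Per-pixel Gaussian prediction from the forest
#'
#' The predictive mean is the average of the tree guesses; the predictive
#' variance pools the tree disagreement with the Inverse-Gamma prior:
#' \deqn{\sigma^2 = \frac{2b + \sum_t (g_t - \mu)^2}{2a + T},}
#' which is bounded below by `2b / (2a + T)` (attained when all trees
#' agree) so the Gaussians never degenerate.
#'
#' @param model a `synthesis_model`.
#' @param features matrix from [extract_features].
#' @return An object of class `prediction_maps` with matrices `mu` and
#'   `var` shaped like the image.
#' @export
predict_synthesis <- function(model, features) {
  stopifnot(inherits(model, "synthesis_model"))
  if (ncol(features) != model$n_features)
    stop("feature count mismatch: got ", ncol(features),
         ", model expects ", model$n_features)
  TT <- length(model$trees)
  G <- vapply(model$trees, function(tr)
    predict(tr, data = features, num.threads = 1)$predictions,
    numeric(nrow(features)))
  mu <- rowMeans(G)
  rss <- rowSums((G - mu)^2)
  a <- model$hyper$a; b <- model$hyper$b
  v <- (2 * b + rss) / (2 * a + TT)
  shape <- attr(features, "shape")
  if (is.null(shape)) shape <- c(length(mu), 1L)
  structure(list(mu = matrix(mu, shape[1], shape[2]),
                 var = matrix(v, shape[1], shape[2])),
            class = "prediction_maps")
}

#' @export
print.prediction_maps <- function(x, ...) {
  cat(sprintf("<prediction_maps> %d x %d, mean mu %.2f, mean var %.2f\n",
              nrow(x$mu), ncol(x$mu), mean(x$mu), mean(x$var)))
  invisible(x)
}
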