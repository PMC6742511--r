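# ---------------------------------------------------------------------------
# Final registration, discrete part: the per-pixel/per-label energy of the
# log-posterior and its minimisation by alpha-expansion graph cuts.
# ---------------------------------------------------------------------------

#' Build the discrete registration energy
#'
#' Per-pixel, per-label unary costs
#' \deqn{[M(x+\Delta_s) - \mu_x]^2 / (2\sigma^2_x) + \beta_1\|\Delta_s\|^2}
#' (a weighted sum of squared differences whose weights are inversely
#' proportional to the predictive variance, downweighting uncertain
#' synthesis), plus a landmark quadratic
#' \eqn{\|k^h - k + \Delta_s\|^2 / (2\sigma_k^2)} at pixels holding a
#' histology landmark. The pairwise cost is
#' \eqn{\beta_2\|\Delta_s - \Delta_{s'}\|^2} per 4-neighbour edge.
#' Out-of-bounds image samples receive the pixel's mean in-bounds image
#' cost (neutral), keeping the unary finite.
#'
#' @param M the MRI [image2d].
#' @param maps `prediction_maps` from the fitted synthesis.
#' @param landmarks a [landmark_set] or `NULL`.
#' @param labels a [label_set].
#' @param config a [reg_config].
#' @param warp optional precomputed [warp_cache].
#' @return An object of class `discrete_energy` with `unary` (npix x S),
#'   `beta2`, `labels`, `shape`, `spacing`.
#' @export
build_energy <- function(M, maps, landmarks, labels, config = reg_config(),
                         warp = NULL) {
  stopifnot(inherits(M, "image2d"), inherits(maps, "prediction_maps"))
  if (is.null(warp)) warp <- warp_cache(M, labels)
  shape <- dim(M$pixels)
  mu <- as.vector(maps$mu)
  v <- as.vector(maps$var)
  stopifnot(all(v > 0))
  U <- (warp$value - mu)^2 / (2 * v)
  if (any(warp$oob)) {
    Uin <- U
    Uin[warp$oob] <- 0
    n_in <- pmax(rowSums(!warp$oob), 1L)
    neutral <- rowSums(Uin) / n_in
    U[warp$oob] <- neutral[row(U)[warp$oob]]
  }
  d2 <- rowSums(labels$deltas^2)
  U <- sweep(U, 2, config$beta1 * d2, "+")
  if (!is.null(landmarks) && length(landmarks) > 0) {
    cc <- round(landmarks$hist[, 1] / M$spacing)
    rr <- round(landmarks$hist[, 2] / M$spacing)
    ok <- cc >= 0 & cc <= shape[2] - 1 & rr >= 0 & rr <= shape[1] - 1
    for (l in which(ok)) {
      p <- cc[l] * shape[1] + rr[l] + 1
      diff_x <- landmarks$hist[l, 1] - landmarks$mri[l, 1] + labels$deltas[, 1]
      diff_y <- landmarks$hist[l, 2] - landmarks$mri[l, 2] + labels$deltas[, 2]
      U[p, ] <- U[p, ] + (diff_x^2 + diff_y^2) / (2 * landmarks$sigma_k^2)
    }
  }
  structure(list(unary = U, beta2 = config$beta2, labels = labels,
                 shape = shape, spacing = M$spacing),
            class = "discrete_energy")
}

#' Total energy of a labeling
#'
#' @param energy a `discrete_energy`.
#' @param lab integer vector of 1-based label indices, one per pixel.
#' @return Scalar total energy (unary + pairwise).
#' @export
labeling_energy <- function(energy, lab) {
  stopifnot(inherits(energy, "discrete_energy"))
  H <- energy$shape[1]; W <- energy$shape[2]
  d <- energy$labels$deltas
  E <- sum(energy$unary[cbind(seq_along(lab), lab)])
  lm <- matrix(lab, H, W)
  pair <- 0
  if (H > 1) {
    a <- lm[-1, ]; b <- lm[-H, ]
    pair <- pair + sum((d[a, 1] - d[b, 1])^2 + (d[a, 2] - d[b, 2])^2)
  }
  if (W > 1) {
    a <- lm[, -1]; b <- lm[, -W]
    pair <- pair + sum((d[a, 1] - d[b, 1])^2 + (d[a, 2] - d[b, 2])^2)
  }
  E + energy$beta2 * pair
}

#' Minimise the discrete energy by alpha-expansion graph cuts
#'
#' Visits the labels in fixed order; each expansion move is solved as an
#' s-t min-cut and accepted only when it strictly lowers the true energy,
#' so the energy trace is non-increasing. Cycling stops when a full pass
#' over the labels yields no accepted move. The result need not be
#' diffeomorphic.
#'
#' @param energy a `discrete_energy` from [build_energy].
#' @param init optional initial 1-based label indices. By default two
#'   starts are tried - the per-pixel unary minimiser and the best
#'   constant labeling (which pays no pairwise cost) - and the lower-energy
#'   result is kept.
#' @param max_cycles maximum passes over the label set.
#' @return A list with `field` (a [deformation_field]), `labels`
#'   (1-based indices), `energy` (final value) and `trace`.
#' @export
minimize_graphcut <- function(energy, init = NULL, max_cycles = 10) {
  stopifnot(inherits(energy, "discrete_energy"))
  npix <- nrow(energy$unary)
  S <- nrow(energy$labels$deltas)
  inits <- if (is.null(init)) {
    ini <- list(max.col(-energy$unary, ties.method = "first"),
                rep(which.min(colSums(energy$unary)), npix))
    if (npix * S <= 20000) {
      # small instances: also restart from every constant labeling
      ini <- c(ini, lapply(seq_len(S), function(s) rep(s, npix)))
    }
    ini
  } else list(init)
  res <- NULL
  for (ini in inits) {
    r <- cpp_alpha_expansion(energy$unary, energy$shape[1], energy$shape[2],
                             energy$beta2,
                             energy$labels$deltas[, 1],
                             energy$labels$deltas[, 2],
                             as.integer(ini) - 1L, as.integer(max_cycles))
    if (is.null(res) || r$energy < res$energy) res <- r
  }
  lab <- res$labels + 1L
  d <- energy$labels$deltas
  field <- deformation_field(matrix(d[lab, 1], energy$shape[1]),
                             matrix(d[lab, 2], energy$shape[1]),
                             spacing = energy$spacing)
  list(field = field, labels = lab, energy = res$energy, trace = res$trace,
       n_moves = res$n_moves)
}

#' Expected displacement and entropy under the beliefs
#'
#' Diagnostic maps of the registration uncertainty: the per-pixel mean
#' displacement \eqn{E_q[\Delta]} and the per-pixel belief entropy.
#'
#' @param q npix x S belief matrix.
#' @param labels a [label_set].
#' @param shape image shape (H, W).
#' @param spacing pixel size in mm.
#' @return A list with `field` (a [deformation_field]) and `entropy`
#'   (vector, nats).
#' @export
expected_displacement <- function(q, labels, shape, spacing = 1) {
  ex <- as.vector(q %*% labels$deltas[, 1])
  ey <- as.vector(q %*% labels$deltas[, 2])
  list(field = deformation_field(matrix(ex, shape[1], shape[2]),
                                 matrix(ey, shape[1], shape[2]),
                                 spacing = spacing),
       entropy = belief_entropy(q))
}
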