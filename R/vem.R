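# ---------------------------------------------------------------------------
# Variational EM: uniform belief initialisation, mean-field E-step fixed
# point, stochastic M-step (forest refit), and the outer loop tracking
# convergence of the prediction maps.
# ---------------------------------------------------------------------------

#' Uniform belief initialisation
#'
#' Evenly spreads probability mass across all candidate displacements
#' (maximum registration uncertainty).
#'
#' @param npix number of pixels.
#' @param S number of displacement labels.
#' @return An `npix x S` matrix with every entry `1/S`.
#' @export
init_beliefs <- function(npix, S) {
  matrix(1 / S, npix, S)
}

#' Per-pixel entropy of a belief field
#'
#' @param q npix x S belief matrix.
#' @return Vector of entropies in nats (`log S` at uniform pixels).
#' @export
belief_entropy <- function(q) {
  lq <- ifelse(q > 0, log(q), 0)
  -rowSums(q * lq)
}

# log-likelihood + unary-prior + landmark part of the fixed-point update,
# npix x S. Out-of-bounds entries get the pixel's mean in-bounds
# likelihood (neutral), so border pixels are driven by prior + neighbours.
estep_logunary <- function(maps, M, landmarks, labels, config,
                           warp = NULL) {
  if (is.null(warp)) warp <- warp_cache(M, labels)
  shape <- dim(M$pixels)
  npix <- prod(shape)
  S <- length(labels)
  mu <- as.vector(maps$mu)
  v <- as.vector(maps$var)
  L <- -(warp$value - mu)^2 / (2 * v) - 0.5 * log(2 * pi * v)
  if (any(warp$oob)) {
    Lin <- L
    Lin[warp$oob] <- -Inf
    rmax <- apply(Lin, 1, max)
    n_in <- rowSums(!warp$oob)
    neutral <- rmax + log(rowSums(exp(Lin - rmax) * !warp$oob)) - log(n_in)
    L[warp$oob] <- neutral[row(L)[warp$oob]]
  }
  d2 <- rowSums(labels$deltas^2)
  L <- sweep(L, 2, config$beta1 * d2, "-")
  if (!is.null(landmarks) && length(landmarks) > 0) {
    cc <- round(landmarks$hist[, 1] / M$spacing)
    rr <- round(landmarks$hist[, 2] / M$spacing)
    ok <- cc >= 0 & cc <= shape[2] - 1 & rr >= 0 & rr <= shape[1] - 1
    for (l in which(ok)) {
      p <- cc[l] * shape[1] + rr[l] + 1
      diff_x <- landmarks$hist[l, 1] - landmarks$mri[l, 1] + labels$deltas[, 1]
      diff_y <- landmarks$hist[l, 2] - landmarks$mri[l, 2] + labels$deltas[, 2]
      L[p, ] <- L[p, ] - (diff_x^2 + diff_y^2) / (2 * landmarks$sigma_k^2)
    }
  }
  pmax(L, log(1e-300))
}

#' Mean-field E-step: fixed-point update of the beliefs
#'
#' Iterates the per-pixel fixed point
#' \deqn{q_x(\Delta_s) \propto N(M(x+\Delta_s); \mu_x, \sigma^2_x)\,
#'   e^{-\beta_1 \|\Delta_s\|^2} \cdot lm_x(\Delta_s) \cdot
#'   \exp\big(-\beta_2 \sum_{x' \in B(x)} E_{q_{x'}}\|\Delta_s -
#'   \Delta'\|^2\big)}
#' with red-black sweeps until the largest per-pixel L1 change falls below
#' `config$inner_tol` or `config$max_inner` sweeps. The landmark factor
#' `lm_x` applies at pixels holding a histology landmark. Each neighbour
#' enters only through its first and second belief moments, so a sweep
#' costs O(npix * S).
#'
#' @param q current npix x S belief matrix.
#' @param maps `prediction_maps` for this pair from the current model.
#' @param M the MRI [image2d].
#' @param landmarks a [landmark_set] or `NULL`.
#' @param labels a [label_set].
#' @param config a [reg_config].
#' @param warp optional precomputed [warp_cache] for `(M, labels)`.
#' @param track_bound if `TRUE`, run sweeps one at a time from R and
#'   record the variational-bound diagnostic after each sweep.
#' @return A list with `q`, `n_sweeps`, `converged` and (if tracked)
#'   `bound_trace`.
#' @export
estep_update <- function(q, maps, M, landmarks, labels, config = reg_config(),
                         warp = NULL, track_bound = FALSE) {
  shape <- dim(M$pixels)
  L <- estep_logunary(maps, M, landmarks, labels, config, warp)
  if (!track_bound) {
    res <- cpp_estep_sweeps(L, q, labels$deltas[, 1], labels$deltas[, 2],
                            config$beta2, shape[1], shape[2],
                            config$max_inner, config$inner_tol)
    return(list(q = res$q, n_sweeps = res$n_sweeps,
                converged = res$converged))
  }
  trace <- numeric(0)
  converged <- FALSE
  n_sweeps <- 0L
  for (i in seq_len(config$max_inner)) {
    res <- cpp_estep_sweeps(L, q, labels$deltas[, 1], labels$deltas[, 2],
                            config$beta2, shape[1], shape[2],
                            1L, config$inner_tol)
    q <- res$q
    n_sweeps <- n_sweeps + 1L
    trace <- c(trace, variational_bound(q, L, labels, config$beta2, shape))
    if (res$max_change < config$inner_tol) { converged <- TRUE; break }
  }
  list(q = q, n_sweeps = n_sweeps, converged = converged,
       bound_trace = trace)
}

# entropy + expected log unary - beta2 * expected pairwise energy
# (the part of the variational lower bound that depends on q at fixed theta)
variational_bound <- function(q, logunary, labels, beta2, shape) {
  ent <- sum(belief_entropy(q))
  eu <- sum(q * logunary)
  m1x <- as.vector(q %*% labels$deltas[, 1])
  m1y <- as.vector(q %*% labels$deltas[, 2])
  m2 <- as.vector(q %*% rowSums(labels$deltas^2))
  H <- shape[1]; W <- shape[2]
  M1x <- matrix(m1x, H, W); M1y <- matrix(m1y, H, W); M2 <- matrix(m2, H, W)
  epair <- 0
  if (H > 1)
    epair <- epair + sum(M2[-1, ] + M2[-H, ] -
                           2 * (M1x[-1, ] * M1x[-H, ] + M1y[-1, ] * M1y[-H, ]))
  if (W > 1)
    epair <- epair + sum(M2[, -1] + M2[, -W] -
                           2 * (M1x[, -1] * M1x[, -W] + M1y[, -1] * M1y[, -W]))
  ent + eu - beta2 * epair
}

#' M-step: refit the synthesis forest under the current beliefs
#'
#' Delegates to [fit_synthesis] with the current beliefs and recomputes
#' the per-pair prediction maps.
#'
#' @param pairs list of pairs as in [fit_synthesis] (with current `q`).
#' @param labels a [label_set].
#' @param config a [reg_config].
#' @param seed integer seed.
#' @return A list with `model` and `maps` (one `prediction_maps` per pair).
#' @export
mstep_update <- function(pairs, labels, config = reg_config(), seed = 1) {
  model <- fit_synthesis(pairs, labels, config, seed = seed)
  maps <- lapply(pairs, function(p) predict_synthesis(model, p$features))
  list(model = model, maps = maps)
}

#' Run the joint synthesis-registration VEM loop
#'
#' Alternates the mean-field E-step and the forest-refit M-step, starting
#' from uniform beliefs and a forest trained under them, until the
#' relative L2 change of the predicted mean map falls below
#' `config$outer_tol` or `config$max_outer` iterations are reached
#' (convergence is assessed on the prediction maps because the forest
#' parameters themselves vary with the injected randomness; the stochastic
#' M-step means monotone convergence is not guaranteed).
#'
#' @param pairs a list of image pairs; each element is a list with `M`
#'   (MRI [image2d]), `H` (histology [image2d]) and optionally
#'   `landmarks` (a [landmark_set]).
#' @param config a [reg_config].
#' @param seed master integer seed.
#' @param checkpoint_dir optional directory; per-iteration expected
#'   displacement and entropy maps are written there.
#' @param verbose print per-iteration map-change statistics.
#' @return An object of class `vem_state`: `beliefs` (list of q matrices),
#'   `model`, `maps`, `labels`, `iterations`, `history` (data frame of
#'   per-iteration relative map changes), `converged`, `pairs_cache`.
#' @export
run_vem <- function(pairs, config = reg_config(), seed = 1,
                    checkpoint_dir = NULL, verbose = FALSE) {
  N <- length(pairs)
  stopifnot(N >= 1)
  labels <- label_set(config$label_radius, config$label_step)
  S <- length(labels)
  for (n in seq_len(N)) {
    p <- pairs[[n]]
    stopifnot(inherits(p$M, "image2d"), inherits(p$H, "image2d"))
    pairs[[n]]$features <- extract_features(p$H)
    pairs[[n]]$warp_cache <- warp_cache(p$M, labels)
    pairs[[n]]$q <- init_beliefs(prod(dim(p$M$pixels)), S)
  }
  fit <- mstep_update(pairs, labels, config, seed = derive_seed(seed, 0))
  model <- fit$model
  maps <- fit$maps
  history <- data.frame(iteration = integer(0), mu_change = numeric(0),
                        var_change = numeric(0), mean_entropy = numeric(0),
                        e_sweeps = integer(0))
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_outer) {
    iter <- iter + 1L
    # E-step (per pair, independent given theta)
    sweeps <- 0L
    for (n in seq_len(N)) {
      es <- estep_update(pairs[[n]]$q, maps[[n]], pairs[[n]]$M,
                         pairs[[n]]$landmarks, labels, config,
                         warp = pairs[[n]]$warp_cache)
      pairs[[n]]$q <- es$q
      sweeps <- sweeps + es$n_sweeps
    }
    # M-step
    fit <- mstep_update(pairs, labels, config, seed = derive_seed(seed, iter))
    model <- fit$model
    new_maps <- fit$maps
    rel <- function(new, old) {
      den <- sqrt(sum(unlist(old)^2))
      if (den == 0) return(Inf)
      sqrt(sum((unlist(new) - unlist(old))^2)) / den
    }
    mu_change <- rel(lapply(new_maps, `[[`, "mu"), lapply(maps, `[[`, "mu"))
    var_change <- rel(lapply(new_maps, `[[`, "var"), lapply(maps, `[[`, "var"))
    maps <- new_maps
    ment <- mean(vapply(pairs, function(p) mean(belief_entropy(p$q)),
                        numeric(1)))
    history <- rbind(history, data.frame(
      iteration = iter, mu_change = mu_change, var_change = var_change,
      mean_entropy = ment, e_sweeps = sweeps))
    if (verbose)
      message(sprintf("iter %d: mu change %.4f, var change %.4f, mean H(q) %.3f",
                      iter, mu_change, var_change, ment))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      for (n in seq_len(N)) {
        ed <- expected_displacement(pairs[[n]]$q, labels,
                                    dim(pairs[[n]]$M$pixels),
                                    pairs[[n]]$M$spacing)
        write_field(ed$field, file.path(checkpoint_dir,
                                        sprintf("iter%02d_pair%02d_edisp.nii.gz",
                                                iter, n)))
        ent <- matrix(ed$entropy, dim(pairs[[n]]$M$pixels)[1])
        write_image(image2d(rescale_intensities(ent),
                            pairs[[n]]$M$spacing),
                    file.path(checkpoint_dir,
                              sprintf("iter%02d_pair%02d_entropy.png", iter, n)))
      }
    }
    if (mu_change < config$outer_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("VEM did not converge within ", config$max_outer,
            " outer iterations; returning the final state")
  structure(list(beliefs = lapply(pairs, `[[`, "q"),
                 model = model, maps = maps, labels = labels,
                 iterations = iter, history = history,
                 converged = converged,
                 pairs_cache = pairs),
            class = "vem_state")
}

#' @export
print.vem_state <- function(x, ...) {
  cat(sprintf("<vem_state> %d pair(s), %d iteration(s), converged: %s\n",
              length(x$beliefs), x$iterations, x$converged))
  invisible(x)
}
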