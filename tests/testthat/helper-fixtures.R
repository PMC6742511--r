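# Small deterministic fixtures shared across tests. Everything is built in
# code; nothing is read from disk.

ramp_image <- function(n = 32, spacing = 1) {
  image2d(matrix(rep(seq_len(n) - 1, each = n), n, n), spacing)
}

random_image <- function(n = 16, spacing = 1, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  image2d(matrix(runif(n * n, lo, hi), n, n), spacing)
}

zero_field <- function(n = 16, spacing = 1) {
  deformation_field(matrix(0, n, n), matrix(0, n, n), spacing)
}

const_field <- function(n, dx, dy, spacing = 1) {
  deformation_field(matrix(dx, n, n), matrix(dy, n, n), spacing)
}

random_maps <- function(n = 16, seed = 1, var_lo = 1, var_hi = 100) {
  set.seed(seed)
  structure(list(mu = matrix(runif(n * n, 0, 255), n, n),
                 var = matrix(runif(n * n, var_lo, var_hi), n, n)),
            class = "prediction_maps")
}

small_phantom_spec <- function(n = 64) {
  phantom_spec(shape = c(n, n))
}

# reduced-cost configuration used by the smaller end-to-end tests
fast_config <- function(...) {
  reg_config(n_trees = 10, label_radius = 4, label_step = 1,
             max_outer = 3, max_inner = 25, ...)
}

# brute-force per-pixel enumeration of the closed-form belief update for
# beta2 = 0 and no landmarks (independent oracle for the E-step)
bruteforce_beliefs <- function(M, maps, labels, beta1) {
  wc <- warp_cache(M, labels)
  S <- length(labels)
  npix <- nrow(wc$value)
  d2 <- rowSums(labels$deltas^2)
  q <- matrix(0, npix, S)
  mu <- as.vector(maps$mu)
  v <- as.vector(maps$var)
  for (p in seq_len(npix)) {
    li <- dnorm(wc$value[p, ], mu[p], sqrt(v[p]))
    oob <- wc$oob[p, ]
    if (any(oob)) li[oob] <- mean(li[!oob])
    li <- li * exp(-beta1 * d2)
    q[p, ] <- li / sum(li)
  }
  q
}

# exact minimiser of a small discrete grid energy by dynamic programming
# over row states (independent oracle for the graph cut); feasible for
# W <= 4 columns and S <= 9 labels
exact_grid_min <- function(energy) {
  H <- energy$shape[1]; W <- energy$shape[2]
  S <- nrow(energy$labels$deltas)
  d <- energy$labels$deltas
  V <- energy$beta2 *
    (outer(d[, 1], d[, 1], "-")^2 + outer(d[, 2], d[, 2], "-")^2)
  U <- energy$unary
  # states: label assignment of one row (pixels in a row share the y index;
  # pixels within a row are horizontal neighbours)
  states <- as.matrix(expand.grid(rep(list(seq_len(S)), W)))
  ns <- nrow(states)
  row_cost <- function(r) {
    cost <- numeric(ns)
    for (c in seq_len(W)) {
      p <- (c - 1) * H + r
      cost <- cost + U[p, states[, c]]
      if (c > 1) cost <- cost + V[cbind(states[, c - 1], states[, c])]
    }
    cost
  }
  f <- row_cost(1)
  for (r in 2:H) {
    # min-plus transition: per-column decomposable cost
    g <- f
    for (c in seq_len(W)) {
      arr <- matrix(g, nrow = S^(c - 1))
      # dimension c of the state index varies with period S^(c-1)
      gn <- numeric(ns)
      dim3 <- ns / S^c
      idx <- array(seq_len(ns), dim = c(S^(c - 1), S, dim3))
      for (b in seq_len(S)) {
        # min over previous label a in column c
        m <- apply(array(g[idx] + rep(V[, b], each = S^(c - 1)),
                         dim = dim(idx)), c(1, 3), min)
        gn[idx[, b, ]] <- m
      }
      g <- gn
    }
    f <- g + row_cost(r)
  }
  min(f)
}
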