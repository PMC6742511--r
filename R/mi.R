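# ---------------------------------------------------------------------------
# Mutual-information baseline: histogram MI estimate and B-spline
# registration driven by -MI with the same landmark and regularisation
# terms as the proposed method.
# ---------------------------------------------------------------------------

#' Mutual information of two intensity vectors
#'
#' Joint-histogram estimate with hard binning: each image is min-max
#' scaled to the bin range and counted into `bins` equal-width bins.
#' Degenerate (constant) images have zero mutual information by
#' convention.
#'
#' @param x,y numeric vectors of equal length (paired intensities).
#' @param bins number of histogram bins per axis.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 64) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n == 0) return(0)
  bx <- hard_bins(x, bins)
  by <- hard_bins(y, bins)
  if (is.null(bx) || is.null(by)) return(0)  # constant image
  p <- table_counts(bx, by, bins) / n
  pi_ <- rowSums(p)
  pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(outer(pi_, pj))[nz]))
}

# hard binning after min-max scaling; NULL for a constant vector
hard_bins <- function(x, bins) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(NULL)
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins)
  pmin(b, bins - 1L) + 1L
}

table_counts <- function(bx, by, bins) {
  idx <- (by - 1L) * bins + bx
  matrix(tabulate(idx, nbins = bins * bins), bins, bins)
}

# Soft (linear-kernel) joint histogram of the warped MRI against the fixed
# histology bins, with the analytic MI gradient w.r.t. the warped
# intensities. Used only inside the MI optimiser, which needs a
# differentiable estimate; reported MI values use the hard-binned
# estimator above.
soft_mi <- function(m, valid, jbin, bins, m_rng, grad = FALSE) {
  n_valid <- sum(valid)
  if (n_valid == 0 || m_rng[2] - m_rng[1] <= 0)
    return(list(mi = 0, dmi_dm = numeric(length(m))))
  scale <- (bins - 1) / (m_rng[2] - m_rng[1])
  t_ <- (m - m_rng[1]) * scale
  t_ <- pmin(pmax(t_, 0), bins - 1)
  i0 <- pmin(floor(t_), bins - 2)
  f <- t_ - i0
  w0 <- 1 - f
  v <- which(valid)
  idx0 <- (jbin[v] - 1L) * bins + i0[v] + 1L
  acc <- rowsum(c(w0[v], f[v]), c(idx0, idx0 + 1L))
  p <- numeric(bins * bins)
  p[as.integer(rownames(acc))] <- acc / n_valid
  P <- matrix(p, bins, bins)        # rows: M bins, cols: H bins
  pm <- rowSums(P)
  ph <- colSums(P)
  nz <- P > 0
  lr <- matrix(0, bins, bins)
  lr[nz] <- log(P[nz]) - log(pm[row(P)[nz]]) - log(ph[col(P)[nz]])
  mi <- sum(P[nz] * lr[nz])
  if (!grad) return(list(mi = mi))
  # d MI / d t for each valid pixel: weight moves from bin i0 to i0+1
  eps <- 1e-12
  lr_at <- function(i, j) {
    pij <- P[cbind(i, j)]
    log(pij + eps) - log(pm[i] + eps) - log(ph[j] + eps)
  }
  dmi_dt <- numeric(length(m))
  dmi_dt[v] <- (lr_at(i0[v] + 2L, jbin[v]) - lr_at(i0[v] + 1L, jbin[v])) /
    n_valid
  clipped <- t_ <= 0 | t_ >= bins - 1
  dmi_dt[clipped] <- 0
  list(mi = mi, dmi_dm = dmi_dt * scale)
}

#' Mutual-information B-spline registration (baseline)
#'
#' Minimises \eqn{-MI[M(V(x;\Psi)), H(x)] + \frac{1}{2\sigma_k^2}\sum_l
#' \|V(k^h_l) - k_l\|^2 + \beta_b E_b + \beta_l E_l + \beta_j E_j} over
#' the same cubic B-spline deformation model as [refine_bspline],
#' starting from the identity. The optimised MI uses a linear-kernel
#' (partial-volume style) histogram so the objective is differentiable;
#' the hard-binned [mutual_information] of the result is reported
#' alongside.
#'
#' @param M the MRI [image2d] (floating image).
#' @param H the histology [image2d] (reference image).
#' @param landmarks a [landmark_set] or `NULL`.
#' @param config a [reg_config] (`mi_bins`, `sigma_k`, `beta_b`,
#'   `beta_l`, `beta_j`).
#' @param cp_spacing control-point spacing in mm (default
#'   `config$cp_spacing_mi`).
#' @param maxit L-BFGS-B iteration cap.
#' @return A list with `field`, `psi`, `basis`, `value`, `mi` (hard-binned
#'   MI of the warped pair) and `convergence`.
#' @export
register_mi <- function(M, H, landmarks = NULL, config = reg_config(),
                        cp_spacing = NULL, maxit = 200) {
  stopifnot(inherits(M, "image2d"), inherits(H, "image2d"))
  if (!identical(dim(M$pixels), dim(H$pixels)))
    stop("image shapes must match")
  if (is.null(cp_spacing)) cp_spacing <- config$cp_spacing_mi
  basis <- bspline_basis(dim(M$pixels), M$spacing, cp_spacing)
  bins <- config$mi_bins
  sp <- basis$spacing
  Hh <- basis$shape[1]; Ww <- basis$shape[2]
  npix <- Hh * Ww
  ncp <- basis$ncp
  cc <- rep(0:(Ww - 1), each = Hh)
  rr <- rep(0:(Hh - 1), times = Ww)
  jbin <- hard_bins(as.vector(H$pixels), bins)
  if (is.null(jbin)) jbin <- rep(1L, npix)  # constant reference: MI = 0
  m_rng <- range(M$pixels)

  eval_obj <- function(psi, grad = FALSE) {
    psi_x <- psi[1:ncp]; psi_y <- psi[ncp + 1:ncp]
    ux <- as.vector(basis$P %*% psi_x)
    uy <- as.vector(basis$P %*% psi_y)
    smp <- cpp_bilinear_grad(M$pixels, cc + ux / sp, rr + uy / sp)
    sm <- soft_mi(smp$value, smp$valid, jbin, bins, m_rng, grad = grad)
    reg <- bspline_objective(psi, basis, M, NULL, landmarks, config,
                             gradient = grad)
    val <- -sm$mi + reg$value
    if (!grad) return(list(value = val))
    gmi_x <- as.vector(Matrix::crossprod(basis$P, -sm$dmi_dm * smp$gx / sp))
    gmi_y <- as.vector(Matrix::crossprod(basis$P, -sm$dmi_dm * smp$gy / sp))
    g <- reg$gradient
    g[1:ncp] <- g[1:ncp] + gmi_x
    g[ncp + 1:ncp] <- g[ncp + 1:ncp] + gmi_y
    list(value = val, gradient = g)
  }

  fn <- function(p) eval_obj(p)$value
  gr <- function(p) eval_obj(p, grad = TRUE)$gradient
  opt <- optim(rep(0, 2 * ncp), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  field <- psi_to_field(basis, opt$par)
  warped <- warp_image(M, field)
  ok <- as.vector(warped$mask)
  mi_final <- mutual_information(as.vector(warped$pixels)[ok],
                                 as.vector(H$pixels)[ok], bins)
  list(field = field, psi = opt$par, basis = basis, value = opt$value,
       mi = mi_final, convergence = opt$convergence)
}
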