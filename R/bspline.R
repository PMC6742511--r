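# ---------------------------------------------------------------------------
# Free-form deformation: cubic B-spline control grid, analytic bases for
# value / first / second derivatives, regularisation energies, and the
# gradient-based refinement of the registration.
# ---------------------------------------------------------------------------

# cubic B-spline basis and derivatives at fractional offset u in [0, 1)
bspl3 <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}
bspl3_d1 <- function(u) {
  cbind(-(1 - u)^2 / 2,
        (3 * u^2 - 4 * u) / 2,
        (-3 * u^2 + 2 * u + 1) / 2,
        u^2 / 2)
}
bspl3_d2 <- function(u) {
  cbind(1 - u, 3 * u - 2, 1 - 3 * u, u)
}

# sparse basis matrices mapping control-point coefficients to per-point
# displacement values and derivatives (derivatives per mm)
basis_rows <- function(x_mm, y_mm, cps, ncx, ncy, what = "v") {
  gx <- x_mm / cps
  gy <- y_mm / cps
  ix <- floor(gx); iy <- floor(gy)
  ux <- gx - ix;   uy <- gy - iy
  bx <- switch(substr(what, 1, 1),
               v = bspl3(ux), x = bspl3_d1(ux) / cps, X = bspl3_d2(ux) / cps^2)
  by <- switch(substr(what, 2, 2),
               v = bspl3(uy), y = bspl3_d1(uy) / cps, Y = bspl3_d2(uy) / cps^2)
  n <- length(x_mm)
  ii <- jj <- vv <- vector("list", 16)
  k <- 0
  for (l in 0:3) {
    for (m in 0:3) {
      k <- k + 1
      # control point (ix + l - 1, iy + m - 1), offset +1 for the margin row
      col <- (ix + l) * ncy + (iy + m) + 1
      ii[[k]] <- seq_len(n)
      jj[[k]] <- col
      vv[[k]] <- bx[, l + 1] * by[, m + 1]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, ncx * ncy))
}

#' Cubic B-spline transform basis for an image domain
#'
#' Builds the sparse matrices that map control-point coefficients to the
#' dense displacement field and its first and second spatial derivatives
#' on the pixel grid. The control grid covers the image extent with a
#' one-point margin on every side.
#'
#' @param shape image shape (H, W) in pixels.
#' @param spacing pixel size in mm.
#' @param cp_spacing control-point spacing in mm.
#' @return A list with sparse matrices `P`, `Px`, `Py`, `Pxx`, `Pxy`,
#'   `Pyy` (npix rows), the control-grid dimensions, and `basis_at(pts)`
#'   returning the value basis at arbitrary (x, y) mm points.
#' @export
bspline_basis <- function(shape, spacing, cp_spacing) {
  stopifnot(cp_spacing > 0)
  H <- shape[1]; W <- shape[2]
  ext_x <- (W - 1) * spacing
  ext_y <- (H - 1) * spacing
  ncx <- floor(ext_x / cp_spacing) + 4L  # indices -1 .. nx + 2
  ncy <- floor(ext_y / cp_spacing) + 4L
  x <- rep(0:(W - 1), each = H) * spacing
  y <- rep(0:(H - 1), times = W) * spacing
  mk <- function(code) basis_rows(x, y, cp_spacing, ncx, ncy, code)
  structure(list(
    P = mk("vv"), Px = mk("xv"), Py = mk("vy"),
    Pxx = mk("Xv"), Pxy = mk("xy"), Pyy = mk("vY"),
    ncx = ncx, ncy = ncy, ncp = ncx * ncy,
    cp_spacing = cp_spacing, shape = shape, spacing = spacing,
    basis_at = function(pts)
      basis_rows(pts[, 1], pts[, 2], cp_spacing, ncx, ncy, "vv")),
    class = "bspline_basis")
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("<bspline_basis> %d x %d control points, spacing %g mm\n",
              x$ncx, x$ncy, x$cp_spacing))
  invisible(x)
}

# least-squares projection of a dense field onto the control grid
fit_psi_to_field <- function(basis, field) {
  P <- basis$P
  A <- Matrix::crossprod(P) + Matrix::Diagonal(basis$ncp, 1e-8)
  psi_x <- Matrix::solve(A, Matrix::crossprod(P, as.vector(field$dx)))
  psi_y <- Matrix::solve(A, Matrix::crossprod(P, as.vector(field$dy)))
  c(as.vector(psi_x), as.vector(psi_y))
}

psi_to_field <- function(basis, psi) {
  ncp <- basis$ncp
  ux <- as.vector(basis$P %*% psi[1:ncp])
  uy <- as.vector(basis$P %*% psi[ncp + 1:ncp])
  deformation_field(matrix(ux, basis$shape[1]), matrix(uy, basis$shape[1]),
                    spacing = basis$spacing)
}

#' Evaluate the B-spline registration objective
#'
#' The objective is
#' \deqn{\alpha \sum_x \frac{[M(V(x)) - \mu_x]^2}{2\sigma^2_x}
#'  + \frac{1}{2\sigma_k^2} \sum_l \|V(k^h_l) - k_l\|^2
#'  + \beta_b E_b + \beta_l E_l + \beta_j E_j,}
#' with `alpha = 2 / (9 |Omega|)` so the image term equals 1 when every
#' pixel's residual is three predicted standard deviations. `E_b` is the
#' mean squared second derivative (bending energy), `E_l` the mean squared
#' symmetric part of the displacement Jacobian (the transform Jacobian
#' with rotation/identity removed; penalises stretch and shear), and
#' `E_j` the mean squared log-Jacobian-determinant (weight 0 by default).
#' Out-of-bounds image samples are excluded from the image term.
#'
#' @param psi coefficient vector `c(psi_x, psi_y)`.
#' @param basis a [bspline_basis].
#' @param M the MRI [image2d].
#' @param maps `prediction_maps` (means and variances of the synthesis).
#' @param landmarks a [landmark_set] or `NULL`.
#' @param config a [reg_config] (weights `beta_b`, `beta_l`, `beta_j`,
#'   `sigma_k`).
#' @param gradient also return the analytic gradient.
#' @return A list with `value`, `parts` (named term values) and, when
#'   requested, `gradient`.
#' @export
bspline_objective <- function(psi, basis, M, maps, landmarks,
                              config = reg_config(), gradient = FALSE) {
  H <- basis$shape[1]; W <- basis$shape[2]
  npix <- H * W
  ncp <- basis$ncp
  sp <- basis$spacing
  psi_x <- psi[1:ncp]; psi_y <- psi[ncp + 1:ncp]
  ux <- as.vector(basis$P %*% psi_x)
  uy <- as.vector(basis$P %*% psi_y)
  img <- 0
  if (!is.null(maps)) {
    cc <- rep(0:(W - 1), each = H)
    rr <- rep(0:(H - 1), times = W)
    smp <- cpp_bilinear_grad(M$pixels, cc + ux / sp, rr + uy / sp)
    alpha <- 2 / (9 * npix)
    v <- as.vector(maps$var)
    r <- smp$value - as.vector(maps$mu)
    wv <- ifelse(smp$valid, alpha / (2 * v), 0)
    img <- sum(wv * r^2)
  }

  lmv <- 0
  if (!is.null(landmarks) && length(landmarks) > 0) {
    Bl <- basis$basis_at(landmarks$hist)
    vx <- landmarks$hist[, 1] + as.vector(Bl %*% psi_x) - landmarks$mri[, 1]
    vy <- landmarks$hist[, 2] + as.vector(Bl %*% psi_y) - landmarks$mri[, 2]
    lmv <- sum(vx^2 + vy^2) / (2 * landmarks$sigma_k^2)
  }

  bxx_x <- as.vector(basis$Pxx %*% psi_x); bxy_x <- as.vector(basis$Pxy %*% psi_x)
  byy_x <- as.vector(basis$Pyy %*% psi_x)
  bxx_y <- as.vector(basis$Pxx %*% psi_y); bxy_y <- as.vector(basis$Pxy %*% psi_y)
  byy_y <- as.vector(basis$Pyy %*% psi_y)
  Eb <- mean(bxx_x^2 + 2 * bxy_x^2 + byy_x^2 +
               bxx_y^2 + 2 * bxy_y^2 + byy_y^2)

  exx <- as.vector(basis$Px %*% psi_x)
  eyy <- as.vector(basis$Py %*% psi_y)
  dyx <- as.vector(basis$Py %*% psi_x)
  dxy <- as.vector(basis$Px %*% psi_y)
  exy <- (dyx + dxy) / 2
  El <- mean(exx^2 + eyy^2 + 2 * exy^2)

  Ej <- 0
  detj <- NULL
  if (config$beta_j > 0) {
    detj <- pmax((1 + exx) * (1 + eyy) - dyx * dxy, 1e-6)
    Ej <- mean(log(detj)^2)
  }

  value <- img + lmv + config$beta_b * Eb + config$beta_l * El +
    config$beta_j * Ej
  out <- list(value = value,
              parts = c(image = img, landmark = lmv, bending = Eb,
                        elastic = El, jacobian = Ej))
  if (!gradient) return(out)

  # image term
  gx <- gy <- rep(0, ncp)
  if (!is.null(maps)) {
    gx <- as.vector(Matrix::crossprod(basis$P, 2 * wv * r * smp$gx / sp))
    gy <- as.vector(Matrix::crossprod(basis$P, 2 * wv * r * smp$gy / sp))
  }
  # landmark term
  if (!is.null(landmarks) && length(landmarks) > 0) {
    gx <- gx + as.vector(Matrix::crossprod(Bl, vx)) / landmarks$sigma_k^2
    gy <- gy + as.vector(Matrix::crossprod(Bl, vy)) / landmarks$sigma_k^2
  }
  # bending energy
  gx <- gx + config$beta_b * (2 / npix) *
    as.vector(Matrix::crossprod(basis$Pxx, bxx_x) +
                2 * Matrix::crossprod(basis$Pxy, bxy_x) +
                Matrix::crossprod(basis$Pyy, byy_x))
  gy <- gy + config$beta_b * (2 / npix) *
    as.vector(Matrix::crossprod(basis$Pxx, bxx_y) +
                2 * Matrix::crossprod(basis$Pxy, bxy_y) +
                Matrix::crossprod(basis$Pyy, byy_y))
  # stretch/shear energy
  gx <- gx + config$beta_l * (2 / npix) *
    as.vector(Matrix::crossprod(basis$Px, exx) +
                Matrix::crossprod(basis$Py, exy))
  gy <- gy + config$beta_l * (2 / npix) *
    as.vector(Matrix::crossprod(basis$Py, eyy) +
                Matrix::crossprod(basis$Px, exy))
  # log-Jacobian energy
  if (config$beta_j > 0) {
    w <- config$beta_j * 2 * log(detj) / detj / npix
    gx <- gx + as.vector(Matrix::crossprod(basis$Px, w * (1 + eyy)) -
                           Matrix::crossprod(basis$Py, w * dxy))
    gy <- gy + as.vector(Matrix::crossprod(basis$Py, w * (1 + exx)) -
                           Matrix::crossprod(basis$Px, w * dyx))
  }
  out$gradient <- c(gx, gy)
  out
}

#' Refine a registration with the B-spline deformation model
#'
#' Quasi-Newton (L-BFGS-B) minimisation of [bspline_objective], starting
#' from the least-squares projection of `init_field` onto the control grid
#' (or from the identity). This is a single-level optimiser with analytic
#' gradients; no multi-resolution pyramid is used.
#'
#' @param M the MRI [image2d].
#' @param maps `prediction_maps` from the fitted synthesis.
#' @param landmarks a [landmark_set] or `NULL`.
#' @param init_field optional [deformation_field] initialisation.
#' @param config a [reg_config].
#' @param cp_spacing control-point spacing in mm (default
#'   `config$cp_spacing`).
#' @param maxit L-BFGS-B iteration cap.
#' @return A list with `field`, `psi`, `basis`, `value`, `parts`,
#'   `trace` (objective per evaluation) and `convergence`.
#' @export
refine_bspline <- function(M, maps, landmarks = NULL, init_field = NULL,
                           config = reg_config(), cp_spacing = NULL,
                           maxit = 200) {
  stopifnot(inherits(M, "image2d"))
  if (is.null(cp_spacing)) cp_spacing <- config$cp_spacing
  basis <- bspline_basis(dim(M$pixels), M$spacing, cp_spacing)
  psi0 <- if (is.null(init_field)) rep(0, 2 * basis$ncp) else
    fit_psi_to_field(basis, init_field)
  trace <- numeric(0)
  fn <- function(p) {
    o <- bspline_objective(p, basis, M, maps, landmarks, config)
    if (!is.finite(o$value))
      stop("non-finite registration objective; parts: ",
           paste(sprintf("%s=%.3g", names(o$parts), o$parts), collapse = ", "))
    trace <<- c(trace, o$value)
    o$value
  }
  gr <- function(p)
    bspline_objective(p, basis, M, maps, landmarks, config,
                      gradient = TRUE)$gradient
  opt <- optim(psi0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  final <- bspline_objective(opt$par, basis, M, maps, landmarks, config)
  list(field = psi_to_field(basis, opt$par), psi = opt$par, basis = basis,
       value = final$value, parts = final$parts, trace = trace,
       convergence = opt$convergence)
}
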