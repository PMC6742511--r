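# ---------------------------------------------------------------------------
# Displacement label set, MRF prior, field application, and diffeomorphic
# field generation by scaling and squaring.
# ---------------------------------------------------------------------------

#' Discrete displacement label set
#'
#' The finite set of candidate 2D displacements: the full square grid
#' \eqn{[-radius, radius]^2} in increments of `step`, in mm. The default
#' (radius 10 mm, step 0.5 mm) gives \eqn{41^2 = 1681} labels and always
#' contains the zero displacement.
#'
#' @param radius_mm grid radius in mm (integer multiple of `step_mm`).
#' @param step_mm grid increment in mm.
#' @return An object of class `label_set` with fields `deltas` (S x 2
#'   matrix, columns dx, dy in mm), `radius`, `step`.
#' @export
label_set <- function(radius_mm = 10, step_mm = 0.5) {
  if (step_mm <= 0 || radius_mm < step_mm)
    stop("need radius >= step > 0")
  k <- radius_mm / step_mm
  if (abs(k - round(k)) > 1e-9)
    stop("radius must be an integer multiple of step")
  ax <- seq(-radius_mm, radius_mm, by = step_mm)
  g <- expand.grid(dx = ax, dy = ax)
  deltas <- as.matrix(g)
  dimnames(deltas) <- list(NULL, c("dx", "dy"))
  structure(list(deltas = deltas, radius = radius_mm, step = step_mm),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d labels, radius %g mm, step %g mm\n",
              nrow(x$deltas), x$radius, x$step))
  invisible(x)
}

#' @export
length.label_set <- function(x) nrow(x$deltas)

#' Warp an image by a displacement field
#'
#' Computes `out(x) = M(x + U(x))` by bilinear interpolation. Samples that
#' fall outside the image take the value 0 and are flagged invalid in the
#' output mask.
#'
#' @param img an [image2d] (the image being resampled).
#' @param field a [deformation_field] on the output grid, in mm.
#' @return An [image2d] whose `mask` marks in-bounds samples.
#' @export
warp_image <- function(img, field) {
  stopifnot(inherits(img, "image2d"), inherits(field, "deformation_field"))
  if (!identical(dim(img$pixels), dim(field$dx)))
    stop("image and field shapes must match")
  d <- dim(img$pixels)
  sp <- img$spacing
  cc <- rep(0:(d[2] - 1), each = d[1])
  rr <- rep(0:(d[1] - 1), times = d[2])
  res <- cpp_bilinear(img$pixels,
                      cc + as.vector(field$dx) / sp,
                      rr + as.vector(field$dy) / sp)
  out <- matrix(res$value, d[1], d[2])
  msk <- matrix(res$valid, d[1], d[2])
  image2d(out, spacing = sp, mask = msk)
}

#' Log-prior of a displacement field under the MRF model
#'
#' Returns \eqn{-\beta_1 \sum_x \|U(x)\|^2 - \beta_2 \sum_{(x,x')}
#' \|U(x) - U(x')\|^2} over 4-neighbour pairs (each unordered pair counted
#' once), i.e. the log of the MRF prior up to its normalising constant,
#' which is never evaluated. It is maximal (zero) uniquely at the zero
#' field when `beta1 > 0`.
#'
#' @param field a [deformation_field].
#' @param beta1 unary weight (>= 0), penalising squared displacement norm.
#' @param beta2 pairwise weight (>= 0), penalising the squared gradient.
#' @return A scalar log-prior (up to a constant).
#' @export
mrf_log_prior <- function(field, beta1, beta2) {
  stopifnot(inherits(field, "deformation_field"), beta1 >= 0, beta2 >= 0)
  dx <- field$dx; dy <- field$dy
  unary <- sum(dx^2 + dy^2)
  H <- nrow(dx); W <- ncol(dx)
  pair <- 0
  if (H > 1)
    pair <- pair + sum((dx[-1, ] - dx[-H, ])^2 + (dy[-1, ] - dy[-H, ])^2)
  if (W > 1)
    pair <- pair + sum((dx[, -1] - dx[, -W])^2 + (dy[, -1] - dy[, -W])^2)
  -beta1 * unary - beta2 * pair
}

# Gaussian kernel covering +-4 sigma (in pixels); returns 1 for sigma ~ 0
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 1e-12) return(1)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k / sum(k)
}

gaussian_smooth <- function(mat, sigma_px) {
  k <- gauss_kernel(sigma_px)
  if (length(k) == 1L) return(mat)
  cpp_sepconv(mat, k)
}

#' Sample a random smooth velocity field
#'
#' Draws i.i.d. bivariate Gaussian noise (no x-y correlation) of standard
#' deviation `sigma_v` at each pixel, smooths each component with a
#' Gaussian filter, and multiplies by a boundary window
#' `w(x) = 1 - exp(-0.01 D(x))`, where `D(x)` is the distance to the image
#' boundary in mm, so that the velocity vanishes at the boundary and
#' approaches the unwindowed field in the interior.
#'
#' @param shape integer vector (H, W) in pixels.
#' @param spacing pixel size in mm.
#' @param sigma_v noise standard deviation in mm (>= 0).
#' @param smooth_sigma_mm Gaussian smoothing standard deviation in mm.
#' @param seed integer seed.
#' @param window apply the boundary window (default `TRUE`).
#' @return An object of class `velocity_field` with fields `vx`, `vy`
#'   (mm), `spacing`, `sigma_v`, `smooth_sigma`.
#' @export
sample_velocity <- function(shape, spacing = 1, sigma_v = 10,
                            smooth_sigma_mm = 5, seed = 1, window = TRUE) {
  stopifnot(sigma_v >= 0)
  H <- shape[1]; W <- shape[2]
  vx <- vy <- matrix(0, H, W)
  if (sigma_v > 0) {
    noise <- with_seed(seed, list(
      vx = matrix(rnorm(H * W, sd = sigma_v), H, W),
      vy = matrix(rnorm(H * W, sd = sigma_v), H, W)))
    vx <- noise$vx
    vy <- noise$vy
    sig_px <- smooth_sigma_mm / spacing
    vx <- gaussian_smooth(vx, sig_px)
    vy <- gaussian_smooth(vy, sig_px)
    if (window) {
      w <- boundary_window(c(H, W), spacing)
      vx <- vx * w
      vy <- vy * w
    }
  }
  structure(list(vx = vx, vy = vy, spacing = spacing, sigma_v = sigma_v,
                 smooth_sigma = smooth_sigma_mm),
            class = "velocity_field")
}

# w(x) = 1 - exp(-0.01 * D(x)), D = distance to boundary in mm; exactly 0 on
# the boundary pixels and -> 1 in the interior.
boundary_window <- function(shape, spacing) {
  H <- shape[1]; W <- shape[2]
  ry <- pmin(0:(H - 1), (H - 1):0) * spacing
  rx <- pmin(0:(W - 1), (W - 1):0) * spacing
  D <- outer(ry, rx, pmin)
  1 - exp(-0.01 * D)
}

#' Integrate a stationary velocity field (scaling and squaring)
#'
#' Integrates the flow of a stationary velocity field over unit time by
#' `n_squarings` recursive self-compositions, yielding a diffeomorphic
#' displacement field. The initial scaling is chosen so that the scaled
#' displacement is below half a pixel; compositions use bilinear
#' resampling.
#'
#' @param vel a `velocity_field` (see [sample_velocity]).
#' @param n_squarings number of squarings; when `NULL`, chosen as
#'   `max(4, ceil(log2(max ||v|| / (0.5 * spacing))))`.
#' @return A [deformation_field].
#' @export
integrate_velocity <- function(vel, n_squarings = NULL) {
  stopifnot(inherits(vel, "velocity_field"))
  sp <- vel$spacing
  vmax <- max(sqrt(vel$vx^2 + vel$vy^2))
  if (is.null(n_squarings)) {
    n_squarings <- if (vmax <= 0) 4L else
      max(4L, ceiling(log2(vmax / (0.5 * sp))))
  }
  if (n_squarings < 1) stop("n_squarings must be >= 1")
  ux <- vel$vx / 2^n_squarings
  uy <- vel$vy / 2^n_squarings
  H <- nrow(ux); W <- ncol(ux)
  cc <- rep(0:(W - 1), each = H)
  rr <- rep(0:(H - 1), times = W)
  for (i in seq_len(n_squarings)) {
    xs <- cc + as.vector(ux) / sp
    ys <- rr + as.vector(uy) / sp
    ax <- cpp_bilinear(ux, xs, ys)  # out of bounds -> 0 displacement added
    ay <- cpp_bilinear(uy, xs, ys)
    ux <- ux + matrix(ax$value, H, W)
    uy <- uy + matrix(ay$value, H, W)
  }
  deformation_field(ux, uy, spacing = sp)
}

#' Draw random similarity-transform parameters
#'
#' Rotation, per-axis translation and log-scale are sampled from zero-mean
#' Gaussians with standard deviations 2 degrees, 1 pixel and 0.1.
#'
#' @param seed integer seed.
#' @param sd_rot_deg,sd_trans_px,sd_log_scale the standard deviations.
#' @return A list with `rot_deg`, `trans_px` (length 2), `log_scale`.
#' @export
random_similarity <- function(seed = 1, sd_rot_deg = 2, sd_trans_px = 1,
                              sd_log_scale = 0.1) {
  with_seed(seed, list(rot_deg = rnorm(1, sd = sd_rot_deg),
                       trans_px = rnorm(2, sd = sd_trans_px),
                       log_scale = rnorm(1, sd = sd_log_scale)))
}

#' Compose a displacement field with a similarity transform
#'
#' Returns the displacement of the composed map `A o phi`, where
#' `phi(x) = x + U(x)` is the nonlinear warp and `A` is a similarity
#' transform (rotation `rot_deg`, scale `exp(log_scale)`, translation
#' `trans_px` pixels) about the image centre:
#' `W(x) = A(x + U(x)) - x`. With identity similarity the field is
#' returned unchanged.
#'
#' @param field a [deformation_field] (the nonlinear part).
#' @param rot_deg rotation in degrees.
#' @param log_scale log of the isotropic scale factor.
#' @param trans_px translation in pixels, length-2 (x, y).
#' @return A [deformation_field] of the composed map.
#' @export
compose_with_similarity <- function(field, rot_deg = 0, log_scale = 0,
                                    trans_px = c(0, 0)) {
  stopifnot(inherits(field, "deformation_field"))
  sp <- field$spacing
  H <- nrow(field$dx); W <- ncol(field$dx)
  ctr <- c((W - 1) / 2, (H - 1) / 2) * sp  # (x, y) mm
  th <- rot_deg * pi / 180
  s <- exp(log_scale)
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tmm <- trans_px * sp
  x <- rep(0:(W - 1), each = H) * sp
  y <- rep(0:(H - 1), times = W) * sp
  px <- x + as.vector(field$dx)
  py <- y + as.vector(field$dy)
  qx <- R[1, 1] * (px - ctr[1]) + R[1, 2] * (py - ctr[2]) + ctr[1] + tmm[1]
  qy <- R[2, 1] * (px - ctr[1]) + R[2, 2] * (py - ctr[2]) + ctr[2] + tmm[2]
  deformation_field(matrix(qx - x, H, W), matrix(qy - y, H, W), spacing = sp)
}

#' Finite-difference Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of `phi(x) = x + U(x)` by central finite
#' differences; positive everywhere for diffeomorphic fields.
#'
#' @param field a [deformation_field].
#' @return A matrix of determinants (border computed with one-sided
#'   differences).
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  sp <- field$spacing
  gx <- function(m) {  # d/dx (columns)
    W <- ncol(m)
    cbind(m[, 2] - m[, 1],
          (m[, -(1:2), drop = FALSE] - m[, 1:(W - 2), drop = FALSE]) / 2,
          m[, W] - m[, W - 1]) / sp
  }
  gy <- function(m) {  # d/dy (rows)
    H <- nrow(m)
    rbind(m[2, ] - m[1, ],
          (m[-(1:2), , drop = FALSE] - m[1:(H - 2), , drop = FALSE]) / 2,
          m[H, ] - m[H - 1, ]) / sp
  }
  (1 + gx(field$dx)) * (1 + gy(field$dy)) - gy(field$dx) * gx(field$dy)
}
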