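# ---------------------------------------------------------------------------
# Synthetic data: multi-contrast phantom pairs, ground-truth diffeomorphic
# deformations, Harris-based landmark simulation, and histology-style
# artefacts. The phantoms stand in for preprocessed multi-contrast MRI
# pairs: two modalities share a tissue label map but have unrelated (and
# deliberately non-monotonically related) per-class intensities.
# ---------------------------------------------------------------------------

#' Phantom specification
#'
#' @param shape image shape (H, W) in pixels.
#' @param spacing pixel size in mm.
#' @param n_classes number of tissue classes inside the elliptical "brain".
#' @param int_a,int_b per-class mean intensities for modality A
#'   (histology role) and modality B (MRI role). The defaults are
#'   non-monotonically related so the modalities are genuinely
#'   inter-modality (not affinely related).
#' @param noise_sd additive Gaussian noise standard deviation per modality
#'   (length 2).
#' @param bias_amp amplitude of the smooth multiplicative bias field.
#' @param class_smooth_px smoothing (pixels) of the noise thresholded into
#'   the tissue label map.
#' @param texture_amp per-modality amplitude of a shared smooth zero-mean
#'   texture field (anatomical detail common to both modalities; opposite
#'   signs by default so the modalities remain non-affinely related as a
#'   whole).
#' @param texture_smooth_px smoothing (pixels) of the texture field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128), spacing = 1, n_classes = 3,
                         int_a = c(60, 130, 200), int_b = c(190, 60, 140),
                         noise_sd = c(3, 3), bias_amp = 0.15,
                         class_smooth_px = 6, texture_amp = c(25, -25),
                         texture_smooth_px = 3) {
  stopifnot(length(int_a) == n_classes, length(int_b) == n_classes,
            all(noise_sd >= 0), n_classes >= 1, length(texture_amp) == 2)
  if (anyDuplicated(int_a) || anyDuplicated(int_b))
    stop("class intensities must be distinct within each modality")
  structure(list(shape = shape, spacing = spacing, n_classes = n_classes,
                 int_a = int_a, int_b = int_b, noise_sd = noise_sd,
                 bias_amp = bias_amp, class_smooth_px = class_smooth_px,
                 texture_amp = texture_amp,
                 texture_smooth_px = texture_smooth_px),
            class = "phantom_spec")
}

#' Generate a multi-contrast phantom pair
#'
#' A smooth random tissue label map (thresholded smoothed noise inside an
#' elliptical brain mask) is rendered in two modalities with the per-class
#' intensities of the spec, a smooth multiplicative bias field, and
#' additive Gaussian noise; intensities are rescaled to \[0, 255\] and
#' quantised to 8 bits. Background outside the mask is 0.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed (same seed, identical phantom).
#' @return A list with `A`, `B` (both [image2d] with the brain mask
#'   attached) and `labels` (integer matrix, 0 = background).
#' @export
make_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  mask <- ((xx - cx) / (0.42 * W))^2 + ((yy - cy) / (0.45 * H))^2 <= 1
  draws <- with_seed(seed, list(
    cls = matrix(rnorm(H * W), H, W),
    bias = matrix(rnorm(H * W), H, W),
    tex = matrix(rnorm(H * W), H, W),
    na = matrix(rnorm(H * W, sd = spec$noise_sd[1]), H, W),
    nb = matrix(rnorm(H * W, sd = spec$noise_sd[2]), H, W)))
  smooth_cls <- gaussian_smooth(draws$cls, spec$class_smooth_px)
  tex <- gaussian_smooth(draws$tex, spec$texture_smooth_px)
  tex <- (tex - mean(tex)) / max(sd(tex), 1e-12)
  qs <- quantile(smooth_cls[mask], probs = seq_len(spec$n_classes - 1) /
                   spec$n_classes)
  labels <- matrix(0L, H, W)
  labels[mask] <- as.integer(cut(smooth_cls[mask],
                                 breaks = c(-Inf, qs, Inf), labels = FALSE))
  bias <- gaussian_smooth(draws$bias, max(H, W) / 6)
  if (sd(bias) > 0) bias <- (bias - mean(bias)) / (3 * sd(bias))
  bias <- 1 + spec$bias_amp * pmin(pmax(bias, -1), 1)
  render <- function(ints, tex_amp, noise) {
    img <- matrix(0, H, W)
    for (k in seq_len(spec$n_classes)) img[labels == k] <- ints[k]
    img <- (img + tex_amp * tex) * bias
    img[mask] <- img[mask] + noise[mask]
    img[!mask] <- 0
    round(rescale_intensities(img))
  }
  list(A = image2d(render(spec$int_a, spec$texture_amp[1], draws$na),
                   spec$spacing, mask = mask),
       B = image2d(render(spec$int_b, spec$texture_amp[2], draws$nb),
                   spec$spacing, mask = mask),
       labels = labels)
}

#' Generate a synthetic registration test pair
#'
#' Draws a phantom pair, samples a random diffeomorphic deformation
#' (smoothed windowed Gaussian velocity noise of standard deviation
#' `sigma_v`, integrated by scaling and squaring), composes it with a
#' random similarity transform (standard deviations 2 degrees, 1 pixel,
#' 0.1 log-scale), warps modality B with the composed field, and
#' generates noisy landmark pairs. Two fields are stored: `field_applied`
#' is the displacement actually used to resample B (so re-warping the
#' pristine B with it reproduces the deformed image), and `field_true` is
#' its inverse - the displacement a registration of the deformed B onto A
#' should recover, computed exactly by integrating the negated velocity
#' and inverting the similarity.
#'
#' @param spec a [phantom_spec].
#' @param sigma_v velocity noise standard deviation in mm (10 / 20 / 30
#'   model mild / medium / strong deformations).
#' @param seed integer seed.
#' @param n_landmarks number of landmark pairs to simulate.
#' @param sigma_k landmark placement noise (mm).
#' @param similarity apply the random similarity component (default TRUE).
#' @return An object of class `synthetic_pair`: `H` (modality A,
#'   histology role), `M` (deformed modality B, MRI role), `B_orig`,
#'   `field_applied`, `field_true`, `landmarks`, `mask`, `spec`,
#'   `sigma_v`, `seed`.
#' @export
make_pair <- function(spec, sigma_v = 10, seed = 1, n_landmarks = 0,
                      sigma_k = 0.5, similarity = TRUE) {
  ph <- make_phantom(spec, derive_seed(seed, 1))
  sp <- spec$spacing
  vel <- sample_velocity(spec$shape, sp, sigma_v,
                         smooth_sigma_mm = 5, seed = derive_seed(seed, 2))
  fwd <- integrate_velocity(vel)
  vel_neg <- vel
  vel_neg$vx <- -vel$vx; vel_neg$vy <- -vel$vy
  inv_nl <- integrate_velocity(vel_neg)
  sim <- if (similarity) random_similarity(derive_seed(seed, 3)) else
    list(rot_deg = 0, trans_px = c(0, 0), log_scale = 0)
  applied <- compose_with_similarity(fwd, sim$rot_deg, sim$log_scale,
                                     sim$trans_px)
  warped <- warp_image(ph$B, applied)
  M <- image2d(round(warped$pixels), sp, mask = warped$mask)
  # inverse: phi = A o phi_nl  =>  phi^-1 = phi_nl^-1 o A^-1
  H_ <- spec$shape[1]; W_ <- spec$shape[2]
  ctr <- c((W_ - 1) / 2, (H_ - 1) / 2) * sp
  th <- sim$rot_deg * pi / 180
  s <- exp(sim$log_scale)
  x <- rep(0:(W_ - 1), each = H_) * sp
  y <- rep(0:(H_ - 1), times = W_) * sp
  tmm <- sim$trans_px * sp
  # A^-1(x) = R^-1 (x - t - c) + c
  dxc <- x - tmm[1] - ctr[1]
  dyc <- y - tmm[2] - ctr[2]
  ax <- (cos(th) * dxc + sin(th) * dyc) / s + ctr[1]
  ay <- (-sin(th) * dxc + cos(th) * dyc) / s + ctr[2]
  ivx <- cpp_bilinear(inv_nl$dx, ax / sp, ay / sp)$value
  ivy <- cpp_bilinear(inv_nl$dy, ax / sp, ay / sp)$value
  field_true <- deformation_field(matrix(ax + ivx - x, H_),
                                  matrix(ay + ivy - y, H_), spacing = sp)
  lm <- make_landmarks(ph$A, field_true, n_landmarks, sigma_k,
                       derive_seed(seed, 4))
  structure(list(H = ph$A, M = M, B_orig = ph$B,
                 field_applied = applied, field_true = field_true,
                 landmarks = lm, mask = ph$A$mask, labels = ph$labels,
                 spec = spec, sigma_v = sigma_v, seed = seed, sim = sim),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  mag <- sqrt(x$field_true$dx^2 + x$field_true$dy^2)
  cat(sprintf(
    "<synthetic_pair> %d x %d px, sigma_v %g mm, |u_true| mean %.2f mm, %d landmark(s)\n",
    nrow(x$H$pixels), ncol(x$H$pixels), x$sigma_v, mean(mag),
    length(x$landmarks)))
  invisible(x)
}

# Harris corner response (k = 0.05, 1 px derivative/window smoothing)
harris_response <- function(img, k = 0.05, sigma_px = 1) {
  sm <- gaussian_smooth(img$pixels, sigma_px)
  ix <- deriv_x(sm, 1)
  iy <- deriv_y(sm, 1)
  sxx <- gaussian_smooth(ix * ix, sigma_px)
  syy <- gaussian_smooth(iy * iy, sigma_px)
  sxy <- gaussian_smooth(ix * iy, sigma_px)
  sxx * syy - sxy^2 - k * (sxx + syy)^2
}

#' Simulate spatially spread landmark pairs
#'
#' Iteratively: take the pixel with the highest Harris corner response in
#' the histology image as the next histology landmark, map it through the
#' ground-truth field and corrupt it with Gaussian noise of standard
#' deviation `sigma_k` to obtain the MRI landmark, then multiply the
#' response by the complementary Gaussian
#' \eqn{1 - \exp(-0.5\|x - x_{max}\|^2/\sigma^2)} (with \eqn{\sigma} a
#' tenth of the image dimensions) so later landmarks are pushed away,
#' yielding a spatially spread set. Ties in the argmax are broken in
#' row-major order.
#'
#' @param imageA histology-role [image2d] (corners are detected here).
#' @param truth_field ground-truth [deformation_field] (histology space).
#' @param n_landmarks number of landmarks requested.
#' @param sigma_k placement noise standard deviation (mm).
#' @param seed integer seed.
#' @return A [landmark_set] (possibly smaller than requested if the
#'   response is exhausted, with a warning).
#' @export
make_landmarks <- function(imageA, truth_field, n_landmarks, sigma_k = 0.5,
                           seed = 1) {
  if (n_landmarks == 0)
    return(landmark_set(sigma_k = max(sigma_k, 1e-6)))
  sp <- imageA$spacing
  H <- nrow(imageA$pixels); W <- ncol(imageA$pixels)
  R <- harris_response(imageA)
  R[R < 0] <- 0
  sig <- mean(c(H, W)) * sp / 10
  yy <- matrix(0:(H - 1), H, W) * sp
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE) * sp
  noise <- with_seed(seed, matrix(rnorm(2 * n_landmarks, sd = sigma_k),
                                  ncol = 2))
  hist_pts <- mri_pts <- matrix(numeric(0), 0, 2)
  for (l in seq_len(n_landmarks)) {
    if (max(R) <= 0) {
      warning("Harris response exhausted after ", l - 1, " landmarks")
      break
    }
    # row-major argmax (ties broken along rows first)
    idx <- which.max(t(R))
    r0 <- (idx - 1) %/% W
    c0 <- (idx - 1) %% W
    kh <- c(c0, r0) * sp
    u <- c(truth_field$dx[r0 + 1, c0 + 1], truth_field$dy[r0 + 1, c0 + 1])
    km <- kh + u + if (sigma_k > 0) noise[l, ] else c(0, 0)
    hist_pts <- rbind(hist_pts, kh)
    mri_pts <- rbind(mri_pts, km)
    R <- R * (1 - exp(-0.5 * ((xx - kh[1])^2 + (yy - kh[2])^2) / sig^2))
  }
  landmark_set(mri_pts, hist_pts, sigma_k = max(sigma_k, 1e-6))
}

#' Inject histology-style artefacts
#'
#' Draws dark crack line segments and elliptical holes into the image and
#' returns the mask of corrupted pixels. Used to exercise the
#' variance-based downweighting of corrupted regions.
#'
#' @param img an [image2d].
#' @param n_cracks number of crack segments.
#' @param crack_width_px crack width in pixels.
#' @param n_holes number of elliptical holes.
#' @param hole_radius_px mean hole radius in pixels.
#' @param value intensity written into artefact pixels.
#' @param seed integer seed.
#' @return A list with `image` (corrupted [image2d]) and `mask` (logical
#'   matrix of artefact pixels).
#' @export
add_artefacts <- function(img, n_cracks = 1, crack_width_px = 2,
                          n_holes = 0, hole_radius_px = 4, value = 0,
                          seed = 1) {
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  amask <- matrix(FALSE, H, W)
  if (n_cracks + n_holes > 0) {
    draws <- with_seed(seed, list(
      cr = matrix(runif(4 * max(n_cracks, 1)), ncol = 4),
      ho = matrix(runif(4 * max(n_holes, 1)), ncol = 4)))
    yy <- matrix(0:(H - 1), H, W)
    xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
    for (i in seq_len(n_cracks)) {
      # segment spanning the central region
      p0 <- c(0.15 + 0.7 * draws$cr[i, 1], 0.15 + 0.7 * draws$cr[i, 2]) *
        c(W - 1, H - 1)
      p1 <- c(0.15 + 0.7 * draws$cr[i, 3], 0.15 + 0.7 * draws$cr[i, 4]) *
        c(W - 1, H - 1)
      d <- p1 - p0
      len2 <- sum(d^2)
      t_ <- if (len2 > 0)
        pmin(pmax(((xx - p0[1]) * d[1] + (yy - p0[2]) * d[2]) / len2, 0), 1)
      else 0
      distseg <- sqrt((xx - p0[1] - t_ * d[1])^2 + (yy - p0[2] - t_ * d[2])^2)
      amask <- amask | (distseg <= crack_width_px / 2)
    }
    for (i in seq_len(n_holes)) {
      ctr <- c(0.2 + 0.6 * draws$ho[i, 1], 0.2 + 0.6 * draws$ho[i, 2]) *
        c(W - 1, H - 1)
      rx <- hole_radius_px * (0.6 + 0.8 * draws$ho[i, 3])
      ry <- hole_radius_px * (0.6 + 0.8 * draws$ho[i, 4])
      amask <- amask | (((xx - ctr[1]) / rx)^2 + ((yy - ctr[2]) / ry)^2 <= 1)
    }
  }
  px <- img$pixels
  px[amask] <- value
  list(image = image2d(px, img$spacing, mask = img$mask), mask = amask)
}

#' Write a synthetic pair to a directory
#'
#' Writes `imageA.png`, `imageB.png` (deformed), the ground-truth and
#' applied fields, `landmarks.csv` and a `spec.yaml` record including the
#' seed.
#'
#' @param pair a `synthetic_pair`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(pair$H, file.path(dir, "imageA.png"))
  write_image(pair$M, file.path(dir, "imageB.png"))
  write_field(pair$field_true, file.path(dir, "field_true.nii.gz"))
  write_field(pair$field_applied, file.path(dir, "field_applied.nii.gz"))
  write_landmarks(pair$landmarks, file.path(dir, "landmarks.csv"))
  yaml::write_yaml(c(unclass(pair$spec),
                     list(sigma_v = pair$sigma_v, seed = pair$seed)),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}
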