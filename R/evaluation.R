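# ---------------------------------------------------------------------------
# Error metrics (field-based and landmark-based) and experiment sweeps.
# ---------------------------------------------------------------------------

error_report <- function(err) {
  if (length(err) == 0) stop("no points to evaluate")
  structure(list(mean_error_mm = mean(err), median_error_mm = median(err),
                 max_error_mm = max(err), n = length(err)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> mean %.3f, median %.3f, max %.3f mm (n = %d)\n",
              x$mean_error_mm, x$median_error_mm, x$max_error_mm, x$n))
  invisible(x)
}

#' Field-based registration error
#'
#' Per-pixel Euclidean distance (mm) between an estimated and the true
#' displacement field, summarised as mean / median / max over the
#' evaluation mask. The mean reflects precision; the max reflects
#' robustness.
#'
#' @param U_est,U_true [deformation_field]s on the same domain.
#' @param mask optional logical matrix of pixels to evaluate (default:
#'   all).
#' @return An `error_report`.
#' @export
field_error <- function(U_est, U_true, mask = NULL) {
  stopifnot(inherits(U_est, "deformation_field"),
            inherits(U_true, "deformation_field"))
  if (!identical(dim(U_est$dx), dim(U_true$dx)))
    stop("fields must share a domain")
  err <- sqrt((U_est$dx - U_true$dx)^2 + (U_est$dy - U_true$dy)^2)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty evaluation mask")
    err <- err[mask]
  }
  error_report(as.vector(err))
}

#' Landmark-based registration error
#'
#' For each pair, the residual \eqn{\|k^h - k + U(k^h)\|} in mm, with the
#' field looked up bilinearly at the histology landmark. Held-out
#' landmarks (not used in the registration) give a cross-validation
#' error.
#'
#' @param U_est a [deformation_field].
#' @param held_out a [landmark_set].
#' @return An `error_report`.
#' @export
landmark_error <- function(U_est, held_out) {
  stopifnot(inherits(U_est, "deformation_field"),
            inherits(held_out, "landmark_set"))
  if (length(held_out) == 0) stop("empty landmark set")
  sp <- U_est$spacing
  ux <- cpp_bilinear(U_est$dx, held_out$hist[, 1] / sp,
                     held_out$hist[, 2] / sp)$value
  uy <- cpp_bilinear(U_est$dy, held_out$hist[, 1] / sp,
                     held_out$hist[, 2] / sp)$value
  err <- sqrt((held_out$hist[, 1] - held_out$mri[, 1] + ux)^2 +
                (held_out$hist[, 2] - held_out$mri[, 2] + uy)^2)
  error_report(err)
}

#' Erode a logical mask
#'
#' Iterated 4-neighbour binary erosion; used to build the evaluation mask
#' (the phantom brain mask eroded by the label-set radius, avoiding
#' boundary extrapolation artefacts).
#'
#' @param mask logical matrix.
#' @param iterations number of single-pixel erosions.
#' @return Eroded logical matrix.
#' @export
erode_mask <- function(mask, iterations = 1) {
  m <- mask
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(iterations)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-H, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -W, drop = FALSE])
    m <- m & up & dn & lf & rt
  }
  m
}

#' Sweep registration experiments over simulation settings
#'
#' Runs the proposed joint pipeline and the MI baseline on fresh synthetic
#' pairs for every combination of deformation severity, control-point
#' spacing and landmark count, and collects field errors in a tidy table.
#'
#' @param spec a [phantom_spec].
#' @param sigma_v_list velocity noise levels (mm).
#' @param spacings control-point spacings (mm) for the proposed method.
#' @param landmark_counts numbers of landmarks.
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param config a [reg_config].
#' @param mi_spacing control-point spacing for the MI baseline (mm).
#' @return A data frame with one row per method x cell x rep.
#' @export
error_sweep <- function(spec, sigma_v_list = 10, spacings = 6,
                        landmark_counts = 0, n_reps = 1, seed = 1,
                        config = reg_config(), mi_spacing = NULL) {
  if (is.null(mi_spacing)) mi_spacing <- config$cp_spacing_mi
  out <- list()
  cell <- 0
  for (sv in sigma_v_list) for (nl in landmark_counts) for (rep in seq_len(n_reps)) {
    cell <- cell + 1
    pair_seed <- derive_seed(seed, cell)
    pair <- make_pair(spec, sigma_v = sv, seed = pair_seed,
                      n_landmarks = nl, sigma_k = config$sigma_k)
    emask <- erode_mask(pair$mask,
                        ceiling(config$label_radius / spec$spacing))
    for (cps in spacings) {
      fit <- register_pair(pair$M, pair$H, pair$landmarks, config,
                           seed = pair_seed, cp_spacing = cps)
      fe <- field_error(fit$field, pair$field_true, emask)
      out[[length(out) + 1L]] <- data.frame(
        method = "proposed", sigma_v = sv, cp_spacing = cps,
        n_landmarks = nl, rep = rep, seed = pair_seed,
        mean_error_mm = fe$mean_error_mm,
        median_error_mm = fe$median_error_mm,
        max_error_mm = fe$max_error_mm, n = fe$n)
    }
    mi <- register_mi(pair$M, pair$H, pair$landmarks, config,
                      cp_spacing = mi_spacing)
    fe <- field_error(mi$field, pair$field_true, emask)
    out[[length(out) + 1L]] <- data.frame(
      method = "mi", sigma_v = sv, cp_spacing = mi_spacing,
      n_landmarks = nl, rep = rep, seed = pair_seed,
      mean_error_mm = fe$mean_error_mm,
      median_error_mm = fe$median_error_mm,
      max_error_mm = fe$max_error_mm, n = fe$n)
  }
  do.call(rbind, out)
}
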