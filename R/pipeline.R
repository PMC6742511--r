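# ---------------------------------------------------------------------------
# End-to-end registration of one image pair: VEM, graph-cut minimisation
# of the discrete posterior, and B-spline refinement.
# ---------------------------------------------------------------------------

#' Register an MRI slice to a histology section (joint pipeline)
#'
#' Runs the full method on one pair: the variational EM loop estimates the
#' synthesis (regression forest) and the belief field over discrete
#' displacements; the discrete log-posterior is then minimised by
#' alpha-expansion graph cuts; finally the deformation is refined with
#' the cubic B-spline model at `cp_spacing`.
#'
#' @param M the MRI [image2d] (floating image, warped towards histology).
#' @param H the histology [image2d] (reference).
#' @param landmarks a [landmark_set] or `NULL`.
#' @param config a [reg_config].
#' @param seed master integer seed.
#' @param cp_spacing control-point spacing in mm for the refinement
#'   (default `config$cp_spacing`).
#' @param refine apply the B-spline refinement (default `TRUE`).
#' @return A list with `field` (final [deformation_field]), `vem` (the
#'   `vem_state`), `graphcut` (discrete solution), `refine` (B-spline
#'   result or `NULL`), `warped` (M warped by the final field) and
#'   `uncertainty` (expected displacement + entropy + predictive maps).
#' @export
register_pair <- function(M, H, landmarks = NULL, config = reg_config(),
                          seed = 1, cp_spacing = NULL, refine = TRUE) {
  stopifnot(inherits(M, "image2d"), inherits(H, "image2d"))
  if (!identical(dim(M$pixels), dim(H$pixels)))
    stop("images must be defined over the same domain")
  vem <- run_vem(list(list(M = M, H = H, landmarks = landmarks)),
                 config, seed = seed)
  maps <- vem$maps[[1]]
  energy <- build_energy(M, maps, landmarks, vem$labels, config,
                         warp = vem$pairs_cache[[1]]$warp_cache)
  gc_res <- minimize_graphcut(energy)
  ref <- NULL
  field <- gc_res$field
  if (refine) {
    ref <- refine_bspline(M, maps, landmarks, init_field = gc_res$field,
                          config = config, cp_spacing = cp_spacing)
    field <- ref$field
  }
  unc <- expected_displacement(vem$beliefs[[1]], vem$labels,
                               dim(M$pixels), M$spacing)
  list(field = field, vem = vem, graphcut = gc_res, refine = ref,
       warped = warp_image(M, field),
       uncertainty = list(expected = unc$field,
                          entropy = matrix(unc$entropy, nrow(M$pixels)),
                          maps = maps))
}
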