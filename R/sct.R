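#' Construct a synthetic CT in the CBCT frame
#'
#' Applies the dental-artifact HU override to the planning CT, warps the
#' overridden pCT through the registration DVF onto the CBCT grid
#' (trilinear), and outside the CBCT field of view copies the
#' (override-applied) pCT values unwarped — a hard switch at the FOV seam.
#' The FOV provenance of every voxel is attached as attribute `fov`.
#'
#' @param pct planning CT (`voxel_image`).
#' @param dvf `vector_field` on the CBCT grid (pull-back), as returned by
#'   [deformable_register()].
#' @param fov logical array on the CBCT grid, TRUE inside the field of view.
#' @param artifact_mask optional logical array on the pCT grid delineating
#'   streak artifacts.
#' @param override_hu HU value replacing artifact voxels before the transfer;
#'   must lie in the soft-tissue range \[-200, 200\].
#' @return `voxel_image` on the CBCT grid with attribute `fov`.
#' @export
build_sct <- function(pct, dvf, fov, artifact_mask = NULL, override_hu = 40) {
  if (!all(dim(fov) == dim(dvf$disp)[1:3]))
    stop("fov and DVF grids do not match")
  if (override_hu < -200 || override_hu > 200)
    stop("override_hu must lie in the soft-tissue range [-200, 200] HU")
  src <- pct
  if (!is.null(artifact_mask)) {
    if (!all(dim(artifact_mask) == dim(pct$values)))
      stop("artifact mask does not conform to the pCT grid")
    v <- pct$values
    v[artifact_mask] <- override_hu
    src <- voxel_image(v, pct$spacing, pct$origin, kind = "hu")
  }
  warped <- warp_image(src, dvf, "trilinear", fill = -1000)
  out <- warped$values
  if (!all(dim(src$values) == dim(out)) || !same_grid(src, dvf)) {
    # pCT fill outside the FOV requires resampling onto the CBCT grid
    pts <- grid_points(dvf)
    fillv <- array(sample_image(src, pts, "trilinear", fill = -1000), dim(out))
  } else {
    fillv <- src$values
  }
  out[!fov] <- fillv[!fov]
  sct <- voxel_image(out, dvf$spacing, dvf$origin, kind = "hu")
  attr(sct, "fov") <- fov
  sct
}

#' Deform a repeat CT into the CBCT frame (gold standard image)
#'
#' Registers the repeat CT to the CBCT and resamples it, yielding the
#' reference image with true HU values in the CBCT frame of reference
#' against which synthetic-CT dose calculations are validated.
#'
#' @param rct repeat CT (`voxel_image`).
#' @param cbct CBCT (`voxel_image`).
#' @param cfg `registration_config`.
#' @param fov optional CBCT field-of-view mask.
#' @return `voxel_image` on the CBCT grid; the DVF used is attached as
#'   attribute `dvf`.
#' @export
build_rct_def <- function(rct, cbct, cfg = registration_config(), fov = NULL) {
  dvf <- deformable_register(cbct, rct, cfg, fov = fov)
  out <- warp_image(rct, dvf, "trilinear", fill = -1000)
  attr(out, "dvf") <- dvf
  out
}

#' Propagate contours through a deformation field
#'
#' Warps every mask of a planning structure set into the frame of the DVF
#' (trilinear on the 0/1 indicator, re-thresholded at 0.5). These are the
#' "uncorrected" DIR-propagated contours; structures that come out empty are
#' kept but listed in the `empty_structures` attribute.
#'
#' @param structures `structure_set` on the planning grid.
#' @param dvf `vector_field` (pull-back) on the target grid.
#' @return `structure_set` on the target grid.
#' @export
propagate_contours <- function(structures, dvf) {
  warp_structures(structures, dvf)
}
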