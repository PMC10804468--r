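#' Hounsfield-unit to relative stopping power calibration curve
#'
#' Piecewise-linear interpolation between ordered (HU, RSP) anchor pairs,
#' clamped outside the anchor range. The water anchor (0 HU, RSP 1) is
#' mandatory.
#'
#' @param hu,rsp anchor vectors; `hu` strictly increasing, `rsp` >= 0.
#' @return An `rsp_curve`.
#' @export
rsp_curve <- function(hu, rsp) {
  if (length(hu) != length(rsp) || length(hu) < 2)
    stop("need at least two (HU, RSP) anchors")
  if (any(diff(hu) <= 0)) stop("HU anchors must be strictly increasing")
  if (any(rsp < 0)) stop("RSP must be >= 0")
  if (!any(hu == 0 & abs(rsp - 1) < 1e-9))
    stop("the water anchor (0 HU, RSP 1.0) is mandatory")
  structure(list(hu = as.numeric(hu), rsp = as.numeric(rsp)),
            class = "rsp_curve")
}

#' Default HU-to-RSP calibration
#'
#' A generic stoichiometric-style calibration adequate for the phantom's
#' tissue classes (air, lung-like, soft tissue, bone).
#' @return An `rsp_curve`.
#' @export
default_rsp_curve <- function() {
  rsp_curve(hu = c(-1000, -120, 0, 60, 1000, 3000),
            rsp = c(0.001, 0.92, 1.0, 1.04, 1.55, 2.60))
}

#' Read/write an RSP curve as YAML
#' @param curve `rsp_curve`; `path` file path.
#' @return `path` (write) or an `rsp_curve` (read).
#' @export
write_rsp_curve <- function(curve, path) {
  yaml::write_yaml(list(hu = curve$hu, rsp = curve$rsp), path)
  invisible(path)
}

#' @rdname write_rsp_curve
#' @param path file path.
#' @export
read_rsp_curve <- function(path) {
  y <- yaml::read_yaml(path)
  rsp_curve(unlist(y$hu), unlist(y$rsp))
}

#' Convert HU to relative stopping power
#' @param hu numeric vector/array of HU values.
#' @param curve `rsp_curve`.
#' @return RSP values with the shape of `hu`.
#' @export
hu_to_rsp <- function(hu, curve = default_rsp_curve()) {
  out <- stats::approx(curve$hu, curve$rsp, xout = as.vector(hu),
                       rule = 2)$y
  if (is.array(hu)) array(out, dim(hu)) else out
}

#' Water-equivalent thickness along a ray
#'
#' Accumulates `RSP(HU) * step` along the ray from `entry` in direction
#' `direction`, until the ray leaves the grid.
#'
#' @param ct `voxel_image` (HU).
#' @param entry world point (mm) inside the grid.
#' @param direction unit 3-vector.
#' @param curve `rsp_curve`.
#' @param step step length in mm; must not exceed half the smallest spacing.
#' @return `data.frame` with geometric distance `s` (mm) and cumulative
#'   `wet` (mm), monotone non-decreasing.
#' @export
wet_raytrace <- function(ct, entry, direction, curve = default_rsp_curve(),
                         step = min(ct$spacing) / 2) {
  if (step > min(ct$spacing) / 2 + 1e-9)
    stop("step must be <= half the smallest voxel spacing")
  direction <- direction / sqrt(sum(direction^2))
  idx0 <- world_to_index(ct, matrix(entry, 1))
  d <- dim(ct$values)
  if (any(idx0 < 1) || any(idx0 > d))
    stop("entry point lies outside the image grid")
  lo <- ct$origin - ct$spacing / 2
  hi <- ct$origin + (d - 0.5) * ct$spacing
  # max path length until any axis exits
  smax <- sqrt(sum((hi - lo)^2))
  s <- seq(0, smax, by = step)
  pts <- cbind(entry[1] + s * direction[1],
               entry[2] + s * direction[2],
               entry[3] + s * direction[3])
  inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
            pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
            pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  keep <- seq_len(match(FALSE, inside, nomatch = length(s) + 1) - 1)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  rsp <- hu_to_rsp(sample_image(ct, pts, fill = -1000), curve)
  wet <- (cumsum(rsp) - rsp / 2) * step
  data.frame(s = s, wet = wet)
}

#' Analytic Bragg depth-dose curve
#'
#' Documented parameterization: a slowly rising entrance plateau joined to a
#' Gaussian peak. Writing `sigma_d = max(0.012 R, 0.8)` mm for the distal
#' falloff width and `R_p = R - 0.668 sigma_d` for the peak depth (so that
#' the distal 80% level sits at the nominal range `R`), the curve is
#' `p0 + (1 - p0) exp(-(d - R_p)^2 / (2 (0.12 R_p)^2))` proximally and
#' `exp(-(d - R_p)^2 / (2 sigma_d^2))` distally, zero beyond
#' `R_p + 6 sigma_d`. Continuous, single maximum at `R_p`, distal falloff
#' below 1% of the peak within 5 `sigma_d` of `R`.
#'
#' @param wet_depth water-equivalent depth(s), mm.
#' @param R nominal range (depth of the distal 80% point), mm water; > 0.
#' @param entrance plateau-to-peak ratio at zero depth.
#' @return dose per unit fluence (peak normalized to 1).
#' @export
bragg_depth_dose <- function(wet_depth, R, entrance = 0.3) {
  if (R <= 0) stop("R must be > 0")
  sigma_d <- max(0.012 * R, 0.8)
  rp <- R - 0.668 * sigma_d
  sigma_p <- 0.12 * rp
  out <- numeric(length(wet_depth))
  prox <- wet_depth <= rp
  out[prox] <- entrance + (1 - entrance) *
    exp(-(wet_depth[prox] - rp)^2 / (2 * sigma_p^2))
  dist <- !prox & wet_depth <= rp + 6 * sigma_d
  out[dist] <- exp(-(wet_depth[dist] - rp)^2 / (2 * sigma_d^2))
  out[wet_depth < 0] <- 0
  if (is.array(wet_depth)) array(out, dim(wet_depth)) else out
}

#' Define a lateral spot-scanning proton beam
#'
#' The analytic engine supports coplanar beams along the cardinal lateral
#' axes (entering from the patient's left/right or anterior/posterior).
#'
#' @param axis 1 (x) or 2 (y): the beam travels along this world axis.
#' @param sign +1 (entering from the low-coordinate side) or -1.
#' @param lateral_spacing spot grid spacing in the plane orthogonal to the
#'   beam (mm).
#' @param layer_spacing energy-layer spacing in WET (mm).
#' @return A `beam` object.
#' @export
beam <- function(axis = 1, sign = 1, lateral_spacing = 7, layer_spacing = 7) {
  if (!axis %in% 1:2) stop("beam axis must be 1 (x) or 2 (y)")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (lateral_spacing <= 0 || layer_spacing <= 0)
    stop("spacings must be > 0")
  structure(list(axis = as.integer(axis), sign = as.integer(sign),
                 lateral_spacing = lateral_spacing,
                 layer_spacing = layer_spacing),
            class = "beam")
}

#' Default beam arrangement: two lateral opposed fields
#' @param lateral_spacing,layer_spacing see [beam()].
#' @return list of two `beam`s along +x and -x.
#' @export
default_beams <- function(lateral_spacing = 7, layer_spacing = 7) {
  list(beam(1, +1, lateral_spacing, layer_spacing),
       beam(1, -1, lateral_spacing, layer_spacing))
}

# WET map (mm) of a CT for a beam: cumulative RSP*dx along the beam axis
# from the entry side, midpoint-corrected. `rsp` is the RSP array.
wet_map <- function(rsp, spacing, bm) {
  ax <- bm$axis
  perm <- c(ax, setdiff(1:3, ax))
  P <- aperm(rsp, perm)
  dp <- dim(P)
  M <- matrix(P, dp[1])
  if (bm$sign < 0) M <- M[dp[1]:1, , drop = FALSE]
  W <- (apply(M, 2, cumsum) - M / 2) * spacing[ax]
  if (bm$sign < 0) W <- W[dp[1]:1, , drop = FALSE]
  aperm(array(W, dp), order(perm))
}

#' Place proton spots covering the field-specific target
#'
#' The field-specific target is the union of all CTVs expanded isotropically
#' by the setup margin; each lateral spot position receives energy layers
#' spanning the target's WET extent along its ray, expanded proximally and
#' distally by the fractional range margin. Spots whose ray crosses the
#' entry-avoidance mask before reaching the target are removed.
#'
#' @param structures `structure_set` whose prescribed CTVs define the target.
#' @param bm `beam`.
#' @param ct `voxel_image` (HU) used for WET computation.
#' @param curve `rsp_curve`.
#' @param setup_margin isotropic expansion (mm), default 3.
#' @param range_margin fractional WET expansion, default 0.03.
#' @param avoidance optional logical array: rays crossing it before the
#'   target are excluded (e.g. chin/teeth region).
#' @param edge_mm extra lateral acceptance beyond the target projection so
#'   a penumbra-covering ring of border spots is retained (default one
#'   nominal spot sigma).
#' @return list with `spots` (data.frame: `ly`, `lz`, `R`, `beam`) and
#'   `target` (the field-specific target mask).
#' @export
place_spots <- function(structures, bm, ct, curve = default_rsp_curve(),
                        setup_margin = 3, range_margin = 0.03,
                        avoidance = NULL, edge_mm = 3) {
  ctvs <- intersect(structures$prescriptions$structure, names(structures$masks))
  if (length(ctvs) == 0) stop("no prescribed CTVs in the structure set")
  target <- Reduce(`|`, structures$masks[ctvs])
  if (!any(target)) stop("union of CTVs is empty")
  fst <- dilate_mask(target, setup_margin, structures$spacing)

  ax <- bm$axis
  lat_axes <- setdiff(1:3, ax)
  axc <- axis_coords(ct)
  W <- wet_map(hu_to_rsp(ct$values, curve), ct$spacing, bm)

  # occupied lateral cells of the field-specific target
  proj <- apply(fst, lat_axes, any)
  l1 <- axc[[lat_axes[1]]]; l2 <- axc[[lat_axes[2]]]
  occ <- which(proj, arr.ind = TRUE)
  ls <- bm$lateral_spacing
  g1 <- seq(min(l1[occ[, 1]]) - edge_mm, max(l1[occ[, 1]]) + edge_mm, by = ls)
  g2 <- seq(min(l2[occ[, 2]]) - edge_mm, max(l2[occ[, 2]]) + edge_mm, by = ls)

  spots <- list()
  n_removed <- 0L
  for (p1 in g1) for (p2 in g2) {
    j <- which.min(abs(l1 - p1)); k <- which.min(abs(l2 - p2))
    # lateral cells within half a spot spacing (plus the penumbra
    # allowance) of (p1, p2)
    jw <- which(abs(l1 - p1) <= ls / 2 + edge_mm + 1e-9)
    kw <- which(abs(l2 - p2) <= ls / 2 + edge_mm + 1e-9)
    if (!any(proj[jw, kw])) next
    col_idx <- function(arr) {
      if (ax == 1) arr[, j, k] else arr[j, , k]
    }
    win_idx <- function(arr) {          # neighbourhood columns of the spot
      if (ax == 1) arr[, jw, kw, drop = FALSE] else arr[jw, , kw, drop = FALSE]
    }
    fst_win <- win_idx(fst)
    if (!any(fst_win)) next
    if (!is.null(avoidance)) {
      tvox <- which(apply(fst_win, if (ax == 1) 1 else 2, any))
      avox <- which(col_idx(avoidance))
      if (length(avox) > 0) {
        first_t <- if (bm$sign > 0) min(tvox) else max(tvox)
        blocked <- if (bm$sign > 0) any(avox < first_t) else any(avox > first_t)
        if (blocked) { n_removed <- n_removed + 1L; next }
      }
    }
    wv <- win_idx(W)[fst_win]
    wlo <- min(wv) * (1 - range_margin)
    whi <- max(wv) * (1 + range_margin)
    layers <- seq(wlo, whi, by = bm$layer_spacing)
    if (layers[length(layers)] < whi) layers <- c(layers, whi)
    spots[[length(spots) + 1L]] <- data.frame(ly = p1, lz = p2, R = layers)
  }
  if (length(spots) == 0)
    stop(sprintf(
      "no spots retained for this field (%d lateral positions blocked by the avoidance region)",
      n_removed))
  sp <- do.call(rbind, spots)
  sp$beam <- NA_integer_  # assigned by the caller when pooling fields
  list(spots = sp, target = fst)
}

#' Place spots for every beam of an arrangement
#' @param structures,ct,curve,setup_margin,range_margin,avoidance,edge_mm
#'   see [place_spots()].
#' @param beams list of `beam`s.
#' @return list with pooled `spots` (with `beam` column) and `target` mask.
#' @export
place_spots_all <- function(structures, beams, ct,
                            curve = default_rsp_curve(),
                            setup_margin = 3, range_margin = 0.03,
                            avoidance = NULL, edge_mm = 3) {
  parts <- lapply(seq_along(beams), function(b) {
    ps <- place_spots(structures, beams[[b]], ct, curve,
                      setup_margin, range_margin, avoidance, edge_mm)
    ps$spots$beam <- b
    ps
  })
  list(spots = do.call(rbind, lapply(parts, `[[`, "spots")),
       target = parts[[1]]$target)
}

#' Compute a sparse influence matrix for one uncertainty scenario
#'
#' For each spot, deposits `RBE * braggDepthDose(WET, R * scale) *
#' Gauss(lateral)` over the voxels of `region`, after shifting the patient
#' by the scenario's setup shift. Entries below `cutoff` times the per-spot
#' maximum are dropped. Total dose is `influence %*% weights` (linear in the
#' spot weights).
#'
#' @param ct `voxel_image` (HU).
#' @param beams list of `beam`s.
#' @param spots data.frame from [place_spots()] with a `beam` column
#'   indexing into `beams`.
#' @param region logical array: voxels for which influence is stored.
#' @param curve `rsp_curve`.
#' @param scenario list with `shift` (mm 3-vector, patient shift) and
#'   `scale` (range scale, e.g. 1.03); default nominal.
#' @param rbe relative biological effectiveness factor (doses are
#'   RBE-weighted).
#' @param sigma0,sigma_slope lateral Gaussian width: `sigma0 + slope * WET`.
#' @param cutoff sparsity cutoff as a fraction of the per-spot maximum.
#' @return `dgCMatrix` (voxels-in-region x spots), with the region voxel
#'   indices as attribute `region_idx`.
#' @export
compute_influence <- function(ct, beams, spots, region,
                              curve = default_rsp_curve(),
                              scenario = list(shift = c(0, 0, 0), scale = 1),
                              rbe = 1.1, sigma0 = 3, sigma_slope = 0.03,
                              cutoff = 1e-4) {
  d <- dim(ct$values)
  ridx <- which(region)
  nreg <- length(ridx)
  shift <- scenario$shift
  scale <- scenario$scale
  rsp <- hu_to_rsp(ct$values, curve)

  # patient shifted by `shift` in the lab frame: the lab-frame CT becomes
  # CT(p - shift), and voxel v sits at lab point x_v + shift, so the dose it
  # receives moves by -shift in the patient frame
  if (any(shift != 0)) {
    pts <- sweep(grid_points(ct), 2, shift, "-")
    rsp_t <- array(interp3(rsp, world_to_index(ct, pts), fill = hu_to_rsp(-1000, curve)), d)
  } else {
    rsp_t <- rsp
  }

  axc <- axis_coords(ct)
  co <- list(
    x = rep(axc[[1]], times = d[2] * d[3]),
    y = rep(rep(axc[[2]], each = d[1]), times = d[3]),
    z = rep(axc[[3]], each = d[1] * d[2]))

  ii <- list(); jj <- list(); xx <- list()
  for (b in seq_along(beams)) {
    bm <- beams[[b]]
    sp <- spots[spots$beam == b, , drop = FALSE]
    if (nrow(sp) == 0) next
    Wt <- wet_map(rsp_t, ct$spacing, bm)
    if (any(shift != 0)) {
      # lab-frame WET sampled at the shifted voxel positions x_v + shift
      ptsb <- sweep(grid_points(ct), 2, shift, "+")
      wet_v <- interp3(Wt, world_to_index(ct, ptsb), fill = NULL)[ridx]
    } else {
      wet_v <- as.vector(Wt)[ridx]
    }
    lat_axes <- setdiff(1:3, bm$axis)
    L1 <- co[[lat_axes[1]]][ridx] + shift[lat_axes[1]]
    L2 <- co[[lat_axes[2]]][ridx] + shift[lat_axes[2]]
    sigma <- sigma0 + sigma_slope * pmax(wet_v, 0)
    rcut2 <- (3.5 * sigma)^2
    for (s in seq_len(nrow(sp))) {
      dy <- L1 - sp$ly[s]; dz <- L2 - sp$lz[s]
      r2 <- dy * dy + dz * dz
      Rs <- sp$R[s] * scale
      sel <- which(r2 <= rcut2 & wet_v <= Rs + 0.1 * Rs + 10)
      if (length(sel) == 0) next
      dd <- bragg_depth_dose(wet_v[sel], Rs) *
        exp(-r2[sel] / (2 * sigma[sel]^2))
      keep <- dd > cutoff * max(dd)
      sel <- sel[keep]; dd <- dd[keep]
      if (length(sel) == 0) next
      srow <- which(spots$beam == b)[s]
      ii[[length(ii) + 1L]] <- sel
      jj[[length(jj) + 1L]] <- rep.int(srow, length(sel))
      xx[[length(xx) + 1L]] <- rbe * dd
    }
  }
  infl <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx),
                               dims = c(nreg, nrow(spots)))
  attr(infl, "region_idx") <- ridx
  infl
}

#' Write/read an influence matrix as a coordinate triplet list
#'
#' Plain-text on-disk format: a CSV with one row per nonzero entry
#' (`voxel` = linear grid index, `spot`, `dose_per_mu`), preceded by a
#' `#`-comment header recording the grid dims and matrix shape.
#'
#' @param infl sparse influence matrix from [compute_influence()].
#' @param path output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_influence_matrix <- function(infl, path) {
  tri <- Matrix::summary(infl)
  ridx <- attr(infl, "region_idx")
  con <- file(path, "w")
  writeLines(sprintf("# influence matrix: %d region voxels x %d spots",
                     nrow(infl), ncol(infl)), con)
  writeLines(paste0("# region_idx: ", paste(ridx, collapse = " ")), con)
  utils::write.csv(data.frame(voxel = ridx[tri$i], spot = tri$j,
                              dose_per_mu = tri$x),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_influence_matrix
#' @export
read_influence_matrix <- function(path) {
  hdr <- readLines(path, n = 2)
  ridx <- as.integer(strsplit(sub("^# region_idx: ", "", hdr[2]), " ")[[1]])
  shape <- as.integer(regmatches(hdr[1], gregexpr("[0-9]+", hdr[1]))[[1]])
  tri <- utils::read.csv(path, comment.char = "#")
  infl <- Matrix::sparseMatrix(i = match(tri$voxel, ridx), j = tri$spot,
                               x = tri$dose_per_mu,
                               dims = c(shape[1], shape[2]))
  attr(infl, "region_idx") <- ridx
  infl
}

#' Assemble a full-grid dose image from an influence matrix and weights
#' @param infl sparse influence matrix from [compute_influence()].
#' @param weights spot weights (>= 0).
#' @param dims grid dims; `spacing`, `origin` grid geometry.
#' @return `voxel_image` (Gy).
#' @export
dose_from_influence <- function(infl, weights, dims, spacing, origin) {
  v <- array(0, dims)
  v[attr(infl, "region_idx")] <- as.numeric(infl %*% weights)
  voxel_image(v, spacing, origin, kind = "dose")
}
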