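#' Specification of a digital head-and-neck phantom
#'
#' Defines a cylindrical neck phantom with parameterized ellipsoidal organs,
#' a weekly anatomy trajectory (body-contour shrinkage from weight loss and
#' tumour growth/shrinkage), a CBCT degradation model, and a dental-artifact
#' region. Axes: x = right-left (lateral), y = anterior(-)/posterior(+),
#' z = inferior(-)/superior(+).
#'
#' @param spacing voxel spacing in mm (default 2 mm isotropic, matching the
#'   dose-grid resolution used for planning).
#' @param dims grid size in voxels.
#' @param body_radii in-plane semi-axes (x, y) of the elliptical body (mm).
#' @param tumor_center,tumor_radius centre (mm) and radius (mm) of the gross
#'   tumour sphere that becomes CTV_primary.
#' @param ctv_margins mm expansions primary->secondary and secondary->tertiary.
#' @param prescriptions_gy,fractions dose levels (Gy) for the up-to-three CTV
#'   levels and the shared fraction count.
#' @param weekly_body_shrink fractional body-radius loss per week, in
#'   (-0.5, 0.5); positive values shrink the external contour.
#' @param weekly_tumor_change fractional tumour-radius change per week, in
#'   (-0.5, 0.5); positive values grow the tumour.
#' @param fov_fraction axial fraction of the grid covered by the CBCT
#'   field of view, in (0, 1].
#' @param cbct_bias_hu amplitude of the radial low-frequency (cupping) bias
#'   field added to the CBCT (HU).
#' @param cbct_noise_hu standard deviation of the Gaussian HU noise added to
#'   the CBCT.
#' @param artifact logical: paint a high-HU dental-artifact region near the
#'   teeth on the planning CT (with its delineation mask).
#' @param tertiary_inferior_extension logical: extend CTV_tertiary inferiorly
#'   toward the bottom of the grid so that part of it falls outside a reduced
#'   CBCT field of view.
#' @param seed integer random seed; all phantom outputs are bit-reproducible
#'   for a fixed seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(spacing = c(2, 2, 2),
                         dims = c(96, 96, 64),
                         body_radii = c(70, 80),
                         tumor_center = c(-25, 10, -5),
                         tumor_radius = 14,
                         ctv_margins = c(5, 5),
                         prescriptions_gy = c(70, 63, 56),
                         fractions = 35,
                         weekly_body_shrink = 0,
                         weekly_tumor_change = 0,
                         fov_fraction = 0.8,
                         cbct_bias_hu = 30,
                         cbct_noise_hu = 15,
                         artifact = TRUE,
                         tertiary_inferior_extension = FALSE,
                         seed = 1L) {
  spec <- list(spacing = as.numeric(spacing), dims = as.integer(dims),
               body_radii = as.numeric(body_radii),
               tumor_center = as.numeric(tumor_center),
               tumor_radius = as.numeric(tumor_radius),
               ctv_margins = as.numeric(ctv_margins),
               prescriptions_gy = as.numeric(prescriptions_gy),
               fractions = as.integer(fractions),
               weekly_body_shrink = weekly_body_shrink,
               weekly_tumor_change = weekly_tumor_change,
               fov_fraction = fov_fraction,
               cbct_bias_hu = cbct_bias_hu,
               cbct_noise_hu = cbct_noise_hu,
               artifact = isTRUE(artifact),
               tertiary_inferior_extension = isTRUE(tertiary_inferior_extension),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$spacing <= 0) || any(spec$dims < 8))
    stop("spacing must be positive and dims at least 8 voxels")
  extent <- spec$dims * spec$spacing
  if (2 * spec$body_radii[1] > extent[1] || 2 * spec$body_radii[2] > extent[2])
    stop(sprintf(paste("body ellipse (%g x %g mm) exceeds the grid extent",
                       "(%g x %g mm): enlarge the grid or shrink the body"),
                 2 * spec$body_radii[1], 2 * spec$body_radii[2],
                 extent[1], extent[2]))
  if (spec$tumor_radius <= 0)
    stop("tumor_radius must be > 0: an empty CTV_primary is not a valid phantom")
  e <- sqrt((spec$tumor_center[1] / spec$body_radii[1])^2 +
            (spec$tumor_center[2] / spec$body_radii[2])^2)
  if (e > 0.85 || abs(spec$tumor_center[3]) + spec$tumor_radius > extent[3] / 2)
    stop("tumour geometry exceeds the body/grid: move or shrink the tumour")
  if (abs(spec$weekly_body_shrink) >= 0.5 || abs(spec$weekly_tumor_change) >= 0.5)
    stop("weekly change fractions must lie in (-0.5, 0.5)")
  if (spec$fov_fraction <= 0 || spec$fov_fraction > 1)
    stop("fov_fraction must lie in (0, 1]")
  if (length(spec$prescriptions_gy) < 1 || length(spec$prescriptions_gy) > 3)
    stop("between 1 and 3 prescription levels are supported")
  if (any(spec$prescriptions_gy < 56) || any(spec$prescriptions_gy > 70) ||
      spec$fractions < 30 || spec$fractions > 35)
    stop("default prescriptions must lie within 56-70 Gy in 30-35 fractions")
  invisible(spec)
}

#' Write/read a phantom spec as YAML
#' @param spec `phantom_spec`.
#' @param path file path.
#' @return `path` (write) or a `phantom_spec` (read).
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

# coordinate arrays (mm) for a spec grid, centred on the world origin
phantom_coords <- function(spec) {
  origin <- -(spec$dims - 1) / 2 * spec$spacing
  ax <- lapply(1:3, function(k)
    origin[k] + (seq_len(spec$dims[k]) - 1) * spec$spacing[k])
  d <- spec$dims
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), d),
       origin = origin, axes = ax)
}

ellipsoid_mask <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 + ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

cylinder_mask <- function(co, center_xy, radius, z_range = NULL) {
  m <- (co$x - center_xy[1])^2 + (co$y - center_xy[2])^2 <= radius^2
  if (!is.null(z_range)) m <- m & co$z >= z_range[1] & co$z <= z_range[2]
  m
}

# tissue-class HU values used throughout the phantom
.hu <- list(air = -1000, soft = 40, tumor = 50, parotid = 35, oral = 20,
            spine = 800, mandible = 1200, cord = 40, artifact = 2800,
            larynx = 40, esophagus = 35)

#' Build the planning CT and structure set of a phantom
#'
#' Deterministic for a fixed spec: constructs the elliptical body against
#' air, spine and mandible bone, an internal airway, soft-tissue OARs
#' (spinal cord, larynx, constrictors, parotids, oral cavity, esophagus),
#' nested CTVs around the tumour sphere, and (optionally) a high-HU dental
#' artifact region with its delineation mask plus an anterior chin/teeth
#' beam-avoidance mask.
#'
#' @param spec `phantom_spec`.
#' @return list with elements `ct` (`voxel_image`, HU) and `structures`
#'   (`structure_set` with prescriptions attached).
#' @export
build_planning_phantom <- function(spec) {
  validate_phantom_spec(spec)
  co <- phantom_coords(spec)
  a <- spec$body_radii[1]; b <- spec$body_radii[2]
  zext <- spec$dims[3] * spec$spacing[3]

  body <- (co$x / a)^2 + (co$y / b)^2 <= 1
  spine    <- cylinder_mask(co, c(0, 45), 11) & body
  cord     <- cylinder_mask(co, c(0, 45), 4.5) & body
  airway   <- cylinder_mask(co, c(0, 18), 6) & body
  larynx   <- cylinder_mask(co, c(0, 18), 12, c(-45, -10)) & body & !airway
  constr   <- cylinder_mask(co, c(0, 18), 11, c(-45, 20)) &
              !cylinder_mask(co, c(0, 18), 6.5) & co$y >= 20 & body
  esoph    <- cylinder_mask(co, c(0, 30), 5, c(-zext / 2, -45)) & body
  par_ips  <- ellipsoid_mask(co, c(-48, 8, 28), c(10, 13, 16)) & body
  par_con  <- ellipsoid_mask(co, c(48, 8, 28), c(10, 13, 16)) & body
  oral     <- ellipsoid_mask(co, c(0, -28, 18), c(16, 13, 11)) & body
  mand_r   <- sqrt(co$x^2 + (co$y + 18)^2)
  mandible <- mand_r >= 24 & mand_r <= 32 & co$y <= -18 &
              co$z >= 8 & co$z <= 28 & body

  tum_d2 <- (co$x - spec$tumor_center[1])^2 + (co$y - spec$tumor_center[2])^2 +
            (co$z - spec$tumor_center[3])^2
  ctv1 <- tum_d2 <= spec$tumor_radius^2 & body
  if (!any(ctv1))
    stop("CTV_primary is empty on this grid: tumour too small for the spacing")
  ctv2 <- dilate_mask(ctv1, spec$ctv_margins[1], spec$spacing) & body
  ctv3 <- dilate_mask(ctv2, spec$ctv_margins[2], spec$spacing) & body
  if (spec$tertiary_inferior_extension) {
    stub <- cylinder_mask(co, spec$tumor_center[1:2], 10,
                          c(-zext / 2, spec$tumor_center[3])) & body
    ctv3 <- ctv3 | stub
  }

  ct <- array(.hu$air, spec$dims)
  ct[body]     <- .hu$soft
  ct[oral]     <- .hu$oral
  ct[par_ips]  <- .hu$parotid
  ct[par_con]  <- .hu$parotid
  ct[larynx]   <- .hu$larynx
  ct[esoph]    <- .hu$esophagus
  ct[spine]    <- .hu$spine
  ct[mandible] <- .hu$mandible
  ct[cord]     <- .hu$cord
  ct[airway]   <- .hu$air
  ct[ctv1]     <- .hu$tumor

  masks <- list(body = body, CTV_primary = ctv1)
  rx <- data.frame(structure = "CTV_primary",
                   dose_gy = spec$prescriptions_gy[1],
                   fractions = spec$fractions)
  if (length(spec$prescriptions_gy) >= 2) {
    masks$CTV_secondary <- ctv2
    rx <- rbind(rx, data.frame(structure = "CTV_secondary",
                               dose_gy = spec$prescriptions_gy[2],
                               fractions = spec$fractions))
  }
  if (length(spec$prescriptions_gy) >= 3) {
    masks$CTV_tertiary <- ctv3
    rx <- rbind(rx, data.frame(structure = "CTV_tertiary",
                               dose_gy = spec$prescriptions_gy[3],
                               fractions = spec$fractions))
  }
  masks <- c(masks, list(spinal_cord = cord, larynx = larynx,
                         constrictors = constr, parotid_ips = par_ips,
                         parotid_con = par_con, oral_cavity = oral,
                         mandible = mandible, esophagus = esoph))

  avoid <- co$y <= -46 & body
  masks$chin_avoidance <- avoid
  if (spec$artifact) {
    artifact <- co$x >= -10 & co$x <= 10 & co$y >= -50 & co$y <= -34 &
                co$z >= 10 & co$z <= 26 & body
    ct[artifact] <- .hu$artifact
    masks$artifact <- artifact
  }

  list(ct = voxel_image(ct, spec$spacing, co$origin, kind = "hu"),
       structures = structure_set(masks, spec$spacing, co$origin,
                                  prescriptions = rx))
}

# Analytic pull-back displacement (mm) of the week-`week` anatomy, evaluated
# at fixed-frame points (x, y, z): global in-plane scaling about the body
# axis models weight loss; a Gaussian radial bump at the tumour models
# growth/shrinkage. Returns a list of the three components.
weekly_displacement <- function(spec, week, x, y, z) {
  lambda <- (1 - spec$weekly_body_shrink)^week
  k <- 1 - (1 + spec$weekly_tumor_change)^(-week)
  ux <- (1 / lambda - 1) * x
  uy <- (1 / lambda - 1) * y
  uz <- 0 * z
  if (k != 0) {
    tc <- spec$tumor_center
    tw <- c(lambda * tc[1], lambda * tc[2], tc[3])  # tumour centre, week frame
    sigma <- 1.6 * spec$tumor_radius
    g <- exp(-((x - tw[1])^2 + (y - tw[2])^2 + (z - tw[3])^2) / (2 * sigma^2))
    ux <- ux - k * (x - tw[1]) * g
    uy <- uy - k * (y - tw[2]) * g
    uz <- uz - k * (z - tw[3]) * g
  }
  list(ux = ux, uy = uy, uz = uz, lambda = lambda, k = k)
}

#' Ground-truth weekly anatomy: deformation, deformed CT and contours
#'
#' The weekly deformation is an analytic smooth pull-back field (in-plane
#' body contraction plus a local tumour dilation) with week-proportional
#' magnitude; the deformed CT and ground-truth ("physician-corrected")
#' contours are the planning CT and structures resampled through it. Week 0
#' returns the identity field and the planning data unchanged.
#'
#' @param spec `phantom_spec`.
#' @param week non-negative integer week index.
#' @param planning optional precomputed result of [build_planning_phantom()]
#'   for this spec (avoids rebuilding).
#' @return list with `dvf` (`vector_field`, pull-back, on the weekly grid),
#'   `ct` (`voxel_image`) and `structures` (`structure_set`).
#' @export
sample_weekly_anatomy <- function(spec, week, planning = NULL) {
  if (week < 0) stop("week must be >= 0")
  if (is.null(planning)) planning <- build_planning_phantom(spec)
  if (week == 0) {
    return(list(dvf = zero_field(planning$ct), ct = planning$ct,
                structures = planning$structures))
  }
  co <- phantom_coords(spec)
  u <- weekly_displacement(spec, week, co$x, co$y, co$z)
  if (abs(u$k) >= 0.6 || abs(1 / u$lambda - 1) >= 0.5)
    stop("weekly deformation exceeds the invertibility bound; reduce the trajectory amplitude or week index")
  disp <- array(c(u$ux, u$uy, u$uz), c(spec$dims, 3L))
  dvf <- vector_field(disp, spec$spacing, co$origin)
  ct <- warp_image(planning$ct, dvf, "trilinear", fill = -1000)
  structures <- warp_structures(planning$structures, dvf)
  list(dvf = dvf, ct = ct, structures = structures)
}

#' Simulate a CBCT rendition of a (deformed) CT
#'
#' Adds a radial low-frequency cupping bias field and seeded Gaussian HU
#' noise, and crops axially to the CBCT field of view; voxels outside the
#' FOV are set to air and flagged invalid via the returned mask.
#'
#' @param ct `voxel_image` (typically the deformed CT of a week).
#' @param spec `phantom_spec` supplying the CBCT model and the seed.
#' @param week week index, mixed into the noise seed so weekly CBCTs get
#'   independent (but reproducible) noise.
#' @return list with `cbct` (`voxel_image`) and `fov` (logical array, TRUE
#'   inside the field of view).
#' @export
simulate_cbct <- function(ct, spec, week = 0L) {
  co <- phantom_coords(spec)
  d <- spec$dims
  zext <- d[3] * spec$spacing[3]
  fov_half <- spec$fov_fraction * zext / 2
  fov <- array(abs(co$z) <= fov_half, d)

  vals <- ct$values
  if (spec$cbct_bias_hu != 0) {
    e2 <- pmin((co$x / spec$body_radii[1])^2 + (co$y / spec$body_radii[2])^2, 1)
    vals <- vals + spec$cbct_bias_hu * (2 * e2 - 1)
  }
  if (spec$cbct_noise_hu > 0) {
    seed <- (spec$seed + 7919L * (as.integer(week) + 1L)) %% .Machine$integer.max
    vals <- vals + withr::with_seed(seed,
      array(stats::rnorm(prod(d), sd = spec$cbct_noise_hu), d))
  }
  vals[!fov] <- -1000
  vals <- pmin(pmax(vals, -1024), 3071)
  list(cbct = voxel_image(vals, spec$spacing, co$origin, kind = "hu"),
       fov = fov)
}
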