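#' Regular 3D scalar voxel grid
#'
#' The common currency of the package: planning CTs, CBCTs, synthetic CTs and
#' dose distributions are all `voxel_image` objects — a 3D numeric array with
#' origin and spacing metadata (mm). Values are HU for CT-like images and Gy
#' for dose.
#'
#' @param values 3D numeric array.
#' @param spacing length-3 numeric, voxel spacing in mm (> 0).
#' @param origin length-3 numeric, world coordinate (mm) of the centre of
#'   voxel (1,1,1). Defaults to centring the grid on the world origin.
#' @param kind one of "hu" or "dose"; HU images are range-checked to
#'   \[-1024, 3071\] and dose images to non-negative values.
#' @return A `voxel_image` object.
#' @export
voxel_image <- function(values, spacing = c(1, 1, 1), origin = NULL,
                        kind = c("hu", "dose")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  dims <- dim(values)
  if (any(dims < 1L)) stop("all dimensions must be >= 1")
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (kind == "hu") {
    rng <- range(values, finite = TRUE)
    if (rng[1] < -1024 || rng[2] > 3071)
      stop("HU values must lie within [-1024, 3071]")
  } else if (any(values < 0, na.rm = TRUE)) {
    stop("dose values must be non-negative")
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 kind = kind),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image [%s]> dims %s, spacing %s mm, origin %s mm\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$values)

#' Check that two gridded objects share geometry
#' @param a,b `voxel_image`, `vector_field` or `structure_set` objects.
#' @param tol tolerance on spacing/origin comparison (mm).
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  da <- grid_dims(a); db <- grid_dims(b)
  all(da == db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

grid_dims <- function(x) {
  if (inherits(x, "vector_field")) dim(x$disp)[1:3]
  else if (inherits(x, "structure_set")) x$dims
  else dim(x$values)
}

#' World coordinates of the voxel centres along each axis
#' @param img object with `origin`/`spacing` and known dims.
#' @return list of three numeric vectors (mm).
#' @export
axis_coords <- function(img) {
  d <- grid_dims(img)
  lapply(1:3, function(k) img$origin[k] + (seq_len(d[k]) - 1) * img$spacing[k])
}

#' Per-voxel 3D displacement field
#'
#' Displacements are in mm and use the pull-back convention: the field lives
#' on the *fixed* grid, and `x + u(x)` is the corresponding point in the
#' *moving* frame. Warping an image through the field therefore samples the
#' moving image at `x + u(x)`.
#'
#' @param disp 4D numeric array, dims `c(nx, ny, nz, 3)`, displacement in mm.
#' @param spacing,origin grid geometry of the fixed frame (mm).
#' @param max_disp optional bound; the field is rejected if any |component|
#'   exceeds it.
#' @return A `vector_field` object; `$convention` is fixed metadata.
#' @export
vector_field <- function(disp, spacing = c(1, 1, 1), origin = NULL,
                         max_disp = NULL) {
  if (!is.array(disp) || length(dim(disp)) != 4L || dim(disp)[4] != 3L)
    stop("`disp` must be a 4D array with last dimension 3")
  if (any(!is.finite(disp))) stop("displacement field must be finite")
  if (!is.null(max_disp) && max(abs(disp)) > max_disp)
    stop(sprintf("displacement exceeds bound %g mm", max_disp))
  spacing <- as.numeric(spacing)
  dims <- dim(disp)[1:3]
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  structure(list(disp = disp, spacing = spacing, origin = as.numeric(origin),
                 convention = "pull-back"),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> dims %s, spacing %s mm, max |u| %.2f mm (%s)\n",
              paste(dim(x$disp)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              max(abs(x$disp)), x$convention))
  invisible(x)
}

#' Zero displacement field on the grid of an image
#' @param img `voxel_image` providing the geometry.
#' @return `vector_field` of zeros.
#' @export
zero_field <- function(img) {
  d <- dim(img$values)
  vector_field(array(0, c(d, 3L)), img$spacing, img$origin)
}

#' Named binary masks on a stated grid
#'
#' @param masks named list of logical 3D arrays, all with identical dims.
#' @param spacing,origin grid geometry (mm).
#' @param prescriptions `data.frame` with columns `structure`, `dose_gy`,
#'   `fractions` for the CTV levels; may be empty for mask-only sets.
#' @param check_nesting verify CTV_primary subset of CTV_secondary subset of
#'   CTV_tertiary for the levels present.
#' @return A `structure_set`.
#' @export
structure_set <- function(masks, spacing = c(1, 1, 1), origin = NULL,
                          prescriptions = NULL, check_nesting = TRUE) {
  if (length(masks) == 0 || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list")
  dims <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L || any(dim(m) != dims))
      stop(sprintf("mask '%s' does not conform to the grid", nm))
    if (!is.logical(m)) masks[[nm]] <- m > 0.5
  }
  spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  if (is.null(prescriptions))
    prescriptions <- data.frame(structure = character(), dose_gy = numeric(),
                                fractions = integer())
  for (ctv in prescriptions$structure) {
    if (!ctv %in% names(masks)) stop(sprintf("prescribed CTV '%s' has no mask", ctv))
    if (!any(masks[[ctv]])) stop(sprintf("CTV mask '%s' is empty", ctv))
  }
  if (check_nesting) {
    lv <- intersect(c("CTV_primary", "CTV_secondary", "CTV_tertiary"), names(masks))
    if (length(lv) > 1) {
      for (i in seq_len(length(lv) - 1)) {
        inner <- masks[[lv[i]]]; outer <- masks[[lv[i + 1]]]
        if (any(inner & !outer))
          stop(sprintf("CTV nesting violated: %s not inside %s", lv[i], lv[i + 1]))
      }
    }
  }
  structure(list(masks = masks, dims = dims, spacing = spacing,
                 origin = as.numeric(origin), prescriptions = prescriptions),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %s grid\n", length(x$masks),
              paste(x$dims, collapse = "x")))
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

# --- interpolation -----------------------------------------------------------

# Trilinear interpolation of a 3D array at continuous 1-based voxel indices.
# `idx` is an n x 3 matrix; out-of-bounds points return `fill`, or are
# clamped to the grid edge when `fill = NULL`.
interp3 <- function(values, idx, fill = 0) {
  d <- dim(values)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  if (is.null(fill)) {
    x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
    z <- pmin(pmax(z, 1), d[3])
    oob <- logical(length(x))
  } else {
    oob <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x0 <- pmin(pmax(x0, 1), d[1] - 1L); fx <- x - x0
  y0 <- pmin(pmax(y0, 1), d[2] - 1L); fy <- y - y0
  z0 <- pmin(pmax(z0, 1), d[3] - 1L); fz <- z - z0
  if (d[1] == 1L) { x0 <- rep(1, length(x)); fx <- 0 }
  if (d[2] == 1L) { y0 <- rep(1, length(y)); fy <- 0 }
  if (d[3] == 1L) { z0 <- rep(1, length(z)); fz <- 0 }
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (x0) + (y0 - 1) * nx + (z0 - 1) * nxy
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) nx else 0L
  sz <- if (d[3] > 1L) nxy else 0L
  v000 <- values[base];           v100 <- values[base + sx]
  v010 <- values[base + sy];      v110 <- values[base + sx + sy]
  v001 <- values[base + sz];      v101 <- values[base + sx + sz]
  v011 <- values[base + sy + sz]; v111 <- values[base + sx + sy + sz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  out <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz
  if (!is.null(fill)) out[oob] <- fill
  out
}

# Nearest-neighbour interpolation at continuous 1-based voxel indices.
interp3_nn <- function(values, idx, fill = 0) {
  d <- dim(values)
  x <- round(idx[, 1]); y <- round(idx[, 2]); z <- round(idx[, 3])
  oob <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  out <- values[cbind(x, y, z)]
  out[oob] <- fill
  out
}

# n x 3 matrix of world coordinates for every voxel, in array linear order
# (first index fastest — matches R array storage).
grid_points <- function(img) {
  ax <- axis_coords(img)
  d <- grid_dims(img)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

world_to_index <- function(img, pts) {
  sweep(sweep(pts, 2, img$origin, "-"), 2, img$spacing, "/") + 1
}

#' Sample an image at arbitrary world points
#' @param img `voxel_image`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param interpolation "trilinear" or "nearest".
#' @param fill value returned outside the grid.
#' @return numeric vector of length n.
#' @export
sample_image <- function(img, pts, interpolation = c("trilinear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  idx <- world_to_index(img, pts)
  if (interpolation == "trilinear") interp3(img$values, idx, fill)
  else interp3_nn(img$values, idx, fill)
}

# --- warping -----------------------------------------------------------------

#' Warp an image through a displacement field
#'
#' `out(x) = img(x + u(x))`: the output lives on the grid of `dvf` (the fixed
#' frame) and samples `img` at the pulled-back points.
#'
#' @param img `voxel_image` to resample (the moving image).
#' @param dvf `vector_field` on the output grid, pull-back convention.
#' @param interpolation "trilinear" or "nearest".
#' @param fill value used for samples falling outside `img`.
#' @return `voxel_image` on the grid of `dvf`.
#' @export
warp_image <- function(img, dvf, interpolation = c("trilinear", "nearest"),
                       fill = -1000) {
  interpolation <- match.arg(interpolation)
  d <- dim(dvf$disp)[1:3]
  pts <- grid_points(dvf)
  n <- prod(d)
  pts <- pts + matrix(dvf$disp, nrow = n, ncol = 3)
  vals <- sample_image(img, pts, interpolation, fill)
  if (img$kind == "hu") vals <- pmin(pmax(vals, -1024), 3071) else vals <- pmax(vals, 0)
  voxel_image(array(vals, d), dvf$spacing, dvf$origin, kind = img$kind)
}

#' Warp a binary mask through a displacement field
#'
#' Masks are warped with trilinear interpolation of the 0/1 indicator and
#' re-thresholded at 0.5 (the package-wide convention).
#'
#' @param mask logical 3D array on the moving grid.
#' @param dvf `vector_field` (pull-back) whose grid defines the output.
#' @param geom object carrying the moving grid geometry (`spacing`, `origin`);
#'   defaults to the geometry of `dvf` (same-grid warp).
#' @return logical array on the grid of `dvf`.
#' @export
warp_mask <- function(mask, dvf, geom = dvf) {
  img <- voxel_image(array(as.numeric(mask), dim(mask)), geom$spacing,
                     geom$origin, kind = "dose")
  w <- warp_image(img, dvf, "trilinear", fill = 0)
  w$values >= 0.5
}

#' Warp every mask of a structure set through a field
#' @param structures `structure_set` on the moving grid.
#' @param dvf `vector_field` defining the output grid.
#' @return `structure_set` on the fixed grid; empty warped masks are kept but
#'   flagged via the `empty_structures` attribute.
#' @export
warp_structures <- function(structures, dvf) {
  out <- lapply(structures$masks, warp_mask, dvf = dvf, geom = structures)
  ss <- structure_set(out, dvf$spacing, dvf$origin,
                      prescriptions = structures$prescriptions,
                      check_nesting = FALSE)
  attr(ss, "empty_structures") <- names(out)[!vapply(out, any, logical(1))]
  ss
}

# --- mask morphology ---------------------------------------------------------

# shift a 3D array by integer voxels, padding with FALSE/0
shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    b <- by[k]
    if (abs(b) >= d[k]) return(out)
    if (b >= 0) { dst[[k]] <- (1 + b):d[k]; src[[k]] <- 1:(d[k] - b) }
    else        { dst[[k]] <- 1:(d[k] + b); src[[k]] <- (1 - b):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Isotropic dilation of a binary mask
#' @param mask logical 3D array.
#' @param radius_mm dilation radius (mm); 0 returns the mask unchanged.
#' @param spacing voxel spacing (mm).
#' @return logical array.
#' @export
dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  r <- ceiling(radius_mm / spacing)
  offs <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  keep <- (offs$x * spacing[1])^2 + (offs$y * spacing[2])^2 +
          (offs$z * spacing[3])^2 <= radius_mm^2
  offs <- offs[keep, , drop = FALSE]
  out <- mask
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    if (all(o == 0L)) next
    out <- out | shift_array(mask, o)
  }
  out
}

#' Dice similarity coefficient of two masks
#'
#' `2|A and B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays on the same grid.
#' @return numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

# --- NIfTI I/O ---------------------------------------------------------------

nifti_header_for <- function(spacing, origin, ndim4 = NULL) {
  pd <- c(-1, spacing, if (is.null(ndim4)) NULL else 1)
  pd <- c(pd, rep(0, 8 - length(pd)))
  list(pixdim = pd, qoffset_x = origin[1], qoffset_y = origin[2],
       qoffset_z = origin[3], qform_code = 1)
}

#' Write a voxel image to NIfTI
#' @param img `voxel_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(img, path) {
  n <- RNifti::asNifti(img$values, nifti_header_for(img$spacing, img$origin))
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' Read a voxel image from NIfTI
#' @param path NIfTI file.
#' @param kind "hu" or "dose".
#' @return `voxel_image`.
#' @export
read_image_nifti <- function(path, kind = "hu") {
  n <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(n)
  voxel_image(array(as.numeric(n), dim(n)[1:3]), spacing = h$pixdim[2:4],
              origin = c(h$qoffset_x, h$qoffset_y, h$qoffset_z), kind = kind)
}

#' Write a displacement field as 4D NIfTI (vector dimension last)
#' @param dvf `vector_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dvf_nifti <- function(dvf, path) {
  n <- RNifti::asNifti(dvf$disp,
                       nifti_header_for(dvf$spacing, dvf$origin, ndim4 = 4))
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' Read a displacement field from 4D NIfTI
#' @param path NIfTI file with vector dimension last.
#' @return `vector_field`.
#' @export
read_dvf_nifti <- function(path) {
  n <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(n)
  vector_field(array(as.numeric(n), dim(n)), spacing = h$pixdim[2:4],
               origin = c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}
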