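#' Configuration for deformable B-spline registration
#'
#' Multiresolution free-form deformation: the displacement field is a cubic
#' B-spline of a coarse coefficient grid, optimized coarse-to-fine by
#' projected gradient descent with a backtracking line search (accepted steps
#' never increase the objective, so the metric trace is monotone).
#'
#' @param levels number of pyramid levels (images downsampled by 2 per level).
#' @param cp_spacing control-point spacing in mm per level, monotonically
#'   decreasing; length must equal `levels`.
#' @param metric "ssd" (sum of squared differences with a radial cupping
#'   pre-correction of the fixed image, the default) or "lncc" (locally
#'   normalized cross-correlation). On piecewise-constant synthetic anatomy
#'   the normalized local windows of LNCC carry little signal, so
#'   bias-corrected SSD is the better-conditioned default here.
#' @param smooth_weight weight of the squared-second-difference penalty on
#'   the B-spline coefficients (dimensionless, >= 0).
#' @param max_iter iterations per level (scalar or per-level vector).
#' @param tol relative objective-change convergence tolerance per level.
#' @param lncc_window local window half-width in voxels for the LNCC metric.
#' @param init_translation optional known rigid pre-alignment (mm, pull-back
#'   convention) applied before the deformable stage.
#' @param translation_stage optimize a global translation at the coarsest
#'   resolution before the B-spline stage (bulk setup-shift recovery).
#' @param ssd_bias_correct for `metric = "ssd"`, subtract a least-squares
#'   radial quadratic intensity bias inside the FOV before matching.
#' @return A `registration_config`.
#' @export
registration_config <- function(levels = 3,
                                cp_spacing = c(32, 16, 8),
                                metric = c("ssd", "lncc"),
                                smooth_weight = 0.01,
                                max_iter = c(40, 30, 20),
                                tol = 1e-6,
                                lncc_window = 2,
                                init_translation = c(0, 0, 0),
                                translation_stage = TRUE,
                                ssd_bias_correct = TRUE) {
  metric <- match.arg(metric)
  if (levels < 1) stop("levels must be >= 1")
  if (length(cp_spacing) != levels)
    stop("cp_spacing must give one spacing per level")
  if (any(diff(cp_spacing) > 0))
    stop("cp_spacing must decrease monotonically across levels")
  if (smooth_weight < 0) stop("smooth_weight must be >= 0")
  if (length(max_iter) == 1) max_iter <- rep(max_iter, levels)
  structure(list(levels = levels, cp_spacing = cp_spacing, metric = metric,
                 smooth_weight = smooth_weight, max_iter = max_iter,
                 tol = tol, lncc_window = as.integer(lncc_window),
                 init_translation = as.numeric(init_translation),
                 translation_stage = isTRUE(translation_stage),
                 ssd_bias_correct = isTRUE(ssd_bias_correct)),
            class = "registration_config")
}

#' Write/read a registration configuration as YAML
#' @param cfg `registration_config`.
#' @param path file path.
#' @return `path` (write) or a `registration_config` (read).
#' @export
write_registration_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_registration_config
#' @export
read_registration_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(registration_config,
          y[intersect(names(y), names(formals(registration_config)))])
}

#' Configuration for fixed-point DVF inversion
#' @param max_iter iteration cap.
#' @param tol_mm residual tolerance in mm (> 0).
#' @return An `inversion_config`.
#' @export
inversion_config <- function(max_iter = 100, tol_mm = 0.1) {
  if (tol_mm <= 0) stop("tol_mm must be > 0")
  structure(list(max_iter = max_iter, tol_mm = tol_mm),
            class = "inversion_config")
}

# --- B-spline machinery ------------------------------------------------------

# Cubic B-spline basis matrix mapping a coefficient line (ncp nodes at
# spacing delta, first node at cp0) to samples at positions `pos` (mm).
bspline_basis <- function(pos, cp0, delta, ncp) {
  s <- (pos - cp0) / delta
  i0 <- floor(s)
  t <- s - i0
  w <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  B <- matrix(0, length(pos), ncp)
  for (l in 0:3) {
    j <- i0 - 1 + l  # 0-based node index; support nodes i0-1 .. i0+2
    ok <- j >= 0 & j < ncp
    B[cbind(which(ok), j[ok] + 1)] <- w[ok, l + 1]
  }
  B
}

# geometry of a coefficient grid covering axis coords `ax` at spacing delta
coeff_geom <- function(ax, delta) {
  lapply(1:3, function(k) {
    lo <- ax[[k]][1]; hi <- ax[[k]][length(ax[[k]])]
    cp0 <- lo - delta          # one node of margin before the grid
    ncp <- floor((hi - cp0) / delta) + 4L
    list(cp0 = cp0, delta = delta, ncp = ncp,
         nodes = cp0 + (seq_len(ncp) - 1) * delta)
  })
}

# contract a 3D coefficient array with per-axis basis matrices
tensor3 <- function(C, Bx, By, Bz) {
  d <- dim(C)
  m <- Bx %*% matrix(C, d[1])                       # nx x (cy*cz)
  a <- array(m, c(nrow(Bx), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  m <- By %*% matrix(a, d[2])                       # ny x (nx*cz)
  a <- array(m, c(nrow(By), nrow(Bx), d[3]))
  a <- aperm(a, c(3, 2, 1))
  m <- Bz %*% matrix(a, d[3])                       # nz x (nx*ny)
  a <- array(m, c(nrow(Bz), nrow(Bx), nrow(By)))
  aperm(a, c(2, 3, 1))
}

# membrane (squared first-difference) smoothness penalty and gradient on a
# coefficient array, normalized per coefficient so its scale matches the
# per-voxel metric. Constant fields (translations) are penalty-free; linear
# growth is not, which keeps metric-indifferent regions from drifting.
coeff_penalty <- function(C) {
  pen <- 0
  grad <- array(0, dim(C))
  nc <- length(C)
  for (axis in 1:3) {
    P <- aperm(C, c(axis, setdiff(1:3, axis)))
    dp <- dim(P)
    if (dp[1] < 2) next
    M <- matrix(P, dp[1])
    D <- M[2:dp[1], , drop = FALSE] - M[1:(dp[1] - 1), , drop = FALSE]
    pen <- pen + sum(D^2)
    G <- matrix(0, dp[1], ncol(M))
    G[2:dp[1], ]       <- G[2:dp[1], ]       + 2 * D
    G[1:(dp[1] - 1), ] <- G[1:(dp[1] - 1), ] - 2 * D
    perm <- c(axis, setdiff(1:3, axis))
    grad <- grad + aperm(array(G, dp), order(perm))
  }
  list(pen = pen / nc, grad = grad / nc)
}

# --- filters and metrics -----------------------------------------------------

# sliding box sum of half-width w along every axis (via padded cumsum)
box_sum <- function(A, w) {
  if (w <= 0) return(A)
  d <- dim(A)
  for (axis in 1:3) {
    P <- aperm(A, c(axis, setdiff(1:3, axis)))
    dp <- dim(P)
    M <- matrix(P, dp[1])
    cs <- rbind(0, apply(M, 2, cumsum))
    hi <- pmin(seq_len(dp[1]) + w, dp[1]) + 1
    lo <- pmax(seq_len(dp[1]) - w, 1)
    M2 <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
    perm <- c(axis, setdiff(1:3, axis))
    A <- aperm(array(M2, dp), order(perm))
  }
  A
}

# central-difference spatial gradient (per mm) of a 3D array
grad3 <- function(A, spacing) {
  d <- dim(A)
  g <- vector("list", 3)
  for (axis in 1:3) {
    fwd <- shift_array(A, -(axis == 1:3))
    bwd <- shift_array(A, (axis == 1:3))
    gg <- (fwd - bwd) / (2 * spacing[axis])
    # one-sided at the borders
    idx <- slice.index(A, axis)
    gg[idx == 1] <- 0; gg[idx == d[axis]] <- 0
    g[[axis]] <- gg
  }
  g
}

# LNCC metric (negated, lower is better) and voxelwise d(metric)/d(warped).
# Each voxel appears in every window containing it, so the gradient gathers
# the window-level factors with a second box filter (adjoint of the first).
lncc_metric <- function(Fv, Mv, roi, w) {
  eps <- 1e-5
  one <- array(1, dim(Fv))
  N <- box_sum(one, w)
  SF <- box_sum(Fv, w);  SM <- box_sum(Mv, w)
  SFF <- box_sum(Fv * Fv, w); SMM <- box_sum(Mv * Mv, w)
  SFM <- box_sum(Fv * Mv, w)
  cov <- SFM - SF * SM / N
  varF <- pmax(SFF - SF^2 / N, 0)
  varM <- pmax(SMM - SM^2 / N, 0)
  denom <- varF * varM + eps
  cc <- cov^2 / denom
  n_roi <- sum(roi)
  metric <- -sum(cc[roi]) / n_roi
  w_roi <- array(as.numeric(roi), dim(Fv))
  muF <- SF / N; muM <- SM / N
  alpha <- (cov / denom) * w_roi
  beta <- (cc / pmax(varM, eps)) * w_roi
  dM <- -2 * (Fv * box_sum(alpha, w) - box_sum(alpha * muF, w) -
              Mv * box_sum(beta, w) + box_sum(beta * muM, w)) / n_roi
  list(metric = metric, dM = dM)
}

ssd_metric <- function(Fv, Mv, roi) {
  n_roi <- sum(roi)
  r <- (Mv - Fv)
  r[!roi] <- 0
  list(metric = sum(r^2) / n_roi, dM = 2 * r / n_roi)
}

# remove a least-squares quadratic radial intensity bias (CBCT cupping),
# estimated on tissue voxels (HU > -500) inside roi so the air/body contrast
# does not masquerade as bias; the fitted radial term is subtracted on
# tissue voxels only
radial_bias_correct <- function(img, roi) {
  co <- grid_points(img)
  r2 <- (co[, 1]^2 + co[, 2]^2)
  r2 <- r2 / max(r2)
  v <- as.vector(img$values)
  tissue <- roi & array(v > -500, dim(img$values))
  if (sum(tissue) < 100) return(img)
  X <- cbind(1, r2[tissue])
  beta <- qr.solve(crossprod(X), crossprod(X, v[tissue]))
  v2 <- v
  v2[tissue] <- v[tissue] - beta[2] * (r2[tissue] - mean(r2[tissue]))
  voxel_image(array(pmin(pmax(v2, -1024), 3071), dim(img$values)),
              img$spacing, img$origin, kind = img$kind)
}

# box-downsample an image by integer factor per axis
downsample_image <- function(img, f) {
  if (all(f == 1)) return(img)
  d <- dim(img$values)
  nd <- pmax(d %/% f, 1L)
  idx <- lapply(1:3, function(k) rep(seq_len(nd[k]), each = f[k])[seq_len(nd[k] * f[k])])
  v <- img$values[seq_along(idx[[1]]), seq_along(idx[[2]]), seq_along(idx[[3]]), drop = FALSE]
  a <- rowsum(matrix(v, length(idx[[1]])), idx[[1]])
  a <- array(a, c(nd[1], length(idx[[2]]), length(idx[[3]])))
  a <- aperm(a, c(2, 1, 3))
  a <- rowsum(matrix(a, length(idx[[2]])), idx[[2]])
  a <- array(a, c(nd[2], nd[1], length(idx[[3]])))
  a <- aperm(a, c(3, 2, 1))
  a <- rowsum(matrix(a, length(idx[[3]])), idx[[3]])
  a <- array(a, c(nd[3], nd[1], nd[2]))
  a <- aperm(a, c(2, 3, 1)) / prod(f)
  voxel_image(a, img$spacing * f,
              img$origin + (f - 1) / 2 * img$spacing, kind = img$kind)
}

# --- registration ------------------------------------------------------------

#' Deformable B-spline registration of a moving image to a fixed image
#'
#' Estimates the pull-back displacement field on the fixed (e.g. CBCT) grid
#' such that `moving(x + u(x))` matches `fixed(x)`. Coarse-to-fine cubic
#' B-spline free-form deformation; the similarity metric is evaluated only
#' inside `fov`. Fully deterministic: uniform zero (or supplied translation)
#' initialization and fixed iteration caps.
#'
#' @param fixed,moving `voxel_image`s (e.g. CBCT and planning CT).
#' @param cfg `registration_config`.
#' @param fov optional logical array on the fixed grid restricting the
#'   metric (e.g. the CBCT field of view); default whole grid.
#' @param roi optional additional logical array intersected with `fov` to
#'   focus the registration on a subregion.
#' @return `vector_field` on the fixed grid (pull-back convention) with a
#'   `trace` attribute giving the per-level objective traces.
#' @export
deformable_register <- function(fixed, moving, cfg = registration_config(),
                                fov = NULL, roi = NULL) {
  if (any(!is.finite(fixed$values)) || any(!is.finite(moving$values)))
    stop("images must be finite")
  if (is.null(fov)) fov <- array(TRUE, dim(fixed$values))
  if (!all(dim(fov) == dim(fixed$values)))
    stop("fov must conform to the fixed grid")
  if (!is.null(roi)) fov <- fov & roi
  if (stats::sd(fixed$values[fov]) == 0 || stats::sd(moving$values) == 0)
    stop("registration metric undefined: an image has no contrast in the region of interest")
  if (cfg$ssd_bias_correct)
    fixed_ssd <- radial_bias_correct(fixed, fov)
  else fixed_ssd <- fixed
  if (cfg$metric == "ssd") fixed <- fixed_ssd

  fov_img <- voxel_image(array(as.numeric(fov), dim(fov)), fixed$spacing,
                         fixed$origin, kind = "dose")
  coeffs <- NULL
  geom <- NULL
  traces <- vector("list", cfg$levels)

  # stage 0: global translation at the coarsest resolution, so that bulk
  # shifts are carried into featureless regions the B-spline stage cannot see
  trans <- cfg$init_translation
  if (cfg$translation_stage) {
    f <- rep(2^(cfg$levels - 1), 3)
    fx <- downsample_image(fixed_ssd, f)   # SSD landscape is smoother for bulk shifts
    fov_l <- downsample_image(fov_img, f)$values > 0.5
    mov_grad <- grad3(moving$values, moving$spacing)
    pts0 <- grid_points(fx)
    eval_t <- function(t) {
      pts <- sweep(pts0, 2, t, "+")
      warped <- array(sample_image(moving, pts, fill = -1000), dim(fx$values))
      met <- ssd_metric(fx$values, warped, fov_l)
      c(met, list(pts = pts))
    }
    st <- eval_t(trans)
    step <- 2
    for (it in 1:30) {
      midx <- world_to_index(moving, st$pts)
      g <- vapply(1:3, function(k)
        sum(st$dM * interp3(mov_grad[[k]], midx, fill = 0)), 0)
      gmax <- max(abs(g))
      if (gmax == 0) break
      step <- max(step, 0.25)
      scale <- step / gmax
      accepted <- FALSE
      for (try in 1:8) {
        st2 <- eval_t(trans - scale * g)
        if (st2$metric < st$metric) { accepted <- TRUE; break }
        scale <- scale / 2
      }
      if (!accepted) break
      trans <- trans - scale * g
      st <- st2
      step <- min(scale * gmax * 1.5, 4)
    }
  }

  for (lev in seq_len(cfg$levels)) {
    f <- rep(2^(cfg$levels - lev), 3)
    fx <- downsample_image(fixed, f)
    fov_l <- downsample_image(fov_img, f)$values > 0.5
    ax <- axis_coords(fx)
    g_new <- coeff_geom(ax, cfg$cp_spacing[lev])
    Bx <- bspline_basis(ax[[1]], g_new[[1]]$cp0, g_new[[1]]$delta, g_new[[1]]$ncp)
    By <- bspline_basis(ax[[2]], g_new[[2]]$cp0, g_new[[2]]$delta, g_new[[2]]$ncp)
    Bz <- bspline_basis(ax[[3]], g_new[[3]]$cp0, g_new[[3]]$delta, g_new[[3]]$ncp)
    cdim <- c(g_new[[1]]$ncp, g_new[[2]]$ncp, g_new[[3]]$ncp)

    if (is.null(coeffs)) {
      coeffs <- lapply(1:3, function(k) array(trans[k], cdim))
    } else {
      # initialize the finer coefficient grid from the coarser field
      NBx <- bspline_basis(g_new[[1]]$nodes, geom[[1]]$cp0, geom[[1]]$delta, geom[[1]]$ncp)
      NBy <- bspline_basis(g_new[[2]]$nodes, geom[[2]]$cp0, geom[[2]]$delta, geom[[2]]$ncp)
      NBz <- bspline_basis(g_new[[3]]$nodes, geom[[3]]$cp0, geom[[3]]$delta, geom[[3]]$ncp)
      coeffs <- lapply(coeffs, function(C) tensor3(C, NBx, NBy, NBz))
    }
    geom <- g_new

    pts0 <- grid_points(fx)
    nvox <- nrow(pts0)
    # moving-image gradient (per mm), sampled at the pulled-back points when
    # the chain rule needs d(warped)/d(u)
    mov_grad <- grad3(moving$values, moving$spacing)
    eval_obj <- function(cf) {
      u <- vapply(cf, function(C) as.vector(tensor3(C, Bx, By, Bz)),
                  numeric(nvox))
      pts <- pts0 + u
      warped <- array(sample_image(moving, pts, fill = -1000), dim(fx$values))
      met <- if (cfg$metric == "lncc")
        lncc_metric(fx$values, warped, fov_l, cfg$lncc_window)
      else ssd_metric(fx$values, warped, fov_l)
      pens <- lapply(cf, coeff_penalty)
      list(metric = met$metric,
           total = met$metric + cfg$smooth_weight * sum(vapply(pens, `[[`, 0, "pen")),
           dM = met$dM, pts = pts, pens = pens)
    }

    st <- eval_obj(coeffs)
    step <- cfg$cp_spacing[lev] / 8      # initial max coefficient update, mm
    trace <- st$total
    stall <- 0L
    # mass-normalizing the adjoint turns the coefficient gradient into a
    # local average of the voxel forces, which keeps the update smooth
    mass <- pmax(tensor3(array(1, dim(fx$values)), t(Bx), t(By), t(Bz)), 1e-8)
    for (it in seq_len(cfg$max_iter[lev])) {
      midx <- world_to_index(moving, st$pts)
      grads <- vector("list", 3)
      for (k in 1:3) {
        gk <- array(interp3(mov_grad[[k]], midx, fill = 0), dim(fx$values))
        force <- st$dM * gk
        grads[[k]] <- tensor3(force, t(Bx), t(By), t(Bz)) / mass +
          2 * cfg$smooth_weight * st$pens[[k]]$grad
      }
      gmax <- max(abs(unlist(grads)))
      if (gmax == 0) break
      step <- max(step, cfg$cp_spacing[lev] / 16)  # step floor: recover from stalls
      scale <- step / gmax
      accepted <- FALSE
      for (try in 1:8) {
        cand <- lapply(1:3, function(k) coeffs[[k]] - scale * grads[[k]])
        st2 <- eval_obj(cand)
        if (isTRUE(getOption("aptkit.reg.debug")))
          message(sprintf("lev %d it %d try %d: total %.6g -> %.6g (gmax %.3g)",
                          lev, it, try, st$total, st2$total, gmax))
        if (st2$total < st$total) { accepted <- TRUE; break }
        scale <- scale / 2
      }
      if (!accepted) break
      rel <- (st$total - st2$total) / max(abs(st$total), 1e-12)
      coeffs <- cand
      st <- st2
      step <- min(scale * gmax * 1.5, cfg$cp_spacing[lev] / 4)
      trace <- c(trace, st$total)
      stall <- if (rel < cfg$tol) stall + 1L else 0L
      if (stall >= 5L) break
    }
    traces[[lev]] <- trace
  }

  # final field on the full-resolution fixed grid
  ax <- axis_coords(fixed)
  Bx <- bspline_basis(ax[[1]], geom[[1]]$cp0, geom[[1]]$delta, geom[[1]]$ncp)
  By <- bspline_basis(ax[[2]], geom[[2]]$cp0, geom[[2]]$delta, geom[[2]]$ncp)
  Bz <- bspline_basis(ax[[3]], geom[[3]]$cp0, geom[[3]]$delta, geom[[3]]$ncp)
  disp <- array(0, c(dim(fixed$values), 3L))
  for (k in 1:3) disp[, , , k] <- tensor3(coeffs[[k]], Bx, By, Bz)
  out <- vector_field(disp, fixed$spacing, fixed$origin)
  attr(out, "trace") <- traces
  out
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(x) = -u(x + v(x))` so that the returned field composes with the
#' input to (near-)identity. Iterates until the worst composition residual
#' `|u(x + v(x)) + v(x)|` drops below `cfg$tol_mm` or the cap is reached.
#'
#' @param dvf `vector_field` to invert (pull-back convention).
#' @param cfg `inversion_config`.
#' @return `vector_field` on the same grid; the residual map (mm) is attached
#'   as attribute `residual`.
#' @export
invert_dvf <- function(dvf, cfg = inversion_config()) {
  d <- dim(dvf$disp)[1:3]
  n <- prod(d)
  pts <- grid_points(dvf)
  u <- matrix(dvf$disp, n, 3)
  v <- matrix(0, n, 3)
  worst <- Inf
  for (it in seq_len(cfg$max_iter)) {
    q <- pts + v
    idx <- world_to_index(dvf, q)
    u_at <- vapply(1:3, function(k)
      interp3(array(u[, k], d), idx, fill = NULL), numeric(n))
    res <- u_at + v
    worst <- max(sqrt(rowSums(res^2)))
    if (worst < cfg$tol_mm) break
    v <- -u_at
  }
  if (worst >= cfg$tol_mm)
    stop(sprintf("DVF inversion did not converge: worst residual %.3f mm after %d iterations",
                 worst, cfg$max_iter))
  out <- vector_field(array(v, c(d, 3L)), dvf$spacing, dvf$origin)
  attr(out, "residual") <- array(sqrt(rowSums((u_at + v)^2)), d)
  out
}
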