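#' Dose-volume indices of a structure
#'
#' Conventions: `Dmean` is the voxel mean, `Dmax` the single-voxel maximum
#' (no near-max percentile), `VxGy` the percent of structure voxels
#' receiving at least x Gy, and `V95`/`V100` the percent receiving at least
#' 95%/100% of the structure's prescription `rx`.
#'
#' @param dose `voxel_image` (Gy) or a numeric array.
#' @param mask logical array on the same grid; must be non-empty.
#' @param rx prescription dose (Gy) for V95/V100; NA skips them.
#' @param vx_gy numeric vector of absolute dose levels for VxGy indices.
#' @return named list: `Dmean`, `Dmax`, `Dmin`, `V95`, `V100`, and one
#'   `V<x>Gy` entry per requested level.
#' @export
dose_indices <- function(dose, mask, rx = NA, vx_gy = numeric()) {
  v <- if (inherits(dose, "voxel_image")) dose$values else dose
  if (!all(dim(v) == dim(mask))) stop("dose and mask grids differ")
  d <- v[mask]
  if (length(d) == 0) stop("empty mask: no dose-volume indices")
  out <- list(Dmean = mean(d), Dmax = max(d), Dmin = min(d))
  if (!is.na(rx)) {
    out$V95 <- mean(d >= 0.95 * rx) * 100
    out$V100 <- mean(d >= rx) * 100
  }
  for (x in vx_gy) out[[sprintf("V%gGy", x)]] <- mean(d >= x) * 100
  out
}

#' Cumulative dose-volume histogram
#' @param dose `voxel_image` (Gy) or numeric array.
#' @param mask logical array.
#' @param bin_gy bin width (Gy), default 0.1.
#' @return data.frame with `dose_gy` (bin edges) and `volume_frac`
#'   (fraction of the structure receiving at least that dose; monotone
#'   non-increasing from 1 to 0).
#' @export
dvh_curve <- function(dose, mask, bin_gy = 0.1) {
  v <- if (inherits(dose, "voxel_image")) dose$values else dose
  d <- v[mask]
  if (length(d) == 0) stop("empty mask")
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  frac <- vapply(edges, function(e) mean(d >= e), 0)
  data.frame(dose_gy = edges, volume_frac = frac)
}

#' Configuration for 3D global gamma analysis
#'
#' @param dd_pct dose-difference criterion, percent of `norm_gy` (global
#'   normalization).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param norm_gy global normalization dose (Gy); by convention the primary
#'   prescription.
#' @param threshold low-dose cutoff as a fraction of `norm_gy` (reference
#'   voxels below it are not analyzed), default 0.10.
#' @param search_mult search radius as a multiple of `dta_mm`.
#' @param step_frac interpolation step of the evaluated dose as a fraction
#'   of `dta_mm`.
#' @return A `gamma_config`.
#' @export
gamma_config <- function(dd_pct = 3, dta_mm = 3, norm_gy,
                         threshold = 0.10, search_mult = 1.5,
                         step_frac = 1 / 3) {
  if (dd_pct <= 0 || dta_mm <= 0) stop("gamma criteria must be > 0")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  if (missing(norm_gy) || norm_gy <= 0)
    stop("a positive global normalization dose is required")
  structure(list(dd_pct = dd_pct, dta_mm = dta_mm, norm_gy = norm_gy,
                 threshold = threshold, search_mult = search_mult,
                 step_frac = step_frac),
            class = "gamma_config")
}

#' 3D global gamma analysis
#'
#' For every reference voxel above the low-dose threshold, the gamma index
#' is the minimum over evaluated positions within the search radius of
#' `sqrt(|dr|^2 / DTA^2 + dD^2 / (dd * Dnorm)^2)`, with the evaluated dose
#' trilinearly interpolated on a subvoxel offset grid. A voxel passes iff
#' gamma <= 1 (inclusive).
#'
#' @param ref reference dose (`voxel_image`, Gy).
#' @param eval_img evaluated dose (`voxel_image`) on the same grid.
#' @param cfg `gamma_config`.
#' @return list with `pass_rate` (percent of analyzed voxels with gamma <=
#'   1), `gamma` (`voxel_image`; NA outside the analyzed region) and
#'   `n_analyzed`.
#' @export
gamma_3d <- function(ref, eval_img, cfg) {
  if (!same_grid(ref, eval_img)) stop("gamma requires a common grid")
  rv <- ref$values
  analyzed <- which(rv > cfg$threshold * cfg$norm_gy)
  if (length(analyzed) == 0) stop("no reference voxels above the gamma threshold")
  d <- dim(rv)
  coords <- arrayInd(analyzed, d)            # 1-based voxel indices
  dd_abs <- cfg$dd_pct / 100 * cfg$norm_gy
  dta <- cfg$dta_mm
  rmax <- cfg$search_mult * dta
  step <- cfg$step_frac * dta

  ns <- floor(rmax / step)
  ax_off <- seq(-ns, ns) * step            # symmetric, always includes 0
  offs <- expand.grid(x = ax_off, y = ax_off, z = ax_off)
  r2 <- offs$x^2 + offs$y^2 + offs$z^2
  keep <- r2 <= rmax^2
  offs <- offs[keep, , drop = FALSE]
  r2 <- r2[keep]
  ord <- order(r2)                           # nearest offsets first
  offs <- offs[ord, , drop = FALSE]; r2 <- r2[ord]

  rd <- rv[analyzed]
  best <- rep(Inf, length(analyzed))
  for (i in seq_len(nrow(offs))) {
    geom2 <- r2[i] / dta^2
    alive <- which(best > geom2)             # this offset can still improve
    if (length(alive) == 0) break
    idx <- cbind(coords[alive, 1] + offs$x[i] / ref$spacing[1],
                 coords[alive, 2] + offs$y[i] / ref$spacing[2],
                 coords[alive, 3] + offs$z[i] / ref$spacing[3])
    ev <- interp3(eval_img$values, idx, fill = NA)
    g2 <- geom2 + (ev - rd[alive])^2 / dd_abs^2
    upd <- !is.na(g2) & g2 < best[alive]
    best[alive[upd]] <- g2[upd]
  }
  gamma <- sqrt(best)
  gmap <- array(NA_real_, d)
  gmap[analyzed] <- gamma
  # gamma <= 1 counts as a pass (inclusive), with a tolerance for floating
  # point at the exact boundary
  list(pass_rate = mean(gamma <= 1 + 1e-9) * 100,
       gamma = structure(list(values = gmap, spacing = ref$spacing,
                              origin = ref$origin, kind = "dose"),
                         class = "voxel_image"),
       n_analyzed = length(analyzed))
}

#' Audit dose indices against the planning constraint table
#'
#' Pass/fail per (structure, constraint) with strict inequality: an index
#' exactly at its limit fails.
#'
#' @param indices data.frame with columns `structure`, `metric`, `value`
#'   (Gy for Dmean/Dmax, percent for VxGy) and optionally `rx` (primary
#'   prescription, needed for pct_rx limits).
#' @param constraints constraint table (see [default_constraints()]).
#' @param rx_primary primary prescription (Gy) for pct_rx limits.
#' @return data.frame `structure`, `metric`, `value`, `limit`, `pass`;
#'   empty input yields an empty report.
#' @export
check_constraints <- function(indices, constraints = default_constraints(),
                              rx_primary = NA) {
  out <- list()
  for (i in seq_len(nrow(indices))) {
    row <- indices[i, ]
    hits <- match_constraints(row$structure, constraints)
    hits <- hits[hits$metric == row$metric, , drop = FALSE]
    if (nrow(hits) == 0) next
    lim <- hits$limit[1]
    if (hits$limit_unit[1] == "pct_rx") {
      if (is.na(rx_primary)) stop("rx_primary needed for percent-of-prescription limits")
      lim <- lim / 100 * rx_primary
    }
    out[[length(out) + 1L]] <- data.frame(
      structure = row$structure, metric = row$metric, value = row$value,
      limit = lim, pass = row$value < lim)
  }
  if (length(out) == 0)
    return(data.frame(structure = character(), metric = character(),
                      value = numeric(), limit = numeric(), pass = logical()))
  do.call(rbind, out)
}

#' Accumulate weekly doses on the planning CT
#'
#' Fraction-weighted average of the weekly full-course doses warped to the
#' planning frame through the inverse DVFs:
#' `accumulated = sum_w (f_w / F) * warp(D_w, invDVF_w)` with trilinear
#' interpolation, where `f_w` is the number of fractions the week stands
#' for and `F` their total.
#'
#' @param weekly_doses list of `voxel_image`s (Gy), one per sampled week.
#' @param inverse_dvfs list of `vector_field`s on the planning grid mapping
#'   planning points into each week's frame (the inverses of the sCT DVFs).
#' @param fractions integer vector, fractions represented by each week;
#'   `sum(fractions)` must equal the course total.
#' @param course_fractions total fraction count of the course.
#' @return `voxel_image` (Gy) on the planning grid.
#' @export
accumulate_dose <- function(weekly_doses, inverse_dvfs, fractions,
                            course_fractions = sum(fractions)) {
  n <- length(weekly_doses)
  if (length(inverse_dvfs) != n || length(fractions) != n)
    stop("need one dose, one inverse DVF and one fraction count per week")
  if (abs(sum(fractions) - course_fractions) > 1e-6)
    stop("fraction counts must sum to the course total")
  acc <- NULL
  for (w in seq_len(n)) {
    warped <- warp_image(weekly_doses[[w]], inverse_dvfs[[w]], "trilinear",
                         fill = 0)
    contrib <- warped$values * fractions[w] / course_fractions
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  voxel_image(acc, inverse_dvfs[[1]]$spacing, inverse_dvfs[[1]]$origin,
              kind = "dose")
}

#' Generalized equivalent uniform dose
#'
#' `gEUD = (sum_i v_i d_i^(1/n))^n` with relative volumes `v_i` summing to
#' 1. Reduces to the mean dose at `n = 1` and approaches the maximum as
#' `n -> 0`.
#'
#' @param dose `voxel_image`/array (with `mask`) or a numeric vector of
#'   voxel doses.
#' @param n volume parameter (> 0).
#' @param mask logical array when `dose` is gridded.
#' @return gEUD in Gy.
#' @export
geud <- function(dose, n, mask = NULL) {
  if (n <= 0) stop("volume parameter n must be > 0")
  d <- if (inherits(dose, "voxel_image")) dose$values[mask]
       else if (!is.null(mask)) dose[mask] else dose
  if (length(d) == 0) stop("no voxels for gEUD")
  mean(d^(1 / n))^n
}

#' Lyman-Kutcher-Burman NTCP parameters for one endpoint
#'
#' The parameter values shipped with the package are editable literature
#' stand-ins for the cited model families; each row carries its source
#' string and should be reviewed before any quantitative use.
#'
#' @param endpoint endpoint label.
#' @param structure structure whose dose feeds the model.
#' @param n,m,td50 LKB volume parameter, slope and 50% tolerance dose (Gy);
#'   all > 0.
#' @param source free-text provenance of the parameter values.
#' @return An `ntcp_params`.
#' @export
ntcp_params <- function(endpoint, structure, n, m, td50, source = "") {
  if (n <= 0 || m <= 0 || td50 <= 0) stop("n, m and TD50 must be > 0")
  structure(list(endpoint = endpoint, structure = structure, n = n, m = m,
                 td50 = td50, source = source),
            class = "ntcp_params")
}

#' Default NTCP endpoint table
#'
#' Four head-and-neck endpoints evaluated after the treatment course:
#' larynx edema, dysphagia (pharyngeal constrictors), xerostomia (parotid)
#' and acute esophagitis. Parameter values are configurable literature
#' stand-ins (see each `source`).
#'
#' @return named list of `ntcp_params`.
#' @export
default_ntcp_params <- function() {
  list(
    larynx_edema = ntcp_params(
      "larynx_edema_grade2plus", "larynx", n = 0.45, m = 0.18, td50 = 46.3,
      source = "LKB fit family for grade >= 2 larynx edema (synthetic stand-in)"),
    dysphagia = ntcp_params(
      "dysphagia_grade2plus", "constrictors", n = 1.0, m = 0.25, td50 = 50,
      source = "mean-dose LKB stand-in for grade >= 2 dysphagia"),
    xerostomia = ntcp_params(
      "xerostomia", "parotid_ips", n = 1.0, m = 0.4, td50 = 39.9,
      source = "mean-dose LKB stand-in for parotid xerostomia"),
    esophagitis = ntcp_params(
      "acute_esophagitis_grade2plus", "esophagus", n = 0.69, m = 0.36,
      td50 = 47, source = "LKB stand-in for grade >= 2 acute esophagitis"))
}

#' Write/read the NTCP parameter table as YAML
#' @param params named list of `ntcp_params`.
#' @param path file path.
#' @return `path` (write) or the list (read).
#' @export
write_ntcp_params <- function(params, path) {
  yaml::write_yaml(lapply(params, unclass), path)
  invisible(path)
}

#' @rdname write_ntcp_params
#' @export
read_ntcp_params <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(p) ntcp_params(p$endpoint, p$structure, p$n, p$m,
                                    p$td50, p$source))
}

#' Lyman-Kutcher-Burman NTCP
#'
#' `NTCP = Phi((gEUD - TD50) / (m * TD50))` with `Phi` the standard normal
#' CDF; strictly increasing in gEUD, decreasing in TD50.
#'
#' @param geud_gy gEUD of the structure (Gy).
#' @param params `ntcp_params`.
#' @return probability in (0, 1).
#' @export
lkb_ntcp <- function(geud_gy, params) {
  stats::pnorm((geud_gy - params$td50) / (params$m * params$td50))
}

#' NTCP of an endpoint from a dose distribution
#' @param dose `voxel_image` (Gy).
#' @param mask logical array for the endpoint's structure.
#' @param params `ntcp_params`.
#' @return probability in (0, 1).
#' @export
ntcp_from_dose <- function(dose, mask, params) {
  lkb_ntcp(geud(dose, params$n, mask), params)
}

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] with the degenerate case handled:
#' when the paired differences have zero variance the test statistic is
#' undefined, and the result carries `p = 1` with `degenerate = TRUE`.
#'
#' @param x,y paired samples of equal length (>= 2).
#' @return list with `mean_diff`, `t`, `df`, `p` and `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
                p = 1, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}
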