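#' Enumerate robustness scenarios
#'
#' Cartesian product of the six signed cardinal setup shifts with the two
#' range scales: `(+/- setup_mm along x, y, z) x (1 -/+ range_frac)`,
#' yielding twelve uncertainty scenarios for the default 3 mm / 3%. The
#' nominal scenario (no shift, scale 1) is returned separately. Degenerate
#' magnitudes deduplicate.
#'
#' @param setup_mm setup-shift magnitude (mm, >= 0).
#' @param range_frac fractional range uncertainty (>= 0), e.g. 0.03.
#' @return list with `nominal` and `scenarios` (list of
#'   `list(shift, scale)`).
#' @export
enumerate_scenarios <- function(setup_mm = 3, range_frac = 0.03) {
  if (setup_mm < 0 || range_frac < 0) stop("magnitudes must be >= 0")
  nominal <- list(shift = c(0, 0, 0), scale = 1)
  shifts <- list()
  for (ax in 1:3) for (sg in c(-1, 1)) {
    s <- c(0, 0, 0); s[ax] <- sg * setup_mm
    shifts[[length(shifts) + 1L]] <- s
  }
  scales <- c(1 - range_frac, 1 + range_frac)
  out <- list()
  seen <- character()
  for (sh in shifts) for (sc in scales) {
    key <- paste(c(sh, sc), collapse = "/")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(shift = sh, scale = sc)
  }
  # fully degenerate case collapses to the nominal scenario
  if (length(out) == 1 && all(out[[1]]$shift == 0) && out[[1]]$scale == 1)
    out <- out[1]
  list(nominal = nominal, scenarios = out)
}

#' Default organ-at-risk dose constraints
#'
#' The planning constraint table: one row per structure and dose-volume
#' metric. `limit_unit` is "Gy", "pct_rx" (percent of the primary
#' prescription, for the body maximum) or "pct_vol" (percent volume for
#' VxGy-type constraints, with `dose_gy` giving the dose level).
#'
#' @return data.frame with columns `structure`, `metric`, `limit`,
#'   `limit_unit`, `dose_gy`.
#' @export
default_constraints <- function() {
  data.frame(
    structure  = c("body", "brainstem", "cochlea", "constrictors", "larynx",
                   "mandible", "oral_cavity", "spinal_cord", "parotid",
                   "parotid", "esophagus", "eye", "optic_nerve",
                   "optic_chiasm", "submandibular"),
    metric     = c("Dmax", "Dmax", "Dmean", "Dmean", "Dmean", "Dmax",
                   "Dmean", "Dmax", "Dmean", "V20Gy", "Dmean", "Dmax",
                   "Dmax", "Dmax", "Dmean"),
    limit      = c(115, 54, 40, 50, 50, 75, 50, 48, 26, 50, 40, 45, 50, 50,
                   39),
    limit_unit = c("pct_rx", "Gy", "Gy", "Gy", "Gy", "Gy", "Gy", "Gy", "Gy",
                   "pct_vol", "Gy", "Gy", "Gy", "Gy", "Gy"),
    dose_gy    = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 20, NA, NA, NA, NA,
                   NA))
}

#' Write/read a constraint table as YAML
#' @param constraints data.frame as from [default_constraints()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_constraints <- function(constraints, path) {
  yaml::write_yaml(lapply(seq_len(nrow(constraints)), function(i)
    as.list(constraints[i, ])), path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  do.call(rbind, lapply(yaml::read_yaml(path), function(r)
    data.frame(structure = r$structure, metric = r$metric, limit = r$limit,
               limit_unit = r$limit_unit,
               dose_gy = if (is.null(r$dose_gy) || is.na(r$dose_gy)) NA_real_
                         else r$dose_gy)))
}

# match a phantom structure name against the constraint table: exact name
# first, then with a laterality suffix (_ips/_con/_l/_r) stripped
match_constraints <- function(name, constraints) {
  hit <- constraints[constraints$structure == name, , drop = FALSE]
  if (nrow(hit) > 0) return(hit)
  base <- sub("_(ips|con|cont|l|r|left|right)$", "", name)
  constraints[constraints$structure == base, , drop = FALSE]
}

#' Rule-based objective generation
#'
#' A deterministic stand-in for DVH-prediction-based automated planning:
#' each prescribed CTV receives a robust minimum-dose objective at its
#' prescription and a robust maximum-dose objective at 103% of it; each OAR
#' with a constraint-table entry receives a non-robust objective placed at a
#' fixed fraction (default 90%) of its constraint. Targets are the only
#' robust structures. Structures with no matching constraint are excluded
#' with a warning.
#'
#' @param structures `structure_set` (prescriptions define the CTVs).
#' @param constraints constraint table, default [default_constraints()].
#' @param oar_fraction fraction of the constraint at which OAR objectives
#'   are placed.
#' @param target_weight,target_max_weight,oar_weight penalty weights.
#' @return data.frame of objectives: `structure`, `kind`
#'   (target-min/target-max/oar-max/oar-mean/oar-dvh-point), `dose_gy`,
#'   `volume_pct`, `weight`, `robust`.
#' @export
generate_objectives <- function(structures, constraints = default_constraints(),
                                oar_fraction = 0.9, target_weight = 100,
                                target_max_weight = 30, oar_weight = 3) {
  rx_tab <- structures$prescriptions
  if (nrow(rx_tab) == 0) stop("structure set carries no prescriptions")
  rx_primary <- rx_tab$dose_gy[1]
  obj <- list()
  add <- function(...) obj[[length(obj) + 1L]] <<- data.frame(...)
  for (i in seq_len(nrow(rx_tab))) {
    add(structure = rx_tab$structure[i], kind = "target-min",
        dose_gy = rx_tab$dose_gy[i], volume_pct = NA_real_,
        weight = target_weight, robust = TRUE)
    add(structure = rx_tab$structure[i], kind = "target-max",
        dose_gy = 1.03 * rx_tab$dose_gy[i], volume_pct = NA_real_,
        weight = target_max_weight, robust = TRUE)
  }
  oars <- setdiff(names(structures$masks),
                  c(rx_tab$structure, "artifact", "chin_avoidance"))
  for (nm in oars) {
    hits <- match_constraints(nm, constraints)
    if (nrow(hits) == 0) {
      warning(sprintf("no dose constraint for structure '%s'; excluded from the objective list", nm))
      next
    }
    for (j in seq_len(nrow(hits))) {
      h <- hits[j, ]
      lim <- if (h$limit_unit == "pct_rx") h$limit / 100 * rx_primary else h$limit
      if (h$metric == "Dmax") {
        add(structure = nm, kind = "oar-max", dose_gy = oar_fraction * lim,
            volume_pct = NA_real_, weight = oar_weight, robust = FALSE)
      } else if (h$metric == "Dmean") {
        add(structure = nm, kind = "oar-mean", dose_gy = oar_fraction * lim,
            volume_pct = NA_real_, weight = oar_weight, robust = FALSE)
      } else {
        add(structure = nm, kind = "oar-dvh-point", dose_gy = h$dose_gy,
            volume_pct = oar_fraction * h$limit, weight = oar_weight,
            robust = FALSE)
      }
    }
  }
  do.call(rbind, obj)
}

# one-sided quadratic penalty (and voxel gradient) of an objective given the
# dose vector on its structure voxels; normalized by level^2 for conditioning
objective_penalty <- function(kind, d, level, volume_pct = NA) {
  norm <- max(level, 1)^2
  n <- length(d)
  if (kind %in% c("target-min")) {
    r <- pmax(level - d, 0)
    list(pen = sum(r^2) / n / norm, grad = -2 * r / n / norm)
  } else if (kind %in% c("target-max", "oar-max")) {
    r <- pmax(d - level, 0)
    list(pen = sum(r^2) / n / norm, grad = 2 * r / n / norm)
  } else if (kind == "oar-mean") {
    m <- mean(d)
    r <- max(m - level, 0)
    list(pen = r^2 / norm, grad = rep(2 * r / n / norm, n))
  } else if (kind == "oar-dvh-point") {
    # VxGy <= volume_pct: penalize the coolest voxels above `level` that
    # exceed the allowed count (classic DVH objective)
    over <- which(d > level)
    allowed <- floor(volume_pct / 100 * n)
    excess <- length(over) - allowed
    g <- numeric(n)
    if (excess <= 0) return(list(pen = 0, grad = g))
    sel <- over[order(d[over])][seq_len(excess)]
    r <- d[sel] - level
    g[sel] <- 2 * r / n / norm
    list(pen = sum(r^2) / n / norm, grad = g)
  } else stop("unknown objective kind: ", kind)
}

#' Optimizer settings for robust spot-weight optimization
#' @param max_iter iteration cap.
#' @param tol relative objective-change tolerance (with 5-iteration
#'   patience).
#' @param include_nominal include the nominal scenario in the worst-case set
#'   for robust target terms.
#' @param aggregation robust aggregation for target terms: "voxelwise"
#'   (per-voxel worst dose over scenarios, the default), "worst" (worst
#'   scenario-level penalty) or "expectation" (scenario average).
#' @return An `optimizer_config`.
#' @export
optimizer_config <- function(max_iter = 120, tol = 1e-7,
                             include_nominal = TRUE,
                             aggregation = c("voxelwise", "worst",
                                             "expectation")) {
  structure(list(max_iter = max_iter, tol = tol,
                 include_nominal = isTRUE(include_nominal),
                 aggregation = match.arg(aggregation)),
            class = "optimizer_config")
}

#' Robust spot-weight optimization
#'
#' Minimizes the weighted sum of one-sided quadratic penalties by projected
#' gradient descent with a backtracking line search (weights >= 0).
#' Robust (target) objectives are evaluated as the worst case over the
#' scenario influence set (plus nominal by default); OAR objectives use the
#' nominal influence only. Deterministic: uniform initialization scaled so
#' the mean target dose matches the primary prescription, fixed iteration
#' budget.
#'
#' @param infl_nominal nominal influence matrix (from [compute_influence()]
#'   over the evaluation region).
#' @param infl_scenarios list of scenario influence matrices over the target
#'   (robust) region.
#' @param objectives data.frame from [generate_objectives()].
#' @param structures `structure_set` (for voxel memberships).
#' @param cfg `optimizer_config`.
#' @return list with `weights`, `trace` (objective per accepted iteration)
#'   and `objective`.
#' @export
optimize_weights <- function(infl_nominal, infl_scenarios, objectives,
                             structures, cfg = optimizer_config()) {
  nspots <- ncol(infl_nominal)
  nom_idx <- attr(infl_nominal, "region_idx")
  rob_idx <- if (length(infl_scenarios)) attr(infl_scenarios[[1]], "region_idx")
             else nom_idx

  # per-objective row sets and per-scenario submatrices
  rx_tab <- structures$prescriptions
  terms <- vector("list", nrow(objectives))
  for (i in seq_len(nrow(objectives))) {
    o <- objectives[i, ]
    mask <- structures$masks[[o$structure]]
    if (o$kind == "target-max" && o$structure %in% rx_tab$structure) {
      # a lower-prescription CTV legitimately carries the higher level's
      # dose where the levels nest; cap only its exclusive volume
      own_rx <- rx_tab$dose_gy[rx_tab$structure == o$structure]
      for (hi in rx_tab$structure[rx_tab$dose_gy > own_rx])
        mask <- mask & !structures$masks[[hi]]
      if (!any(mask)) { terms[i] <- list(NULL); next }
    }
    mvox <- which(mask)
    rows_nom <- match(mvox, nom_idx)
    rows_nom <- rows_nom[!is.na(rows_nom)]
    if (length(rows_nom) == 0)
      stop(sprintf("structure '%s' has no voxels in the influence region", o$structure))
    mats <- list(nominal = infl_nominal[rows_nom, , drop = FALSE])
    if (isTRUE(o$robust) && length(infl_scenarios)) {
      rows_rob <- match(mvox, rob_idx)
      rows_rob <- rows_rob[!is.na(rows_rob)]
      mats$scenarios <- lapply(infl_scenarios, function(A)
        A[rows_rob, , drop = FALSE])
    }
    terms[[i]] <- list(o = o, mats = mats)
  }

  eval_all <- function(w) {
    total <- 0
    grad <- numeric(nspots)
    for (tm in terms) {
      if (is.null(tm)) next
      o <- tm$o
      if (isTRUE(o$robust) && !is.null(tm$mats$scenarios)) {
        cand <- tm$mats$scenarios
        if (cfg$include_nominal) cand <- c(cand, tm$mats["nominal"])
        D <- vapply(cand, function(A) as.numeric(A %*% w),
                    numeric(nrow(cand[[1]])))
        if (cfg$aggregation == "voxelwise") {
          # per-voxel worst dose: minimum over scenarios for coverage
          # terms, maximum for overdose terms; gradient flows to each
          # voxel's active scenario
          worst_fun <- if (o$kind == "target-min") which.min else which.max
          arg <- apply(D, 1, worst_fun)
          dworst <- D[cbind(seq_len(nrow(D)), arg)]
          p <- objective_penalty(o$kind, dworst, o$dose_gy, o$volume_pct)
          total <- total + o$weight * p$pen
          for (s in seq_along(cand)) {
            sel <- which(arg == s & p$grad != 0)
            if (length(sel) == 0) next
            grad <- grad + o$weight * as.numeric(
              Matrix::crossprod(cand[[s]][sel, , drop = FALSE], p$grad[sel]))
          }
        } else {
          pens <- vector("list", length(cand))
          for (s in seq_along(cand))
            pens[[s]] <- objective_penalty(o$kind, D[, s], o$dose_gy,
                                           o$volume_pct)
          pvals <- vapply(pens, `[[`, 0, "pen")
          if (cfg$aggregation == "worst") {
            s <- which.max(pvals)
            total <- total + o$weight * pvals[s]
            grad <- grad + o$weight *
              as.numeric(Matrix::crossprod(cand[[s]], pens[[s]]$grad))
          } else {
            for (s in seq_along(pens)) {
              total <- total + o$weight * pvals[s] / length(pens)
              grad <- grad + o$weight / length(pens) *
                as.numeric(Matrix::crossprod(cand[[s]], pens[[s]]$grad))
            }
          }
        }
      } else {
        d <- as.numeric(tm$mats$nominal %*% w)
        p <- objective_penalty(o$kind, d, o$dose_gy, o$volume_pct)
        total <- total + o$weight * p$pen
        grad <- grad + o$weight *
          as.numeric(Matrix::crossprod(tm$mats$nominal, p$grad))
      }
    }
    list(total = total, grad = grad)
  }

  # uniform start: mean dose over all target voxels ~ primary prescription
  rx1 <- structures$prescriptions$dose_gy[1]
  t1 <- terms[[1]]
  mean_dose_unit <- mean(as.numeric(t1$mats$nominal %*% rep(1, nspots)))
  w <- rep(if (mean_dose_unit > 0) rx1 / mean_dose_unit else 1, nspots)

  st <- eval_all(w)
  trace <- st$total
  step <- max(w) / 4
  stall <- 0L
  for (it in seq_len(cfg$max_iter)) {
    g <- st$grad
    gmax <- max(abs(g))
    if (gmax == 0 || !is.finite(st$total)) break
    step <- max(step, max(w) / 1e4)
    scale <- step / gmax
    accepted <- FALSE
    for (try in 1:12) {
      w2 <- pmax(w - scale * g, 0)
      st2 <- eval_all(w2)
      if (st2$total < st$total) { accepted <- TRUE; break }
      scale <- scale / 2
    }
    if (!accepted) break
    rel <- (st$total - st2$total) / max(st$total, 1e-300)
    w <- w2; st <- st2
    step <- scale * gmax * 1.5
    trace <- c(trace, st$total)
    stall <- if (rel < cfg$tol) stall + 1L else 0L
    if (stall >= 5L) break
  }
  if (!is.finite(st$total)) stop("objective became non-finite during optimization")
  list(weights = w, trace = trace, objective = st$total)
}

#' Plan-normalization scale factor
#'
#' Returns the factor `s` such that after scaling all spot weights by `s`,
#' 95% of the primary CTV volume receives at least the prescription
#' (V100 = 95%). Convention: with `N` CTV voxels sorted by dose, `s = rx /
#' d_(k)` with `k = floor(0.05 N) + 1`, so voxels `k..N` reach the
#' prescription — ties break toward V100 >= 95%.
#'
#' @param ctv_dose nominal dose values (Gy) of the primary CTV voxels.
#' @param rx prescription dose (Gy).
#' @return scale factor `s` > 0.
#' @export
normalize_factor <- function(ctv_dose, rx) {
  if (length(ctv_dose) == 0 || max(ctv_dose) <= 0)
    stop("cannot normalize: no dose in the primary CTV")
  k <- floor(0.05 * length(ctv_dose)) + 1L
  dk <- sort(ctv_dose, partial = k)[k]
  if (dk <= 0) stop("cannot normalize: 5th-percentile CTV dose is zero")
  rx / dk
}

#' Worst-case robust evaluation of CTV coverage
#'
#' Computes V95 (percent of structure volume at or above 95% of its
#' prescription) for every CTV under every scenario dose, and reports the
#' worst case.
#'
#' @param scenario_doses named-by-structure list: each element a matrix
#'   (voxels x scenarios) of doses, or a list of per-scenario dose vectors.
#' @param prescriptions data.frame with `structure`, `dose_gy`.
#' @param threshold pass threshold on V95, default 95 (%).
#' @return list with `table` (structure x scenario V95), `worst` (named
#'   minima) and `pass`.
#' @export
robust_evaluate <- function(scenario_doses, prescriptions, threshold = 95) {
  out <- list()
  for (nm in names(scenario_doses)) {
    rx <- prescriptions$dose_gy[prescriptions$structure == nm]
    D <- scenario_doses[[nm]]
    if (is.list(D)) D <- do.call(cbind, D)
    v95 <- apply(D >= 0.95 * rx, 2, mean) * 100
    out[[nm]] <- v95
  }
  worst <- vapply(out, min, 0)
  list(table = out, worst = worst, pass = all(worst > threshold),
       threshold = threshold)
}

#' Planning configuration
#'
#' @param beams list of `beam`s; default two lateral opposed fields.
#' @param setup_mm,range_frac robustness magnitudes (3 mm / 3% default).
#' @param setup_margin_mm,range_margin_frac spot-placement margins (same
#'   defaults as the robustness set).
#' @param rbe RBE weighting factor, 1.1.
#' @param curve `rsp_curve`.
#' @param constraints OAR constraint table.
#' @param oar_fraction objective placement fraction of each constraint.
#' @param optimizer `optimizer_config`.
#' @param sigma0,sigma_slope,cutoff pencil-beam lateral model and sparsity
#'   cutoff (see [compute_influence()]).
#' @param use_avoidance exclude spots entering through the chin/teeth
#'   avoidance region when the structure set carries one.
#' @param edge_mm lateral penumbra ring allowance for spot placement (see
#'   [place_spots()]).
#' @return A `plan_config`.
#' @export
plan_config <- function(beams = default_beams(), setup_mm = 3,
                        range_frac = 0.03, setup_margin_mm = 3,
                        range_margin_frac = 0.03, rbe = 1.1,
                        curve = default_rsp_curve(),
                        constraints = default_constraints(),
                        oar_fraction = 0.9,
                        optimizer = optimizer_config(),
                        sigma0 = 3, sigma_slope = 0.03, cutoff = 1e-4,
                        use_avoidance = TRUE, edge_mm = 4) {
  structure(list(beams = beams, setup_mm = setup_mm, range_frac = range_frac,
                 setup_margin_mm = setup_margin_mm,
                 range_margin_frac = range_margin_frac, rbe = rbe,
                 curve = curve, constraints = constraints,
                 oar_fraction = oar_fraction, optimizer = optimizer,
                 sigma0 = sigma0, sigma_slope = sigma_slope, cutoff = cutoff,
                 use_avoidance = isTRUE(use_avoidance), edge_mm = edge_mm),
            class = "plan_config")
}

# region over which dose is computed and reported: the body if present,
# otherwise everything above -300 HU
dose_region <- function(ct, structures) {
  if ("body" %in% names(structures$masks)) structures$masks$body
  else ct$values > -300
}

#' Generate a robustly optimized IMPT plan on an image
#'
#' Full planning pass: spot placement in the field-specific targets,
#' rule-based objective generation, robust spot-weight optimization over the
#' scenario set, and V100 = 95% normalization of the primary CTV.
#'
#' @param ct `voxel_image` (HU) to plan on.
#' @param structures `structure_set` with prescriptions.
#' @param cfg `plan_config`.
#' @return An `impt_plan`: spots, weights (normalized), normalization
#'   factor, nominal dose (`voxel_image`, Gy, RBE-weighted), per-scenario
#'   CTV doses, robust evaluation and the objective trace.
#' @export
plan_on_image <- function(ct, structures, cfg = plan_config()) {
  avoid <- if (cfg$use_avoidance) structures$masks[["chin_avoidance"]] else NULL
  placed <- place_spots_all(structures, cfg$beams, ct, cfg$curve,
                            cfg$setup_margin_mm, cfg$range_margin_frac,
                            avoid, cfg$edge_mm)
  spots <- placed$spots
  region <- dose_region(ct, structures)
  ctv_names <- structures$prescriptions$structure
  robust_region <- Reduce(`|`, structures$masks[ctv_names])

  scen <- enumerate_scenarios(cfg$setup_mm, cfg$range_frac)
  infl_nom <- compute_influence(ct, cfg$beams, spots, region, cfg$curve,
                                scen$nominal, cfg$rbe, cfg$sigma0,
                                cfg$sigma_slope, cfg$cutoff)
  infl_scen <- lapply(scen$scenarios, function(s)
    compute_influence(ct, cfg$beams, spots, robust_region, cfg$curve, s,
                      cfg$rbe, cfg$sigma0, cfg$sigma_slope, cfg$cutoff))

  objectives <- generate_objectives(structures, cfg$constraints,
                                    cfg$oar_fraction)
  opt <- optimize_weights(infl_nom, infl_scen, objectives, structures,
                          cfg$optimizer)

  # normalization on the nominal dose
  nom_idx <- attr(infl_nom, "region_idx")
  ctv1 <- which(structures$masks[[ctv_names[1]]])
  rows1 <- match(ctv1, nom_idx); rows1 <- rows1[!is.na(rows1)]
  d_ctv1 <- as.numeric(infl_nom[rows1, , drop = FALSE] %*% opt$weights)
  s <- normalize_factor(d_ctv1, structures$prescriptions$dose_gy[1])
  w <- opt$weights * s

  dose <- dose_from_influence(infl_nom, w, dim(ct$values), ct$spacing,
                              ct$origin)
  rob_idx <- attr(infl_scen[[1]], "region_idx")
  scenario_doses <- lapply(ctv_names, function(nm) {
    mvox <- which(structures$masks[[nm]])
    rows <- match(mvox, rob_idx); rows <- rows[!is.na(rows)]
    cols <- c(lapply(infl_scen, function(A)
      as.numeric(A[rows, , drop = FALSE] %*% w)),
      list(as.numeric(infl_nom[match(mvox, nom_idx), , drop = FALSE] %*% w)))
    do.call(cbind, cols)
  })
  names(scenario_doses) <- ctv_names
  robust <- robust_evaluate(scenario_doses, structures$prescriptions)

  structure(list(spots = spots, weights = w, normalization = s,
                 beams = cfg$beams, scenario_set = scen,
                 prescriptions = structures$prescriptions,
                 dose = dose, scenario_ctv_doses = scenario_doses,
                 robust = robust, objectives = objectives,
                 trace = opt$trace, config = cfg),
            class = "impt_plan")
}

#' @export
print.impt_plan <- function(x, ...) {
  cat(sprintf("<impt_plan> %d spots, %d beams, normalization %.4f\n",
              nrow(x$spots), length(x$beams), x$normalization))
  cat(sprintf("  worst-case CTV V95: %s\n",
              paste(sprintf("%s %.1f%%", names(x$robust$worst),
                            x$robust$worst), collapse = ", ")))
  invisible(x)
}

#' Recalculate an existing plan's dose on another image
#'
#' Keeps the spots and optimized weights fixed and recomputes the nominal
#' influence on the new image (e.g. a weekly synthetic CT).
#'
#' @param plan `impt_plan`.
#' @param ct `voxel_image` to recalculate on.
#' @param structures `structure_set` on the grid of `ct` (defines the dose
#'   region).
#' @return `voxel_image` (Gy).
#' @export
recalc_plan_dose <- function(plan, ct, structures) {
  cfg <- plan$config
  region <- dose_region(ct, structures)
  infl <- compute_influence(ct, plan$beams, plan$spots, region, cfg$curve,
                            plan$scenario_set$nominal, cfg$rbe, cfg$sigma0,
                            cfg$sigma_slope, cfg$cutoff)
  dose_from_influence(infl, plan$weights, dim(ct$values), ct$spacing,
                      ct$origin)
}

#' Re-optimize a plan on a weekly image (adaptation)
#'
#' A full planning pass on the weekly anatomy with the same robustness
#' parameters as the initial plan; no warm start from the initial weights
#' (documented choice — adaptation and initial planning use the identical
#' automated pass).
#'
#' @param weekly_ct weekly synthetic CT (`voxel_image`).
#' @param weekly_structures `structure_set` on the weekly grid.
#' @param cfg `plan_config` (the initial plan's configuration).
#' @return An `impt_plan`.
#' @export
adapt_plan <- function(weekly_ct, weekly_structures, cfg = plan_config()) {
  if (!any(vapply(weekly_structures$masks[weekly_structures$prescriptions$structure],
                  any, logical(1))))
    stop("weekly structures contain no CTV voxels; cannot adapt")
  plan_on_image(weekly_ct, weekly_structures, cfg)
}

#' Serialize a plan (spots, weights, scenarios, normalization) to JSON
#' @param plan `impt_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    spots = plan$spots, weights = plan$weights,
    normalization = plan$normalization,
    beams = lapply(plan$beams, unclass),
    scenarios = plan$scenario_set,
    prescriptions = plan$prescriptions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
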