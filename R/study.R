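#' Default phantom cohort spanning the study's anatomy-change phenotypes
#'
#' Six phantoms: static anatomy, weight loss, tumour growth, tumour
#' shrinkage, combined change, and a weight-loss phantom whose tertiary CTV
#' extends inferiorly beyond a reduced CBCT field of view.
#'
#' @param spacing,dims grid geometry passed to every [phantom_spec()].
#' @param master_seed integer; per-phantom seeds are derived as
#'   `master_seed + 101 * i`.
#' @param which optional subset of the cohort names.
#' @return named list of `phantom_spec`s.
#' @export
default_phantom_cohort <- function(spacing = c(2, 2, 2), dims = c(96, 96, 64),
                                   master_seed = 1,
                                   which = NULL) {
  defs <- list(
    static       = list(weekly_body_shrink = 0,     weekly_tumor_change = 0),
    weight_loss  = list(weekly_body_shrink = 0.02,  weekly_tumor_change = 0),
    tumor_growth = list(weekly_body_shrink = 0,     weekly_tumor_change = 0.03),
    tumor_shrink = list(weekly_body_shrink = 0,     weekly_tumor_change = -0.03),
    combined     = list(weekly_body_shrink = 0.015, weekly_tumor_change = 0.02),
    fov_truncated = list(weekly_body_shrink = 0.015, weekly_tumor_change = 0,
                         tertiary_inferior_extension = TRUE,
                         fov_fraction = 0.7))
  if (!is.null(which)) defs <- defs[which]
  out <- lapply(seq_along(defs), function(i) {
    args <- c(defs[[i]], list(spacing = spacing, dims = dims,
                              seed = as.integer(master_seed + 101L * i)))
    do.call(phantom_spec, args)
  })
  names(out) <- names(defs)
  out
}

#' Configuration of a phantom study
#'
#' @param phantoms named list of `phantom_spec`s (see
#'   [default_phantom_cohort()]).
#' @param weeks number of weekly CBCT samples (fractions 1, 6, 11, ... of
#'   the course).
#' @param registration `registration_config`.
#' @param plan `plan_config`.
#' @param inversion `inversion_config` for dose accumulation.
#' @param gamma_criteria list of `c(dd_pct, dta_mm)` pairs evaluated in the
#'   validation study.
#' @param ntcp named list of `ntcp_params`.
#' @param use_registration register pCT to each weekly CBCT (the full
#'   workflow); FALSE substitutes the ground-truth deformation fields,
#'   exercising the planning/accumulation chain without registration cost.
#' @param out_dir optional directory for CSV/NIfTI outputs.
#' @param master_seed master seed recorded with the study.
#' @return A `study_config`.
#' @export
study_config <- function(phantoms = default_phantom_cohort(),
                         weeks = 3,
                         registration = registration_config(),
                         plan = plan_config(),
                         inversion = inversion_config(),
                         gamma_criteria = list(c(3, 3), c(2, 2)),
                         ntcp = default_ntcp_params(),
                         use_registration = TRUE,
                         out_dir = NULL,
                         master_seed = 1) {
  if (length(phantoms) < 1) stop("cohort must contain at least one phantom")
  if (weeks < 1) stop("need at least one weekly sample")
  structure(list(phantoms = phantoms, weeks = weeks,
                 registration = registration, plan = plan,
                 inversion = inversion, gamma_criteria = gamma_criteria,
                 ntcp = ntcp, use_registration = isTRUE(use_registration),
                 out_dir = out_dir, master_seed = master_seed),
            class = "study_config")
}

# stage-granular logging (phantom/week/stage with wall time), enabled via
# options(aptkit.verbose = TRUE)
log_stage <- function(fmt, ..., t0 = NULL) {
  if (!isTRUE(getOption("aptkit.verbose"))) return(invisible())
  msg <- sprintf(fmt, ...)
  if (!is.null(t0))
    msg <- sprintf("%s [%.1f s]", msg, (proc.time() - t0)[["elapsed"]])
  message(msg)
}

# weekly imaging chain shared by both studies: ground-truth anatomy, CBCT,
# DVF (registered or ground truth), synthetic CT and contour sets
weekly_chain <- function(spec, week, planning, cfg) {
  gt <- sample_weekly_anatomy(spec, week, planning)
  cb <- simulate_cbct(gt$ct, spec, week)
  dvf <- if (cfg$use_registration)
    deformable_register(cb$cbct, planning$ct, cfg$registration, fov = cb$fov)
  else gt$dvf
  sct <- build_sct(planning$ct, dvf, cb$fov,
                   planning$structures$masks[["artifact"]], 40)
  uncorr <- propagate_contours(planning$structures, dvf)
  list(gt = gt, cbct = cb$cbct, fov = cb$fov, dvf = dvf, sct = sct,
       uncorrected = uncorr)
}

rel_pct <- function(a, b, ref) 100 * (a - b) / ref

# dose-volume index rows for one dose/contour pairing
index_rows <- function(dose, structures, rx_tab, label) {
  out <- list()
  for (nm in names(structures$masks)) {
    if (nm %in% c("body", "artifact", "chin_avoidance")) next
    m <- structures$masks[[nm]]
    if (!any(m)) next
    rx <- rx_tab$dose_gy[rx_tab$structure == nm]
    di <- dose_indices(dose, m, if (length(rx)) rx else NA, vx_gy = 20)
    for (ix in names(di))
      out[[length(out) + 1L]] <- data.frame(
        arm = label, structure = nm, index = ix, value = di[[ix]])
  }
  do.call(rbind, out)
}

#' Run the synthetic-CT dose-validation study
#'
#' Per phantom and week: simulate the CBCT, register (or use the
#' ground-truth field), build the synthetic CT and the deformed repeat CT
#' (the gold standard), recalculate the initial IMPT plan on pCT, sCT and
#' rCT_def, compare the sCT dose against the gold standard by 3D global
#' gamma at each configured criterion, score contour propagation by Dice
#' against the gold-standard contours, and tabulate dose-volume index
#' deviations for the three comparisons (gold minus pCT, gold minus sCT
#' with uncorrected contours, gold minus sCT with corrected contours).
#'
#' @param cfg `study_config`.
#' @return list of data.frames: `gamma`, `dsc`, `index_dev`; written as CSV
#'   under `cfg$out_dir` when set.
#' @export
run_validation_study <- function(cfg) {
  gamma_rows <- list(); dsc_rows <- list(); dev_rows <- list()
  for (pname in names(cfg$phantoms)) {
    spec <- cfg$phantoms[[pname]]
    t0 <- proc.time()
    planning <- build_planning_phantom(spec)
    plan <- plan_on_image(planning$ct, planning$structures, cfg$plan)
    log_stage("validation %s: initial plan", pname, t0 = t0)
    rx_tab <- planning$structures$prescriptions
    rx1 <- rx_tab$dose_gy[1]
    for (w in seq_len(cfg$weeks)) {
      t0 <- proc.time()
      ch <- weekly_chain(spec, w, planning, cfg)
      # repeat CT: the noise-free deformed CT of the same day; its deformed
      # version is built through the same registration path
      rct_def <- if (cfg$use_registration)
        build_rct_def(ch$gt$ct, ch$cbct, cfg$registration, fov = ch$fov)
      else ch$gt$ct
      gold <- ch$gt$structures

      dose_sct <- recalc_plan_dose(plan, ch$sct, gold)
      dose_gold <- recalc_plan_dose(plan, rct_def, gold)

      for (crit in cfg$gamma_criteria) {
        g <- gamma_3d(dose_gold, dose_sct,
                      gamma_config(crit[1], crit[2], norm_gy = rx1))
        gamma_rows[[length(gamma_rows) + 1L]] <- data.frame(
          phantom = pname, week = w,
          criterion = sprintf("%g%%/%gmm", crit[1], crit[2]),
          pass_rate = g$pass_rate, n_analyzed = g$n_analyzed)
      }
      for (nm in names(gold$masks)) {
        if (nm %in% c("artifact", "chin_avoidance")) next
        dsc_rows[[length(dsc_rows) + 1L]] <- data.frame(
          phantom = pname, week = w, structure = nm,
          dsc = dice(ch$uncorrected$masks[[nm]], gold$masks[[nm]]),
          voxels = sum(gold$masks[[nm]]))
      }
      rows <- rbind(
        cbind(index_rows(plan$dose, planning$structures, rx_tab, "pCT")),
        cbind(index_rows(dose_sct, ch$uncorrected, rx_tab, "sCT_uncorr")),
        cbind(index_rows(dose_sct, gold, rx_tab, "sCT")),
        cbind(index_rows(dose_gold, gold, rx_tab, "rCT_def")))
      gold_rows <- rows[rows$arm == "rCT_def", ]
      for (arm in c("pCT", "sCT_uncorr", "sCT")) {
        a <- rows[rows$arm == arm, ]
        mg <- merge(gold_rows, a, by = c("structure", "index"),
                    suffixes = c("_gold", ""))
        dev_rows[[length(dev_rows) + 1L]] <- data.frame(
          phantom = pname, week = w, comparison = paste0("rCT_def-", arm),
          structure = mg$structure, index = mg$index,
          gold = mg$value_gold, value = mg$value,
          delta = mg$value_gold - mg$value)
      }
      log_stage("validation %s week %d: sCT/gamma/DSC", pname, w, t0 = t0)
    }
  }
  out <- list(gamma = do.call(rbind, gamma_rows),
              dsc = do.call(rbind, dsc_rows),
              index_dev = do.call(rbind, dev_rows))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]],
                       file.path(cfg$out_dir, paste0("validation_", nm, ".csv")),
                       row.names = FALSE)
  }
  out
}

#' Run the adaptation-versus-non-adaptation study
#'
#' Per phantom: plan on the planning CT; for each weekly synthetic CT,
#' recalculate the initial plan (non-adapt arm) and fully re-optimize with
#' the same robustness parameters (adapt arm); accumulate both arms on the
#' planning CT through the inverse DVFs (fraction-weighted average of the
#' weekly full-course doses); evaluate weekly CTV V95 tracks, accumulated
#' dose-volume indices, NTCP per endpoint and paired t-tests across the
#' cohort.
#'
#' @param cfg `study_config`.
#' @return list of data.frames: `weekly_v95`, `accumulated`, `ntcp`,
#'   `tests`; written as CSV under `cfg$out_dir` when set.
#' @export
run_adaptation_study <- function(cfg) {
  v95_rows <- list(); acc_rows <- list(); ntcp_rows <- list()
  for (pname in names(cfg$phantoms)) {
    spec <- cfg$phantoms[[pname]]
    t0 <- proc.time()
    planning <- build_planning_phantom(spec)
    plan <- plan_on_image(planning$ct, planning$structures, cfg$plan)
    log_stage("adaptation %s: initial plan", pname, t0 = t0)
    rx_tab <- planning$structures$prescriptions
    course_fx <- rx_tab$fractions[1]

    doses_na <- list(); doses_ad <- list(); invs <- list()
    for (w in seq_len(cfg$weeks)) {
      t0 <- proc.time()
      ch <- weekly_chain(spec, w, planning, cfg)
      gold <- ch$gt$structures
      dose_na <- recalc_plan_dose(plan, ch$sct, gold)
      plan_ad <- adapt_plan(ch$sct, gold, cfg$plan)
      dose_ad <- plan_ad$dose
      for (i in seq_len(nrow(rx_tab))) {
        nm <- rx_tab$structure[i]
        for (arm in c("non_adapt", "adapt")) {
          dv <- if (arm == "adapt") dose_ad else dose_na
          v95_rows[[length(v95_rows) + 1L]] <- data.frame(
            phantom = pname, week = w, structure = nm, arm = arm,
            v95 = dose_indices(dv, gold$masks[[nm]],
                               rx_tab$dose_gy[i])$V95)
        }
      }
      doses_na[[w]] <- dose_na
      doses_ad[[w]] <- dose_ad
      invs[[w]] <- if (w == 1 && max(abs(ch$dvf$disp)) == 0) ch$dvf
                   else invert_dvf(ch$dvf, cfg$inversion)
      log_stage("adaptation %s week %d: recalc + re-plan", pname, w, t0 = t0)
    }
    fx <- rep(course_fx / cfg$weeks, cfg$weeks)
    acc_na <- accumulate_dose(doses_na, invs, fx, course_fx)
    acc_ad <- accumulate_dose(doses_ad, invs, fx, course_fx)

    for (arm in c("plan", "non_adapt", "adapt")) {
      dv <- switch(arm, plan = plan$dose, non_adapt = acc_na, adapt = acc_ad)
      rows <- index_rows(dv, planning$structures, rx_tab, arm)
      rows$phantom <- pname
      acc_rows[[length(acc_rows) + 1L]] <- rows
      for (en in names(cfg$ntcp)) {
        p <- cfg$ntcp[[en]]
        if (!p$structure %in% names(planning$structures$masks)) next
        ntcp_rows[[length(ntcp_rows) + 1L]] <- data.frame(
          phantom = pname, arm = arm, endpoint = en,
          structure = p$structure,
          ntcp = 100 * ntcp_from_dose(dv, planning$structures$masks[[p$structure]], p))
      }
    }
  }
  weekly_v95 <- do.call(rbind, v95_rows)
  accumulated <- do.call(rbind, acc_rows)
  ntcp <- do.call(rbind, ntcp_rows)

  # paired tests across the cohort (adapt vs non-adapt)
  tests <- list()
  if (length(cfg$phantoms) >= 2) {
    key <- accumulated[accumulated$index == "Dmean", ]
    for (nm in unique(key$structure)) {
      a <- key[key$structure == nm & key$arm == "adapt", ]
      b <- key[key$structure == nm & key$arm == "non_adapt", ]
      m <- merge(a, b, by = "phantom", suffixes = c("_ad", "_na"))
      if (nrow(m) < 2) next
      tt <- paired_ttest(m$value_ad, m$value_na)
      tests[[length(tests) + 1L]] <- data.frame(
        quantity = paste0(nm, "_Dmean"), mean_diff = tt$mean_diff,
        p = tt$p, degenerate = tt$degenerate)
    }
    for (en in unique(ntcp$endpoint)) {
      a <- ntcp[ntcp$endpoint == en & ntcp$arm == "adapt", ]
      b <- ntcp[ntcp$endpoint == en & ntcp$arm == "non_adapt", ]
      m <- merge(a, b, by = "phantom", suffixes = c("_ad", "_na"))
      if (nrow(m) < 2) next
      tt <- paired_ttest(m$ntcp_ad, m$ntcp_na)
      tests[[length(tests) + 1L]] <- data.frame(
        quantity = paste0("NTCP_", en), mean_diff = tt$mean_diff,
        p = tt$p, degenerate = tt$degenerate)
    }
  }
  out <- list(weekly_v95 = weekly_v95, accumulated = accumulated,
              ntcp = ntcp,
              tests = if (length(tests)) do.call(rbind, tests) else NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) if (!is.null(out[[nm]]))
      utils::write.csv(out[[nm]],
                       file.path(cfg$out_dir, paste0("adaptation_", nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
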