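# Shared fixtures, built once per test session. All phantoms are generated
# in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small 4 mm phantom grid used by most unit tests
small_spec <- function(...) {
  phantom_spec(spacing = c(4, 4, 4), dims = c(48, 48, 32), seed = 11, ...)
}

small_phantom <- function() {
  fixture("small_phantom", function() build_planning_phantom(small_spec()))
}

# deforming variant: weight loss + tumour growth
deforming_spec <- function() {
  small_spec(weekly_body_shrink = 0.02, weekly_tumor_change = 0.03)
}

deforming_week3 <- function() {
  fixture("deforming_week3", function() {
    spec <- deforming_spec()
    planning <- build_planning_phantom(spec)
    wk <- sample_weekly_anatomy(spec, 3, planning)
    cb <- simulate_cbct(wk$ct, spec, 3)
    list(spec = spec, planning = planning, week = wk, cbct = cb$cbct,
         fov = cb$fov)
  })
}

# registration of the week-3 CBCT (shared by registration and sCT tests)
week3_registration <- function() {
  fixture("week3_registration", function() {
    fx <- deforming_week3()
    cfg <- registration_config(levels = 2, cp_spacing = c(24, 12),
                               max_iter = c(40, 30))
    deformable_register(fx$cbct, fx$planning$ct, cfg, fov = fx$fov)
  })
}

# a fast planning configuration for the small grid
fast_plan_config <- function(...) {
  plan_config(optimizer = optimizer_config(max_iter = 100), ...)
}

small_plan <- function() {
  fixture("small_plan", function() {
    ph <- small_phantom()
    plan_on_image(ph$ct, ph$structures, fast_plan_config())
  })
}

# reduced adaptation cohort: three anatomy-change phantoms, three weekly
# synthetic CTs each, 4 mm grid, ground-truth deformations
adaptation_cohort_result <- function() {
  fixture("adaptation_cohort", function() {
    ph <- default_phantom_cohort(spacing = c(4, 4, 4), dims = c(48, 48, 32),
                                 master_seed = 5,
                                 which = c("weight_loss", "tumor_growth",
                                           "combined"))
    cfg <- study_config(phantoms = ph, weeks = 3, use_registration = FALSE,
                        plan = fast_plan_config(), master_seed = 5)
    run_adaptation_study(cfg)
  })
}

# small validation run through the full registration path
validation_result <- function() {
  fixture("validation_small", function() {
    ph <- default_phantom_cohort(spacing = c(4, 4, 4), dims = c(48, 48, 32),
                                 master_seed = 5,
                                 which = c("static", "weight_loss"))
    cfg <- study_config(
      phantoms = ph, weeks = 2, use_registration = TRUE,
      registration = registration_config(levels = 2, cp_spacing = c(24, 12),
                                         max_iter = c(40, 30)),
      plan = fast_plan_config(), master_seed = 5)
    run_validation_study(cfg)
  })
}

# static-anatomy adaptation run (null control)
static_adaptation_result <- function() {
  fixture("static_adaptation", function() {
    ph <- default_phantom_cohort(spacing = c(4, 4, 4), dims = c(48, 48, 32),
                                 master_seed = 5, which = "static")
    cfg <- study_config(phantoms = ph, weeks = 2, use_registration = FALSE,
                        plan = fast_plan_config(), master_seed = 5)
    run_adaptation_study(cfg)
  })
}

# water-box CT for dose-engine tests (0 HU = water)
water_box <- function(dims = c(60, 40, 20), spacing = c(2, 2, 2)) {
  voxel_image(array(0, dims), spacing, kind = "hu")
}

constant_field <- function(img, t) {
  d <- dim(img$values)
  disp <- array(0, c(d, 3))
  for (k in 1:3) disp[, , , k] <- t[k]
  vector_field(disp, img$spacing, img$origin)
}
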