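test_that("dose-volume indices follow their conventions", {
  m <- array(TRUE, c(4, 4, 4))
  uniform <- voxel_image(array(60, c(4, 4, 4)), c(2, 2, 2), kind = "dose")
  di <- dose_indices(uniform, m, rx = 60)
  expect_equal(di$V100, 100)
  expect_equal(di$V95, 100)
  expect_equal(di$Dmean, 60)
  expect_equal(di$Dmax, 60)

  # half at 2x Gy, half at 0 -> VxGy = 50%
  v <- array(0, c(4, 4, 4)); v[1:2, , ] <- 40
  half <- voxel_image(v, c(2, 2, 2), kind = "dose")
  expect_equal(dose_indices(half, m, vx_gy = 20)$V20Gy, 50)
  expect_error(dose_indices(half, array(FALSE, c(4, 4, 4))), "empty mask")

  # normalization example carried to the index: V100 = 95% after scaling
  d <- seq(1.00, 1.99, by = 0.01)
  s <- normalize_factor(d, 1.50)
  arr <- array(d * s, c(100, 1, 1))
  di2 <- dose_indices(voxel_image(arr, c(1, 1, 1), kind = "dose"),
                      array(TRUE, c(100, 1, 1)), rx = 1.50)
  expect_equal(di2$V100, 95)
})

test_that("DVH curves are monotone non-increasing from 1 to 0", {
  plan <- small_plan()
  ph <- small_phantom()
  dvh <- dvh_curve(plan$dose, ph$structures$masks$CTV_primary)
  expect_equal(dvh$volume_frac[1], 1)
  expect_equal(dvh$volume_frac[nrow(dvh)], 0)
  expect_true(all(diff(dvh$volume_frac) <= 0))
})

test_that("gamma of an image against itself is zero and passes everywhere", {
  d <- c(16, 14, 8)
  v <- array(0, d)
  for (i in 1:d[1]) v[i, , ] <- 50 * exp(-((i - 8) / 5)^2) + 5
  ref <- voxel_image(v, c(2, 2, 2), kind = "dose")
  for (crit in list(c(3, 3), c(2, 2), c(1, 1))) {
    g <- gamma_3d(ref, ref, gamma_config(crit[1], crit[2], norm_gy = 55))
    expect_equal(g$pass_rate, 100)
    expect_equal(max(g$gamma$values, na.rm = TRUE), 0)
  }
})

test_that("a uniform offset of exactly the dose criterion gives gamma 1", {
  d <- c(10, 10, 6)
  ref <- voxel_image(array(30, d), c(2, 2, 2), kind = "dose")
  ev <- voxel_image(array(30 + 0.03 * 60, d), c(2, 2, 2), kind = "dose")
  g <- gamma_3d(ref, ev, gamma_config(3, 3, norm_gy = 60))
  expect_equal(unique(round(g$gamma$values[!is.na(g$gamma$values)], 9)), 1)
  expect_equal(g$pass_rate, 100)
})

test_that("gamma equals an exhaustive brute-force search on a 1D profile", {
  n <- 20
  refv <- array(0, c(n, 1, 1)); refv[, 1, 1] <- 30 + 20 * sin((1:n) / 3)
  evv <- refv; evv[, 1, 1] <- 30 + 20 * sin(((1:n) + 0.8) / 3) + 0.5
  r1 <- voxel_image(refv, c(2, 2, 2), kind = "dose")
  e1 <- voxel_image(evv, c(2, 2, 2), kind = "dose")
  cfg <- gamma_config(2, 2, norm_gy = 50, search_mult = 1.5, step_frac = 0.1)
  g <- gamma_3d(r1, e1, cfg)

  x <- (0:(n - 1)) * 2
  evalf <- stats::approxfun(x, evv[, 1, 1])
  ns <- floor(1.5 * 2 / 0.2)
  bf <- vapply(which(refv[, 1, 1] > 0.1 * 50), function(i) {
    off <- seq(-ns, ns) * 0.2
    xs <- x[i] + off
    ok <- xs >= 0 & xs <= max(x)
    min(sqrt((off[ok] / 2)^2 +
             ((evalf(xs[ok]) - refv[i, 1, 1]) / (0.02 * 50))^2))
  }, 0)
  got <- g$gamma$values[!is.na(g$gamma$values)]
  expect_lt(max(abs(got - bf)), 1e-3)
})

test_that("gamma pass rate is invariant to translating both images together", {
  d <- c(16, 14, 8)
  v <- array(0, d)
  for (i in 1:d[1]) v[i, , ] <- 40 * exp(-((i - 8) / 4)^2) + 6
  set.seed(5)
  e <- v + array(rnorm(prod(d), 0, 1.2), d)
  e[e < 0] <- 0
  ref1 <- voxel_image(v, c(2, 2, 2), kind = "dose")
  ev1 <- voxel_image(e, c(2, 2, 2), kind = "dose")
  # same arrays shifted by two voxels along y
  v2 <- array(0, d); v2[, 3:14, ] <- v[, 1:12, ]
  e2 <- array(0, d); e2[, 3:14, ] <- e[, 1:12, ]
  ref2 <- voxel_image(v2, c(2, 2, 2), kind = "dose")
  ev2 <- voxel_image(e2, c(2, 2, 2), kind = "dose")
  cfg <- gamma_config(3, 3, norm_gy = 46)
  g1 <- gamma_3d(ref1, ev1, cfg)
  g2 <- gamma_3d(ref2, ev2, cfg)
  # voxels whose search region is clipped by the grid edge differ; compare
  # the common interior
  expect_equal(g2$gamma$values[, 5:12, 3:6], g1$gamma$values[, 3:10, 3:6],
               tolerance = 1e-12)
})

test_that("pass rates do not increase when the criteria tighten", {
  fx <- deforming_week3()
  dvf <- week3_registration()
  plan <- fixture("plan_deforming", function()
    plan_on_image(fx$planning$ct, fx$planning$structures, fast_plan_config()))
  sct <- build_sct(fx$planning$ct, dvf, fx$fov,
                   fx$planning$structures$masks$artifact, 40)
  d_sct <- recalc_plan_dose(plan, sct, fx$week$structures)
  d_ref <- recalc_plan_dose(plan, fx$week$ct, fx$week$structures)
  g33 <- gamma_3d(d_ref, d_sct, gamma_config(3, 3, norm_gy = 70))
  g22 <- gamma_3d(d_ref, d_sct, gamma_config(2, 2, norm_gy = 70))
  expect_gte(g33$pass_rate, g22$pass_rate)
  expect_gt(g33$pass_rate, 90)
})

test_that("constraint auditing uses strict inequalities", {
  idx <- data.frame(structure = c("spinal_cord", "parotid_ips", "larynx"),
                    metric = c("Dmax", "V20Gy", "Dmean"),
                    value = c(47, 50, 49.99))
  rep <- check_constraints(idx, rx_primary = 70)
  expect_true(rep$pass[rep$structure == "spinal_cord"])    # 47 < 48
  expect_false(rep$pass[rep$structure == "parotid_ips"])   # 50 < 50 fails
  expect_true(rep$pass[rep$structure == "larynx"])
  empty <- check_constraints(idx[0, ], rx_primary = 70)
  expect_equal(nrow(empty), 0)
})

test_that("dose accumulation is a fraction-weighted convex combination", {
  ph <- small_phantom()
  d <- dim(ph$ct$values)
  base <- array(10, d)
  dose <- voxel_image(base, ph$ct$spacing, ph$ct$origin, kind = "dose")
  ident <- zero_field(ph$ct)
  acc <- accumulate_dose(list(dose, dose, dose), list(ident, ident, ident),
                         fractions = rep(10, 3), course_fractions = 30)
  expect_equal(acc$values, base)

  # 30-fraction course sampled by 6 weeks -> each weight 5/30
  expect_equal(rep(30 / 6, 6) / 30, rep(5 / 30, 6))

  # mask means stay inside the envelope of the weekly warped means
  dose2 <- voxel_image(base * 2, ph$ct$spacing, ph$ct$origin, kind = "dose")
  acc2 <- accumulate_dose(list(dose, dose2), list(ident, ident),
                          fractions = c(15, 15), course_fractions = 30)
  m <- ph$structures$masks$CTV_primary
  mm <- mean(acc2$values[m])
  expect_gte(mm, mean(dose$values[m]))
  expect_lte(mm, mean(dose2$values[m]))
  expect_error(accumulate_dose(list(dose), list(ident), fractions = 10,
                               course_fractions = 30), "course total")
})

test_that("gEUD reduces to the mean at n = 1 and matches direct arithmetic", {
  expect_equal(geud(rep(40, 100), 0.7), 40)          # homogeneity
  expect_equal(geud(c(20, 40), 1), 30)               # mean dose
  expect_equal(geud(c(20, 40), 0.25),
               (0.5 * 20^4 + 0.5 * 40^4)^0.25)       # 34.1495 Gy
  d <- c(10, 25, 60, 70)
  for (n in c(0.2, 0.5, 1, 2)) {
    g <- geud(d, n)
    expect_gte(g, min(d)); expect_lte(g, max(d))
  }
  # approaches Dmax as n -> 0
  expect_equal(geud(d, 0.01), max(d), tolerance = 0.05)
  expect_error(geud(d, 0), "n must be")
})

test_that("LKB NTCP matches the normal-CDF closed form and is monotone", {
  p <- ntcp_params("test", "larynx", n = 1, m = 0.2, td50 = 50)
  expect_equal(lkb_ntcp(50, p), 0.5)
  expect_equal(lkb_ntcp(1e-12, p), pnorm(-5), tolerance = 1e-10)
  ge <- seq(5, 95, by = 5)
  vals <- lkb_ntcp(ge, p)
  expect_true(all(diff(vals) > 0))
  # decreasing in TD50
  p2 <- ntcp_params("test", "larynx", n = 1, m = 0.2, td50 = 60)
  expect_lt(lkb_ntcp(50, p2), lkb_ntcp(50, p))
})

test_that("paired t-test matches the hand computation and handles degeneracy", {
  x <- c(5, 7, 9); y <- x - c(1, 2, 3)
  tt <- paired_ttest(x, y)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(tt$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  # antisymmetry
  ts <- paired_ttest(y, x)
  expect_equal(ts$mean_diff, -tt$mean_diff)
  expect_equal(ts$p, tt$p)
  # degenerate variance
  td <- paired_ttest(1:5, 1:5)
  expect_true(td$degenerate)
  expect_equal(td$p, 1)
})

test_that("NTCP parameter tables round-trip through YAML", {
  params <- default_ntcp_params()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_ntcp_params(params, tf)
  back <- read_ntcp_params(tf)
  expect_equal(lapply(back, unclass), lapply(params, unclass))
})
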