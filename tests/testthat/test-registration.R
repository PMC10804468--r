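test_that("self-registration yields a near-zero field", {
  ph <- small_phantom()
  cfg <- registration_config(levels = 2, cp_spacing = c(32, 16),
                             max_iter = c(15, 10))
  dvf <- deformable_register(ph$ct, ph$ct, cfg)
  expect_lt(max(abs(dvf$disp)), 0.25 * min(ph$ct$spacing))
})

test_that("a known 6 mm translation is recovered to sub-millimetre mean error", {
  ph <- small_phantom()
  mv <- warp_image(ph$ct, constant_field(ph$ct, c(0, 6, 0)))
  cfg <- registration_config(levels = 2, cp_spacing = c(32, 16),
                             max_iter = c(40, 25))
  dvf <- deformable_register(ph$ct, mv, cfg)
  body <- as.vector(ph$structures$masks$body)
  mu <- colMeans(matrix(dvf$disp, ncol = 3)[body, ])
  # pull-back convention: moving = fixed pulled by +6 -> recovered field -6
  expect_lt(abs(mu[2] - (-6)), 1)
  expect_lt(abs(mu[1]), 1)
  expect_lt(abs(mu[3]), 1)
})

test_that("week-3 CBCT registration aligns the body to the ground truth", {
  fx <- deforming_week3()
  dvf <- week3_registration()
  warped_body <- warp_mask(fx$planning$structures$masks$body, dvf,
                           fx$planning$structures)
  d <- dice(warped_body & fx$fov, fx$week$structures$masks$body & fx$fov)
  expect_gte(d, 0.95)
  # and clearly improves on not registering at all
  base <- dice(fx$planning$structures$masks$body & fx$fov,
               fx$week$structures$masks$body & fx$fov)
  expect_gt(d, base)
})

test_that("objective trace is non-increasing at every pyramid level", {
  fx <- deforming_week3()
  dvf <- week3_registration()
  for (tr in attr(dvf, "trace")) expect_true(all(diff(tr) <= 1e-12))
})

test_that("registration rejects contrast-free inputs with a diagnostic", {
  flat <- voxel_image(array(0, c(8, 8, 8)), c(2, 2, 2))
  ph <- small_phantom()
  expect_error(deformable_register(flat, flat, registration_config(levels = 1,
               cp_spacing = 16, max_iter = 5)), "no contrast")
  expect_error(deformable_register(ph$ct, ph$ct,
               registration_config(levels = 1, cp_spacing = 16, max_iter = 2),
               fov = array(TRUE, c(2, 2, 2))), "fov")
})

test_that("registration config validates its invariants", {
  expect_error(registration_config(levels = 0), "levels")
  expect_error(registration_config(levels = 2, cp_spacing = c(8, 16)),
               "monotonically")
  expect_error(registration_config(smooth_weight = -1), "smooth_weight")
})

test_that("inverting the zero field gives the zero field", {
  ph <- small_phantom()
  inv <- invert_dvf(zero_field(ph$ct))
  expect_equal(max(abs(inv$disp)), 0)
})

test_that("the inverse of a constant translation is its negation", {
  ph <- small_phantom()
  dvf <- constant_field(ph$ct, c(3, -2, 1))
  inv <- invert_dvf(dvf, inversion_config(tol_mm = 0.01))
  # away from the grid edge the inverse is exactly -t
  interior <- array(FALSE, dim(ph$ct$values))
  interior[5:44, 5:44, 3:30] <- TRUE
  for (k in 1:3) {
    comp <- inv$disp[, , , k][interior]
    expect_lt(max(abs(comp - c(-3, 2, -1)[k])), 0.01)
  }
})

test_that("analytic weekly field inverts with small composition residual", {
  fx <- deforming_week3()
  inv <- invert_dvf(fx$week$dvf, inversion_config(tol_mm = 0.05))
  # residual |u(x + v(x)) + v(x)| evaluated by direct composition
  d <- dim(fx$week$dvf$disp)[1:3]
  pts <- aptkit:::grid_points(fx$week$dvf)
  v <- matrix(inv$disp, ncol = 3)
  q <- pts + v
  idx <- aptkit:::world_to_index(fx$week$dvf, q)
  u_at <- vapply(1:3, function(k)
    aptkit:::interp3(fx$week$dvf$disp[, , , k], idx, fill = NULL),
    numeric(nrow(pts)))
  res <- sqrt(rowSums((u_at + v)^2))
  expect_lt(max(res), 0.5)
})

test_that("non-invertible displacement fails with the worst residual reported", {
  ph <- small_phantom()
  d <- dim(ph$ct$values)
  set.seed(9)
  disp <- array(stats::rnorm(prod(d) * 3, 0, 15), c(d, 3))
  bad <- vector_field(disp, ph$ct$spacing, ph$ct$origin)
  expect_error(invert_dvf(bad, inversion_config(max_iter = 10, tol_mm = 0.1)),
               "residual")
})

test_that("warp round-trip through the numeric inverse is close to identity", {
  # smooth image: round-trip error then reflects only the field inverse,
  # not interpolation smearing at tissue edges
  fx <- deforming_week3()
  co <- aptkit:::phantom_coords(fx$spec)
  smooth <- voxel_image(
    500 + 400 * sin(co$x / 30) * cos(co$y / 25) + 3 * co$z,
    fx$spec$spacing, co$origin, kind = "hu")
  inv <- invert_dvf(fx$week$dvf, inversion_config(tol_mm = 0.05))
  fwd <- warp_image(smooth, fx$week$dvf)
  back <- warp_image(fwd, inv)
  body <- fx$planning$structures$masks$body
  interior <- body & !dilate_mask(!body, 8, fx$spec$spacing)
  nz <- dim(interior)[3]
  interior[, , c(1:2, nz - 1, nz)] <- FALSE   # z-boundary samples use fill
  mae <- mean(abs(back$values - smooth$values)[interior])
  expect_lt(mae, 5)
})
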