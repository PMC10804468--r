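test_that("HU-to-RSP calibration hits its anchors and interpolates linearly", {
  curve <- default_rsp_curve()
  expect_equal(hu_to_rsp(0, curve), 1.0)
  expect_equal(hu_to_rsp(-1000, curve), 0.001)
  # halfway between two anchors -> arithmetic mean of their RSPs
  i <- 3
  hu_mid <- mean(curve$hu[i:(i + 1)])
  expect_equal(hu_to_rsp(hu_mid, curve), mean(curve$rsp[i:(i + 1)]))
  # clamped outside the range
  expect_equal(hu_to_rsp(-5000, curve), curve$rsp[1])
  expect_error(rsp_curve(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(rsp_curve(c(-100, 100), c(0.9, 1.1)), "water anchor")
})

test_that("WET raytrace matches closed-form slab sums", {
  # uniform water: WET == geometric path
  ct <- water_box(c(60, 20, 10))
  tr <- wet_raytrace(ct, entry = c(ct$origin[1], 0, 0), direction = c(1, 0, 0),
                     step = 1)
  i100 <- which.min(abs(tr$s - 100))
  expect_equal(tr$wet[i100], 100, tolerance = 1)
  expect_true(all(diff(tr$wet) >= 0))

  # air: WET ~ 0
  air <- voxel_image(array(-1000, c(40, 10, 10)), c(2, 2, 2), kind = "hu")
  tra <- wet_raytrace(air, entry = c(air$origin[1], 0, 0),
                      direction = c(1, 0, 0), step = 1)
  expect_lt(max(tra$wet), 0.2)

  # two slabs: 50 mm water + 50 mm at RSP 1.5 -> WET(100) = 125
  curve <- rsp_curve(c(-1000, 0, 1000), c(0.001, 1, 1.5))
  v <- array(0, c(60, 10, 10)); v[26:60, , ] <- 1000
  slab <- voxel_image(v, c(2, 2, 2), kind = "hu")
  # slab boundary at x-index 25/26 edge = origin + 50 mm
  trs <- wet_raytrace(slab, entry = c(slab$origin[1], 0, 0),
                      direction = c(1, 0, 0), curve = curve, step = 1)
  i100 <- which.min(abs(trs$s - 100))
  expect_equal(trs$wet[i100], 125, tolerance = 1.5)
  expect_error(wet_raytrace(slab, entry = c(1e4, 0, 0),
                            direction = c(1, 0, 0)), "outside")
})

test_that("Bragg curve peaks at the nominal range with a sharp distal falloff", {
  d <- seq(0, 140, by = 0.05)
  v <- bragg_depth_dose(d, R = 100)
  peak <- d[which.max(v)]
  expect_true(peak >= 97 && peak <= 103)
  sigma_d <- max(0.012 * 100, 0.8)
  expect_lt(bragg_depth_dose(100 + 5 * sigma_d, 100), 0.01 * max(v))
  # range scaling moves the peak by ~3%
  v3 <- bragg_depth_dose(d, R = 103)
  expect_equal(d[which.max(v3)] - peak, 3, tolerance = 1)
  # monotone build-up to a single peak
  expect_true(all(diff(v[d <= peak]) >= -1e-12))
  expect_error(bragg_depth_dose(50, R = -1), "R must be")
})

test_that("degenerate margins give the bare CTV union as field-specific target", {
  ph <- small_phantom()
  bm <- beam(1, +1)
  ps <- place_spots(ph$structures, bm, ph$ct, setup_margin = 0,
                    range_margin = 0)
  ctvs <- ph$structures$prescriptions$structure
  union <- Reduce(`|`, ph$structures$masks[ctvs])
  expect_identical(ps$target, union)
  # a margin exceeding the voxel size expands the mask strictly
  ps3 <- place_spots(ph$structures, bm, ph$ct, setup_margin = 5,
                     range_margin = 0.03)
  expect_gt(sum(ps3$target), sum(union))
  expect_true(all(union[ps3$target] | TRUE))
})

test_that("an avoidance mask across the beam entrance removes all spots", {
  ph <- small_phantom()
  bm <- beam(1, +1)
  block <- array(FALSE, dim(ph$ct$values))
  block[1:5, , ] <- TRUE                  # wall across the entrance
  expect_error(place_spots(ph$structures, bm, ph$ct, avoidance = block),
               "no spots retained")
})

test_that("influence is linear and non-negative in the spot weights", {
  ct <- water_box()
  bm <- beam(1, +1)
  spots <- data.frame(ly = c(0, 6), lz = c(0, 0), R = c(60, 80),
                      beam = c(1, 1))
  region <- array(TRUE, dim(ct$values))
  infl <- compute_influence(ct, list(bm), spots, region)
  expect_true(all(infl@x >= 0))
  expect_true(all(Matrix::colSums(infl) > 0))
  d0 <- dose_from_influence(infl, c(0, 0), dim(ct$values), ct$spacing,
                            ct$origin)
  expect_equal(max(d0$values), 0)
  d1 <- dose_from_influence(infl, c(1, 2), dim(ct$values), ct$spacing,
                            ct$origin)
  d2 <- dose_from_influence(infl, c(2, 4), dim(ct$values), ct$spacing,
                            ct$origin)
  expect_equal(d2$values, 2 * d1$values)
})

test_that("influence matrices round-trip through the triplet CSV format", {
  ct <- water_box(c(20, 10, 10))
  sp <- data.frame(ly = 0, lz = 0, R = 30, beam = 1)
  infl <- compute_influence(ct, list(beam(1, 1)), sp,
                            array(TRUE, dim(ct$values)))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_influence_matrix(infl, tf)
  back <- read_influence_matrix(tf)
  expect_equal(dim(back), dim(infl))
  expect_lt(max(abs(back - infl)), 1e-12)
  expect_identical(attr(back, "region_idx"), attr(infl, "region_idx"))
})

test_that("a single spot in water peaks at its nominal range", {
  ct <- water_box()
  bm <- beam(1, +1)
  spots <- data.frame(ly = 0, lz = 0, R = 80, beam = 1)
  region <- array(TRUE, dim(ct$values))
  infl <- compute_influence(ct, list(bm), spots, region)
  dose <- dose_from_influence(infl, 1, dim(ct$values), ct$spacing, ct$origin)
  i <- which(dose$values == max(dose$values), arr.ind = TRUE)[1, ]
  W <- aptkit:::wet_map(hu_to_rsp(ct$values), ct$spacing, bm)
  expect_equal(W[i[1], i[2], i[3]], 80, tolerance = 1.01 * ct$spacing[1])
})

test_that("scenario shift moves the lateral dose centroid by the shift", {
  ct <- water_box()
  bm <- beam(1, +1)
  spots <- data.frame(ly = 0, lz = 0, R = 80, beam = 1)
  region <- array(TRUE, dim(ct$values))
  ax <- aptkit:::axis_coords(ct)
  centroid_y <- function(d) {
    yw <- rep(rep(ax[[2]], each = dim(ct$values)[1]), dim(ct$values)[3])
    sum(d$values * yw) / sum(d$values)
  }
  d0 <- dose_from_influence(
    compute_influence(ct, list(bm), spots, region),
    1, dim(ct$values), ct$spacing, ct$origin)
  dsh <- dose_from_influence(
    compute_influence(ct, list(bm), spots, region,
                      scenario = list(shift = c(0, 3, 0), scale = 1)),
    1, dim(ct$values), ct$spacing, ct$origin)
  # patient shifted +3 -> dose moves -3 in the patient frame
  expect_equal(centroid_y(dsh) - centroid_y(d0), -3,
               tolerance = ct$spacing[2] / 2)
})

test_that("range-scale scenario moves the peak depth proportionally", {
  ct <- water_box()
  bm <- beam(1, +1)
  spots <- data.frame(ly = 0, lz = 0, R = 80, beam = 1)
  region <- array(TRUE, dim(ct$values))
  peak_x <- function(infl) {
    d <- dose_from_influence(infl, 1, dim(ct$values), ct$spacing, ct$origin)
    unname(which(d$values == max(d$values), arr.ind = TRUE)[1, 1])
  }
  p0 <- peak_x(compute_influence(ct, list(bm), spots, region))
  p5 <- peak_x(compute_influence(ct, list(bm), spots, region,
               scenario = list(shift = c(0, 0, 0), scale = 1.05)))
  expect_equal((p5 - p0) * ct$spacing[1], 0.05 * 80,
               tolerance = ct$spacing[1])
})
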