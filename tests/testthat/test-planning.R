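test_that("3 mm / 3% robustness gives exactly 12 scenarios of the right shape", {
  sc <- enumerate_scenarios(3, 0.03)
  expect_length(sc$scenarios, 12)
  expect_equal(sc$nominal, list(shift = c(0, 0, 0), scale = 1))
  for (s in sc$scenarios) {
    expect_equal(sqrt(sum(s$shift^2)), 3)
    expect_equal(sum(s$shift != 0), 1)
    expect_true(s$scale %in% c(0.97, 1.03))
  }
  # all 12 are distinct
  keys <- vapply(sc$scenarios, function(s) paste(c(s$shift, s$scale),
                                                 collapse = "/"), "")
  expect_length(unique(keys), 12)
})

test_that("degenerate magnitudes deduplicate to the nominal scenario", {
  sc <- enumerate_scenarios(0, 0)
  expect_length(sc$scenarios, 1)
  expect_equal(sc$scenarios[[1]], sc$nominal)
})

test_that("objective generation follows the constraint-table rules", {
  m_ctv <- array(FALSE, c(10, 10, 10)); m_ctv[4:6, 4:6, 4:6] <- TRUE
  m_cord <- array(FALSE, c(10, 10, 10)); m_cord[8, 8, 1:10] <- TRUE
  ss <- structure_set(list(CTV_primary = m_ctv, spinal_cord = m_cord),
                      prescriptions = data.frame(structure = "CTV_primary",
                                                 dose_gy = 70, fractions = 35))
  obj <- generate_objectives(ss)
  expect_equal(nrow(obj), 3)
  expect_setequal(obj$kind, c("target-min", "target-max", "oar-max"))
  cord <- obj[obj$structure == "spinal_cord", ]
  expect_equal(cord$dose_gy, 0.9 * 48)          # 43.2 Gy from the 48 Gy limit
  expect_false(cord$robust)
  expect_true(all(obj$robust[obj$structure == "CTV_primary"]))

  # no OARs -> only robust target objectives
  ss2 <- structure_set(list(CTV_primary = m_ctv),
                       prescriptions = ss$prescriptions)
  obj2 <- generate_objectives(ss2)
  expect_true(all(obj2$robust))
  expect_setequal(obj2$kind, c("target-min", "target-max"))

  # parotid gets the V20Gy DVH-point objective
  ss3 <- structure_set(list(CTV_primary = m_ctv, parotid_ips = m_cord),
                       prescriptions = ss$prescriptions)
  obj3 <- generate_objectives(ss3)
  dvh <- obj3[obj3$kind == "oar-dvh-point", ]
  expect_equal(dvh$dose_gy, 20)
  expect_equal(dvh$volume_pct, 0.9 * 50)

  # unknown structure is excluded with a warning
  ss4 <- structure_set(list(CTV_primary = m_ctv, mystery_organ = m_cord),
                       prescriptions = ss$prescriptions)
  expect_warning(obj4 <- generate_objectives(ss4), "mystery_organ")
  expect_false("mystery_organ" %in% obj4$structure)
})

test_that("single-voxel single-spot optimization reaches the closed-form optimum", {
  # influence 1 Gy/MU, target-min at 60 Gy: optimum weight 60
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  ss <- structure_set(list(CTV_primary = m),
                      prescriptions = data.frame(structure = "CTV_primary",
                                                 dose_gy = 60, fractions = 30))
  infl <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  attr(infl, "region_idx") <- which(m)
  obj <- data.frame(structure = "CTV_primary", kind = "target-min",
                    dose_gy = 60, volume_pct = NA, weight = 1, robust = FALSE)
  res <- optimize_weights(infl, list(), obj, ss,
                          optimizer_config(max_iter = 200))
  expect_equal(res$weights[1], 60, tolerance = 0.1 / 60)
})

test_that("the objective trace is monotone non-increasing", {
  plan <- small_plan()
  expect_true(all(diff(plan$trace) <= 1e-12))
})

test_that("a 2-spot/2-voxel problem matches a brute-force weight grid", {
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1, 1] <- TRUE
  ss <- structure_set(list(CTV_primary = m),
                      prescriptions = data.frame(structure = "CTV_primary",
                                                 dose_gy = 60, fractions = 30))
  A <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                            x = c(1, 0.4, 0.3, 1), dims = c(2, 2))
  attr(A, "region_idx") <- which(m)
  obj <- rbind(
    data.frame(structure = "CTV_primary", kind = "target-min", dose_gy = 60,
               volume_pct = NA, weight = 1, robust = FALSE),
    data.frame(structure = "CTV_primary", kind = "target-max", dose_gy = 62,
               volume_pct = NA, weight = 1, robust = FALSE))
  res <- optimize_weights(A, list(), obj, ss, optimizer_config(max_iter = 400))

  f <- function(w) {
    d <- as.numeric(A %*% w)
    sum(pmax(60 - d, 0)^2) / 2 / 60^2 + sum(pmax(d - 62, 0)^2) / 2 / 62^2
  }
  grid <- seq(0, 80, length.out = 200)
  best <- Inf; wbest <- c(0, 0)
  for (w1 in grid) for (w2 in grid) {
    v <- f(c(w1, w2))
    if (v < best) { best <- v; wbest <- c(w1, w2) }
  }
  # the zero-penalty set is a region, so compare objective values, not
  # argmins; the optimizer must do at least as well as the grid search
  expect_lte(f(res$weights), best + 1e-6)
  d <- as.numeric(A %*% res$weights)
  expect_true(all(d >= 60 - 0.5 & d <= 62 + 0.5))
})

test_that("normalization scale follows the sorting-oracle convention", {
  # 100 voxels with doses 1.00, 1.01, ..., 1.99; rx 1.50 -> s = 1.50/1.05
  d <- seq(1.00, 1.99, by = 0.01)
  s <- normalize_factor(d, 1.50)
  expect_equal(s, 1.50 / 1.05)
  expect_equal(mean(d * s >= 1.50) * 100, 95)
  # a dose already at V100 = 95% is a fixed point
  s2 <- normalize_factor(d * s, 1.50)
  expect_equal(s2, 1)
  # idempotence: re-normalizing changes nothing
  expect_equal(normalize_factor(d * s * s2, 1.50), 1)
  expect_error(normalize_factor(rep(0, 10), 1.5), "no dose")
})

test_that("robust evaluation reports the worst scenario and pass flag", {
  rx <- data.frame(structure = "CTV_primary", dose_gy = 60, fractions = 30)
  # identical dose across scenarios -> worst equals nominal
  D <- matrix(60, nrow = 50, ncol = 5)
  r <- robust_evaluate(list(CTV_primary = D), rx)
  expect_equal(unname(r$worst["CTV_primary"]), 100)
  expect_true(r$pass)
  # one scenario fully off target -> fail
  D2 <- D; D2[, 3] <- 0
  r2 <- robust_evaluate(list(CTV_primary = D2), rx)
  expect_equal(unname(r2$worst["CTV_primary"]), 0)
  expect_false(r2$pass)
})

test_that("planning on the phantom meets coverage and normalization invariants", {
  ph <- small_phantom()
  plan <- small_plan()
  rx <- ph$structures$prescriptions
  d <- plan$dose$values
  m1 <- ph$structures$masks[[rx$structure[1]]]
  n1 <- sum(m1)
  v100 <- mean(d[m1] >= rx$dose_gy[1]) * 100
  # V100 = 95% up to the voxel quantization of this CTV
  expect_gte(v100, 95)
  expect_lte(v100, 95 + 100 / n1 + 1e-9)
  expect_gt(plan$normalization, 0)
  expect_true(all(plan$weights >= 0))
  # every CTV holds worst-case V95 > 95%
  expect_true(plan$robust$pass)
  # re-running the identical adaptation input reproduces the plan
  plan2 <- adapt_plan(ph$ct, ph$structures, fast_plan_config())
  dm1 <- mean(plan$dose$values[m1])
  dm2 <- mean(plan2$dose$values[m1])
  expect_lt(abs(dm1 - dm2) / dm1, 0.01)
})

test_that("plans serialize to JSON with spots, weights and scenarios", {
  plan <- small_plan()
  tf <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, tf)
  back <- jsonlite::read_json(tf)
  expect_length(back$weights, nrow(plan$spots))
  expect_length(back$spots, nrow(plan$spots))   # one object per spot
  expect_equal(back$normalization, plan$normalization)
  expect_length(back$scenarios$scenarios, 12)
})
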