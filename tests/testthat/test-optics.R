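# First-order optics bookkeeping and the sensorless AO optimizer.

p <- optical_prescription()

test_that("field of view: calibrated and first-order extents", {
  fov <- fov_extent(p)
  expect_equal(fov$calibrated_mm, 5.0)
  expect_equal(fov$first_order_mm, 5.24932, tolerance = 1e-5)
  expect_equal(fov$area_mm2, 25)
  p0 <- optical_prescription(max_half_angle_deg = 1e-12)
  expect_lt(fov_extent(p0)$calibrated_mm, 1e-9)
})

test_that("telescope magnification and space-bandwidth product", {
  m <- telescope_magnification(p)
  expect_equal(m$magnification, 243 / 61)
  expect_equal(m$nominal, 4)
  expect_equal(telescope_magnification(
    optical_prescription(efl_scan_mm = 50, efl_tube_mm = 100))$nominal, 2)
  expect_equal(space_bandwidth_product(p), 25e6)
  expect_equal(space_bandwidth_product(
    optical_prescription(lateral_resolution_um = 2)), 6.25e6)
  expect_equal(space_bandwidth_product(p, fov_area_mm2 = 0), 0)
})

test_that("square field exceeds the inscribed circle by ~27%", {
  cmp <- fov_area_comparison(5, 5)
  expect_equal(cmp$circle_area_mm2, 19.63495, tolerance = 1e-5)
  expect_equal(cmp$excess_fraction, 0.2732395, tolerance = 1e-6)
  equal <- fov_area_comparison(2 * sqrt(pi) / 2, 2)
  expect_equal(equal$excess_fraction, 0, tolerance = 1e-12)
  expect_lt(fov_area_comparison(1, 2)$excess_fraction, 0)
})

test_that("paraxial focal shift is the index ratio", {
  expect_equal(paraxial_focal_shift(1, 1.333), 1.333)
  expect_equal(paraxial_focal_shift(1.33, 1.33), 1)
  expect_equal(paraxial_focal_shift(1, 1.515), 1.515)
})

test_that("defocus range is linear in stroke with the right fold-change", {
  dm <- deformable_mirror_spec()
  expect_equal(defocus_range(dm)$range_um, 120)
  expect_equal(defocus_range(dm)$half_range_um, 60)
  expect_equal(defocus_range(deformable_mirror_spec(stroke_um = 80),
                             reference_stroke_um = 3.5)$fold_vs_reference,
               22.857143, tolerance = 1e-6)
  expect_equal(defocus_range(deformable_mirror_spec(stroke_um = 0))$range_um, 0)
  strokes <- seq(0.5, 5, by = 0.5)
  rng <- vapply(strokes, function(s)
    defocus_range(deformable_mirror_spec(stroke_um = s))$range_um,
    numeric(1))
  expect_equal(rng, strokes * (120 / 3.5))
})

test_that("zernike state protects piston, tip, tilt and defocus", {
  expect_error(zernike_state(numeric(15), adjustable = 4:15), "never")
  expect_error(zernike_state(numeric(10)))
  st <- zernike_state()
  expect_equal(st$adjustable, 5:15)
})

test_that("AO optimizer recovers a separable optimum in one sweep", {
  target <- c(numeric(4), seq(-0.4, 0.6, length.out = 11))
  metric <- function(a) exp(-sum((a[5:15] - target[5:15])^2))
  out <- sensorless_ao_optimize(metric, zernike_state(), sweeps = 1)
  expect_equal(out$state$coefficients[5:15], target[5:15],
               tolerance = 0.02)
  expect_equal(out$state$coefficients[1:4], numeric(4))
})

test_that("AO optimizer handles coupled modes within 5% in three sweeps", {
  set.seed(42)
  # rotated quadratic with condition number <= 5 over the 11 modes
  Q <- qr.Q(qr(matrix(rnorm(121), 11)))
  H <- Q %*% diag(seq(1, 5, length.out = 11)) %*% t(Q)
  target <- seq(-0.5, 0.5, length.out = 11)
  metric <- function(a) {
    d <- a[5:15] - target
    100 - 0.5 * sum(d * (H %*% d))
  }
  best <- metric(c(numeric(4), target))
  start_val <- metric(numeric(15))
  out <- sensorless_ao_optimize(metric, zernike_state(), sweeps = 3)
  achieved <- metric(out$state$coefficients)
  expect_gt((achieved - start_val) / (best - start_val), 0.95)
  expect_equal(out$state$coefficients[1:4], numeric(4))
  # best-so-far metric trace is monotone non-decreasing
  expect_true(all(diff(out$metric_trace) >= 0))
})

test_that("AO optimizer leaves an already-optimal state unchanged", {
  metric <- function(a) -sum(a[5:15]^2)
  out <- sensorless_ao_optimize(metric, zernike_state(), sweeps = 2)
  expect_equal(out$state$coefficients, numeric(15), tolerance = 1e-6)
})

test_that("field flatness check compares sag against a plane fit", {
  xg <- seq(-2.5, 2.5, length.out = 21)
  flat <- outer(xg, xg, function(x, y) 5 + 0.1 * x - 0.2 * y)
  res <- field_flatness_check(flat)
  expect_true(res$pass)
  expect_lt(res$max_sag_um, 1e-9)
  # spherical sag scaled to reach s_max at the corners; the plane fit
  # absorbs about a third of a symmetric bowl
  r2 <- outer(xg, xg, function(x, y) x^2 + y^2)
  sphere <- function(s_max) s_max * r2 / max(r2)
  expect_true(field_flatness_check(sphere(29))$pass)
  expect_false(field_flatness_check(sphere(60))$pass)
  expect_error(field_flatness_check(matrix(numeric(0), 0, 0)), "empty")
})

test_that("optics report aggregates the headline quantities", {
  rep <- optics_report()
  expect_equal(rep$fov_side_mm, 5)
  expect_equal(rep$space_bandwidth_product, 25e6)
  expect_equal(rep$defocus_range_um, 120)
})
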