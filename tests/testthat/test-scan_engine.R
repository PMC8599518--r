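# Resonant scan timing: pulses-per-pixel profile, dwell-time conservation,
# frame timing, throughput, sequential dead time, random access.

cfg <- resonant_config(frequency = 8000, fill_fraction = 0.9)

test_that("resonant mirror position is sinusoidal and periodic", {
  expect_equal(resonant_position(0), 0)
  expect_equal(resonant_position(pi / 2), 1)
  expect_equal(resonant_position(0.1), 0.09983342, tolerance = 1e-6)
  expect_equal(resonant_position(0.3 + 2 * pi), resonant_position(0.3))
})

test_that("pulses per pixel matches direct evaluation at the reference point", {
  # frozen from an independent numeric oracle
  expect_equal(pulses_per_pixel(256, cfg, N = 512, rep_rate_hz = 80e6),
               5.5952996, tolerance = 1e-6)
  expect_equal(pulses_per_pixel(1, cfg, N = 512, rep_rate_hz = 80e6),
               12.8364778, tolerance = 1e-6)
  # edge value equals centre value inflated by 1 / sqrt(1 - FF^2)
  ctr <- (2 * 0.9 / 512) * 80e6 / (2 * pi * 8000)
  expect_equal(pulses_per_pixel(1, cfg, 512), ctr / sqrt(1 - 0.9^2),
               tolerance = 1e-9)
})

test_that("pulses per pixel is symmetric, edge-heavy, and conserves line time", {
  for (FF in c(0.3, 0.7, 0.9)) {
    c2 <- resonant_config(8000, FF)
    for (N in c(128, 512, 2048)) {
      p <- pulses_per_pixel(seq_len(N), c2, N)
      expect_equal(p, rev(p))                       # exact symmetry
      expect_true(all(diff(p[1:(N %/% 2)]) < 0))    # decreasing to centre
      expect_true(all(p > 0))
      active <- 80e6 * asin(FF) / (pi * 8000)
      # endpoint sampling overshoots near the edge where velocity -> 0;
      # 0.5% holds except at the steepest case (FF = 0.9, N = 128: 0.7%)
      tol <- if (FF >= 0.9 && N < 512) 0.01 else 0.005
      expect_lt(abs(sum(p) - active) / active, tol)
    }
  }
})

test_that("invalid pulse-per-pixel inputs are rejected", {
  expect_error(resonant_config(8000, 1.0), "fill_fraction")
  expect_error(resonant_config(8000, 0), "fill_fraction")
  expect_error(pulses_per_pixel(0, cfg, 512), "pixel index")
  expect_error(pulses_per_pixel(513, cfg, 512), "pixel index")
  expect_error(pulses_per_pixel(1, cfg, N = 1))
})

test_that("dwell times are repetition-rate free and sum to the active line time", {
  d <- line_pixel_dwell_times(cfg, 512)
  expect_equal(d, pulses_per_pixel(seq_len(512), cfg, 512, 80e6) / 80e6)
  expect_equal(sum(d), asin(0.9) / (pi * 8000), tolerance = 0.005)
  expect_equal(sum(d) * 1e6, 44.55, tolerance = 0.01)   # ~44.6 us
  # refinement: N = 128 and N = 4096 agree within 0.5% (FF = 0.8)
  c8 <- resonant_config(8000, 0.8)
  s1 <- sum(line_pixel_dwell_times(c8, 128))
  s2 <- sum(line_pixel_dwell_times(c8, 4096))
  expect_lt(abs(s1 - s2) / s2, 0.005)
  # small fill fraction: sum -> FF / (pi * Freq)
  c0 <- resonant_config(8000, 0.01)
  expect_equal(sum(line_pixel_dwell_times(c0, 512)), 0.01 / (pi * 8000),
               tolerance = 1e-4)
})

test_that("frame timing reproduces nominal and calibrated frame rates", {
  big <- raster_job(c(-0.75, -2.5), c(1.5, 5), c(1024, 4096))
  nominal <- resonant_config(8000, 0.9, effective_line_rate = NULL)
  expect_equal(frame_timing(big, nominal)$frame_rate_hz, 16000 / 4096)
  expect_equal(frame_timing(big, default_scan_config())$frame_rate_hz,
               3.85, tolerance = 0.001)
  small <- raster_job(c(0, 0), c(0.5, 0.5), c(512, 512),
                      bidirectional = FALSE)
  expect_equal(frame_timing(small, nominal)$frame_rate_hz, 8000 / 512)
  # flyback lines fold into the effective rate
  ft <- frame_timing(big, nominal, flyback_lines = 96)
  expect_equal(ft$frame_rate_hz, 16000 / (4096 + 96))
  expect_equal(ft$frame_rate_hz, ft$line_rate_hz / 4096)
})

test_that("session throughput aggregates both engines", {
  big <- raster_job(c(-0.75, -2.5), c(1.5, 5), c(1024, 4096))
  sch <- list(engine_schedule(list(big), engine_id = 1),
              engine_schedule(list(big), engine_id = 2))
  tp <- session_throughput(sch, default_scan_config())
  expect_equal(tp$megapixels_per_s_report, 32.3)
  # one engine, 512 x 512 at 30 frames/s
  cfg30 <- resonant_config(8000, 0.9, effective_line_rate = 512 * 30)
  one <- engine_schedule(list(raster_job(c(0, 0), c(0.5, 0.5),
                                         c(512, 512))))
  expect_equal(session_throughput(list(one), cfg30)$megapixels_per_s,
               7.86432, tolerance = 1e-6)
  expect_equal(session_throughput(list(), cfg)$pixels_per_s, 0)
})

test_that("sequential dead time grows with jump time and frame rate", {
  expect_equal(sequential_dead_fraction(rep(1 / 60, 2), 0), 0)
  expect_equal(sequential_dead_fraction(rep(1 / 60, 2), 0.005),
               0.23076923, tolerance = 1e-7)
  expect_gt(sequential_dead_fraction(rep(1 / 60, 2), 0.005), 0.2)
  expect_equal(sequential_dead_fraction(rep(1, 2), 0.005),
               0.01 / 2.01, tolerance = 1e-12)
  jumps <- seq(0, 0.02, by = 0.002)
  dead <- vapply(jumps, function(j)
    sequential_dead_fraction(rep(1 / 30, 2), j), numeric(1))
  expect_true(all(diff(dead) > 0))
  rates <- c(1, 5, 15, 30, 60)
  dead_r <- vapply(rates, function(r)
    sequential_dead_fraction(rep(1 / r, 2), 0.005), numeric(1))
  expect_true(all(diff(dead_r) > 0))
  expect_error(sequential_dead_fraction(1 / 30, 0.005), "two regions")
  expect_error(sequential_dead_fraction(rep(1 / 30, 2), -1))
})

test_that("random-access plans revisit points at the cycle rate", {
  set.seed(9)
  pts <- cbind(runif(12, -1, 1), runif(12, -1, 1))
  plan <- plan_random_access(random_access_job(pts, 1e-3, 0.5e-3))
  expect_equal(plan$cycle_period_s, 0.018)
  expect_equal(plan$per_point_rate_hz, 55.5556, tolerance = 1e-4)
  expect_equal(plan$visit_start_s[2] - plan$visit_start_s[1], 1.5e-3)
  single <- plan_random_access(random_access_job(cbind(0, 0), 1e-3, 0))
  expect_equal(single$per_point_rate_hz, 1000)
  expect_error(random_access_job(matrix(numeric(0), ncol = 2), 1e-3),
               "at least one")
  # random access beats rastering the bounding box when coverage is sparse:
  # 12 somata in a 2 x 2 mm region vs a 2 um-per-line raster of the box
  box <- raster_job(c(-1, -1), c(2, 2), c(1024, 1024),
                    scan_mode = "galvo")
  expect_lt(plan$cycle_period_s,
            frame_timing(box, default_scan_config())$frame_period_s)
})

test_that("job geometry constraints are enforced", {
  expect_error(raster_job(c(0, 0), c(2, 1), c(512, 512)), "resonant")
  expect_silent(raster_job(c(-2.5, -2.5), c(5, 5), c(512, 512),
                           scan_mode = "galvo"))
  expect_error(raster_job(c(2, 2), c(1, 1), c(64, 64)), "FOV")
  expect_error(raster_job(c(0, 0), c(1, 1), c(1, 64)), "2 pixels")
  expect_error(random_access_job(cbind(3, 0), 1e-3), "FOV")
})

test_that("engines are timed independently", {
  job2 <- raster_job(c(0.5, 0.5), c(1, 1), c(512, 512))
  before <- frame_timing(job2, cfg)
  # reconfigure engine 1 arbitrarily; engine 2 timing is bit-identical
  for (e1_lines in c(128, 1024, 4096)) {
    invisible(frame_timing(
      raster_job(c(-2, -2), c(1, 1), c(256, e1_lines)), cfg))
    expect_identical(frame_timing(job2, cfg), before)
  }
})
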