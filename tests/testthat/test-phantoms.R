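# Synthetic phantoms: bead volumes, calibration grid, correlated neuron
# fields, and the image-formation renderer.

test_that("bead volumes are seeded, depth-structured, and validated", {
  ph <- make_bead_volume(n_beads = 8, depths_um = 250, seed = 1)
  expect_equal(nrow(ph$positions_um), 8)
  expect_true(all(ph$positions_um[, "z"] == 250))
  ph3 <- make_bead_volume(n_beads = 8, seed = 2)
  expect_equal(table(ph3$positions_um[, "z"]),
               table(rep(c(50, 250, 500), each = 8)))
  expect_identical(make_bead_volume(5, seed = 7)$positions_um,
                   make_bead_volume(5, seed = 7)$positions_um)
  expect_error(make_bead_volume(0), "at least one")
  expect_warning(make_bead_volume(500, extent_um = c(2, 2), seed = 3),
                 "overlap")
})

test_that("line grid places floor(extent / period) lines strictly inside", {
  g <- make_line_grid()
  expect_equal(g$n_lines, 25L)
  expect_true(all(g$centers_mm > 0 & g$centers_mm < 5))
  expect_equal(make_line_grid(period_mm = 1)$n_lines, 5L)
  expect_equal(make_line_grid(period_mm = 6)$n_lines, 0L)
  # profile shows one suprathreshold run per line
  pos <- seq(0, 5, by = 1e-3)
  prof <- line_grid_profile(g, pos)
  expect_equal(count_profile_peaks(prof), 25L)
})

test_that("correlation kernel is non-increasing with the right endpoints", {
  k <- correlation_kernel()
  expect_equal(kernel_rho(k, 0), 0.25)
  expect_equal(kernel_rho(k, 2000), 0.05, tolerance = 1e-9)
  d <- seq(0, 4000, by = 10)
  expect_true(all(diff(kernel_rho(k, d)) <= 0))
  expect_true(all(kernel_rho(k, d) >= 0 & kernel_rho(k, d) <= 1))
  expect_gt(kernel_rho(k, 39), 0.2)       # high below the knee
  expect_error(correlation_kernel(rho0 = 0.01, rho_far = 0.2))
})

test_that("neuron field realizes the target rate and distance kernel", {
  ph <- make_neuron_field(n_neurons = 200, seed = 11)
  expect_equal(dim(ph$spikes), c(200, 5000))
  expect_equal(mean(ph$spikes) * ph$frame_rate_hz, ph$rate_hz,
               tolerance = 0.05)
  expect_true(min(dist(ph$positions_um)) >= 15)
  prof <- correlation_profile(ph$spikes, ph$positions_um,
                              seq(0, 2600, by = 40))
  k <- kernel_rho(ph$kernel, prof$bin_mid_um)
  ok <- prof$n_pairs >= 20
  expect_gt(sum(ok), 30)
  expect_lt(max(abs(prof$mean_corr - k)[ok]), 0.05)
})

test_that("a null kernel gives independent trains and seeds reproduce", {
  ph0 <- make_neuron_field(n_neurons = 60, area_um = c(600, 600),
                           n_frames = 3000,
                           kernel = correlation_kernel(rho0 = 0,
                                                       rho_far = 0),
                           seed = 12)
  R <- cor(t(ph0$spikes))
  expect_lt(abs(mean(R[upper.tri(R)])), 0.005)
  ph_a <- make_neuron_field(n_neurons = 30, area_um = c(300, 300),
                            n_frames = 500, seed = 13)
  ph_b <- make_neuron_field(n_neurons = 30, area_um = c(300, 300),
                            n_frames = 500, seed = 13)
  expect_identical(ph_a$spikes, ph_b$spikes)
  expect_identical(ph_a$positions_um, ph_b$positions_um)
  expect_error(make_neuron_field(n_neurons = 1000,
                                 area_um = c(100, 100)), "density")
})

test_that("rendered uniform field follows the pulses-per-pixel profile", {
  cfg <- default_scan_config()
  job <- raster_job(c(-0.75, -0.25), c(1.5, 0.5), c(256, 64), frames = 40)
  stack <- render_raster_frames(function(x, y) matrix(1, 64, 256), job,
                                cfg, emission_model(3e-9, 2), seed = 21)
  prof <- apply(stack, 2, mean)
  expected <- pulses_per_pixel(1:256, cfg, 256) * 2
  expect_lt(max(abs(prof - expected) / expected), 0.05)
  # shot noise: variance ~ mean (Poisson)
  v <- apply(stack, c(1, 2), var)
  m <- apply(stack, c(1, 2), mean)
  expect_equal(mean(v) / mean(m), 1, tolerance = 0.05)
  # zero emission -> all-zero stack
  dark <- render_raster_frames(function(x, y) matrix(1, 64, 256), job,
                               cfg, emission_model(3e-9, 0), seed = 22)
  expect_equal(sum(dark), 0)
})

test_that("galvo raster spreads the same pulse budget uniformly", {
  cfg <- default_scan_config()
  jobg <- raster_job(c(-2.5, -0.25), c(5, 0.5), c(512, 8),
                     scan_mode = "galvo")
  w <- pixel_pulse_weights(jobg, cfg)
  expect_equal(length(unique(round(w, 12))), 1L)
  jobr <- raster_job(c(-0.75, -0.25), c(1.5, 0.5), c(512, 8))
  expect_equal(sum(pixel_pulse_weights(jobr, cfg)), sum(w),
               tolerance = 0.005)
})

test_that("full-scan render of the calibration grid shows 25 lines", {
  grid <- make_line_grid()
  job <- raster_job(c(-2.5, -2.5), c(5, 5), c(1024, 64),
                    scan_mode = "galvo")
  img <- render_movie(grid, job, emission = emission_model(3e-9, 5),
                      seed = 23)
  expect_equal(count_profile_peaks(colMeans(img[, , 1])), 25L)
  # orthogonal orientation counts the same number along y
  gy <- make_line_grid(orientation = "y")
  joby <- raster_job(c(-2.5, -2.5), c(5, 5), c(64, 1024),
                     scan_mode = "galvo")
  imy <- render_movie(gy, joby, emission = emission_model(3e-9, 5),
                      seed = 24)
  expect_equal(count_profile_peaks(rowMeans(imy[, , 1])), 25L)
})

test_that("rendered bead spot has the PSF width", {
  ph <- make_bead_volume(1, extent_um = c(20, 20), depths_um = 100,
                         seed = 25)
  img <- render_movie(ph, z_um = 100, pixel_pitch_um = 0.1,
                      peak_counts = 2000, background_counts = 1,
                      frames = 1, seed = 26)
  mean_img <- attr(img, "mean_image")
  iy <- which(rowSums(mean_img) == max(rowSums(mean_img)))[1]
  xs <- seq(0.05, 20, by = 0.1)
  fit <- fit_fwhm(xs, img[iy, , 1])
  expect_equal(fit$fwhm, 1.0, tolerance = 0.05)
})
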