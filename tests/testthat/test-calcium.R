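# Trace extraction, neuropil subtraction, dF/F, SNR, AR(2) spike
# deconvolution and distance-binned correlations.

test_that("ROI sets enforce mask validity", {
  m <- list(1:3, 10:12)
  a <- list(20:25, 30:35)
  pos <- cbind(c(1, 2), c(1, 2))
  expect_s3_class(roi_set(m, a, pos, c(10, 10)), "roi_set")
  expect_error(roi_set(m, list(2:4, 30:35), pos, c(10, 10)), "exclude")
  expect_error(roi_set(list(1:3, integer()), a, pos, c(10, 10)), "empty")
  expect_error(roi_set(m, list(20:25, 99:101), pos, c(10, 10)), "bounds")
})

test_that("trace extraction averages masks per frame", {
  movie <- array(0, dim = c(4, 4, 3))
  movie[1, 1, ] <- c(5, 6, 7)
  rois <- roi_set(list(1L), list(6:7), cbind(0, 0), c(4, 4))
  ts <- extract_traces(movie, rois)
  expect_equal(ts$raw[1, ], c(5, 6, 7))     # single-pixel mask
  uni <- array(3.5, dim = c(4, 4, 2))
  ts2 <- extract_traces(uni, roi_set(list(1:2), list(9:12),
                                     cbind(0, 0), c(4, 4)))
  expect_true(all(ts2$raw == 3.5) && all(ts2$neuropil == 3.5))
})

test_that("neuropil subtraction is exact and linear", {
  raw <- matrix(rnorm(20, 10), 2)
  np <- matrix(rnorm(20, 3), 2)
  expect_equal(neuropil_subtract(raw, 0.7, np), raw - 0.7 * np)
  expect_equal(neuropil_subtract(raw, 0.7, matrix(0, 2, 10)), raw)
  expect_equal(max(abs(neuropil_subtract(raw, 1, raw))), 0)
  # linear in both arguments
  a <- matrix(rnorm(20), 2); b <- matrix(rnorm(20), 2)
  expect_equal(neuropil_subtract(raw + a, 0.7, np + b),
               neuropil_subtract(raw, 0.7, np) +
                 neuropil_subtract(a, 0.7, b))
  expect_error(neuropil_subtract(raw, 0.7, matrix(0, 3, 10)), "shape|shape")
  expect_error(neuropil_subtract(raw, 1.5, np))
})

test_that("transient SNR matches a constructed trace and scales", {
  set.seed(41)
  noise <- rnorm(2000)
  noise[498:530] <- 0               # keep the transient peak unperturbed
  transient <- numeric(2000)
  transient[500:520] <- 8 * exp(-(0:20) / 8)   # one transient peaking at 8
  trace <- noise + transient
  mask <- logical(2000); mask[498:530] <- TRUE
  snr <- compute_snr(trace, mask)   # peak 8 over ~unit-SD noise
  expect_equal(snr, 8, tolerance = 0.1)
  # doubling the transient amplitude doubles the SNR
  snr2 <- compute_snr(noise + 2 * transient, mask)
  expect_equal(snr2, 2 * snr, tolerance = 1e-9)
  expect_warning(out <- compute_snr(rnorm(500)), "no transients|SNR")
  expect_true(is.na(out))
})

test_that("AR(2) kernel equals the discrete double exponential", {
  ker <- ar2_kernel(30)
  d <- exp(-1 / (30 * 1.5)); r <- exp(-1 / (30 * 0.18))
  expect_equal(ker$g1, d + r)
  expect_equal(ker$g2, -d * r)
  k <- seq_along(ker$h)
  expect_equal(ker$h, (d^k - r^k) / (d - r))
  # convolution via the AR recursion reproduces the kernel
  s <- numeric(100); s[10] <- 1
  tr <- calcium_traces_from_spikes(s, 30, amplitude = 1)
  expect_equal(max(tr), 1, tolerance = 1e-9)
  expect_equal(tr[10:15], ker$h[1:6] / ker$peak, tolerance = 1e-9)
  expect_equal(tr[1:9], numeric(9))
})

test_that("deconvolution recovers a noiseless transient exactly", {
  s <- numeric(400); s[120] <- 1
  y <- calcium_traces_from_spikes(s, 30)
  sp <- infer_spikes(y, 30)
  ev <- which(sp$amplitudes > 0)
  expect_equal(ev, 120L)
  expect_equal(sp$amplitudes[120], 1, tolerance = 1e-4)
  expect_gt(sp$r_squared, 0.999)
  # zero trace yields zero spikes
  expect_equal(sum(infer_spikes(numeric(300), 30)$amplitudes), 0)
  expect_error(infer_spikes(c(1, NA, 3), 30), "finite")
})

test_that("pipeline on a rendered phantom: SNR ~8 supports F1 >= 0.8", {
  ph <- make_neuron_field(n_neurons = 40, area_um = c(400, 400),
                          rate_hz = 0.15, frame_rate_hz = 30,
                          n_frames = 3000, seed = 51)
  ses <- run_phantom_session(ph, soma_peak_counts = 100,
                             baseline_counts = 2, seed = 52)
  expect_gt(median(ses$snr, na.rm = TRUE), 6)
  f1 <- spike_f1(ses$spikes, ph$spikes, tol_frames = 2)
  expect_gte(f1$f1, 0.8)
  # raw traces track the ground-truth calcium
  gt <- calcium_traces_from_spikes(ph$spikes, ph$frame_rate_hz)
  cc <- vapply(seq_len(40), function(i) cor(ses$traces$raw[i, ], gt[i, ]),
               numeric(1))
  expect_gt(median(cc), 0.8)
  # neuropil subtraction reduces contamination by the population signal
  pop <- colMeans(gt)
  r_raw <- abs(vapply(seq_len(40), function(i)
    cor(ses$traces$raw[i, ], pop), numeric(1)))
  r_cor <- abs(vapply(seq_len(40), function(i)
    cor(ses$traces$corrected[i, ], pop), numeric(1)))
  expect_lt(mean(r_cor), mean(r_raw))
})

test_that("correlation profile bins, excludes and conserves pairs", {
  set.seed(61)
  n <- 12; T_ <- 400
  sp <- matrix(rpois(n * T_, 0.1), n)
  sp[2, ] <- sp[1, ]          # identical pair, 10 um apart
  sp[3, ] <- 0                # constant train
  pos <- cbind(c(0, 10, seq(250, by = 250, length.out = n - 2)), 0)
  prof <- correlation_profile(sp, pos, seq(0, 3000, by = 40))
  expect_equal(sum(prof$n_pairs) + attr(prof, "n_excluded_constant") +
                 attr(prof, "n_excluded_range"), n * (n - 1) / 2)
  expect_equal(attr(prof, "n_excluded_constant"), n - 1L)
  # the identical pair is alone in the first bin: correlation exactly 1
  expect_equal(prof$n_pairs[1], 1L)
  expect_equal(prof$mean_corr[1], 1)
  expect_error(correlation_profile(sp[1, , drop = FALSE], pos[1, ,
                                                              drop = FALSE]),
               "two neurons")
  expect_equal(n_pairwise(5874), 17249001)
})

test_that("dF/F baseline tracks a slow drift", {
  set.seed(62)
  T_ <- 2000
  drift <- 10 + 2 * sin(seq(0, 2 * pi, length.out = T_))
  tr <- matrix(drift + rnorm(T_, 0, 0.05), 1)
  dff <- delta_f_over_f(tr, frame_rate_hz = 10)
  expect_lt(max(abs(colMeans(dff))), 0.35)
  # the low-percentile baseline tracks the drift, biased slightly low
  # within rising stretches of the 60 s window
  base <- attr(dff, "baseline")
  expect_lt(max(abs(base - drift)) / mean(drift), 0.2)
})
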