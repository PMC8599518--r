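# Pulse-train interleaving, stochastic emission, and photon
# demultiplexing with lifetime crosstalk.

test_that("path length converts to delay via the speed of light", {
  expect_equal(delay_from_path_length(1.875) * 1e9, 6.25, tolerance = 0.001)
  expect_equal(delay_from_path_length(0), 0)
  expect_equal(delay_from_path_length(0.2998) * 1e9, 1.00, tolerance = 1e-4)
  expect_error(delay_from_path_length(-1), "non-negative")
})

test_that("two half-period-offset trains interleave to twice the rate", {
  a <- pulse_train(80e6, 0, 200, source = 1L)
  b <- pulse_train(80e6, 6.25e-9, 200, source = 2L)
  it <- interleave_trains(a, b)
  expect_equal(it$effective_rate_hz, 160e6)
  expect_true(it$evenly_spaced)
  expect_equal(unique(round(diff(it$times_s), 15)), 6.25e-9)
  expect_equal(it$source[1:4], c(1L, 2L, 1L, 2L))
  # degenerate zero offset: coincident pulses, flagged uneven
  it0 <- interleave_trains(a, pulse_train(80e6, 0, 200, source = 2L))
  expect_false(it0$evenly_spaced)
  expect_equal(it0$effective_rate_hz, 80e6)
  # 3 ns offset: alternating 3 / 9.5 ns gaps, flagged
  it3 <- interleave_trains(a, pulse_train(80e6, 3e-9, 200, source = 2L))
  expect_false(it3$evenly_spaced)
  expect_setequal(round(it3$gap_s * 1e9, 6), c(3, 9.5))
  expect_error(interleave_trains(a, pulse_train(40e6, 0, 10)),
               "repetition rate")
})

test_that("emission simulation follows Poisson statistics and the lifetime", {
  tr <- pulse_train(80e6, 0, 10)
  expect_length(simulate_emission(tr, emission_model(3e-9, 0),
                                  seed = 1)$times_s, 0)
  big <- pulse_train(80e6, 0, 1e6)
  ev <- simulate_emission(big, emission_model(3e-9, 0.1), seed = 2)
  expect_lt(abs(length(ev$times_s) - 1e5), 4 * sqrt(1e5))
  expect_false(is.unsorted(ev$times_s))
  # vanishing lifetime: photons at the pulse times
  fast <- simulate_emission(pulse_train(80e6, 0, 1000),
                            emission_model(1e-15, 0.5), seed = 3)
  residue <- fast$times_s %% 12.5e-9
  expect_true(all(pmin(residue, 12.5e-9 - residue) < 1e-12))
})

test_that("demultiplexing conserves events and respects the gates", {
  a <- pulse_train(80e6, 0, 5e4, source = 1L)
  b <- pulse_train(80e6, 6.25e-9, 5e4, source = 2L)
  it <- interleave_trains(a, b)
  ev <- simulate_emission(it, emission_model(3e-9, 1), seed = 4)
  edges <- seq(0, 5e4 / 80e6, length.out = 65)
  dm <- demultiplex(ev, demux_gates(), edges)
  expect_equal(sum(dm$counts1) + sum(dm$counts2) + dm$n_veto + dm$n_dropped,
               length(ev$times_s))
  # zero-lifetime events at the pulse times are never misassigned
  ev0 <- simulate_emission(it, emission_model(1e-15, 0.3), seed = 5)
  dm0 <- demultiplex(ev0, demux_gates(), edges)
  expect_equal(sum(dm0$assigned != ev0$true_source & dm0$assigned != 0), 0)
  # full blanking vetoes everything
  wide <- demux_gates(6.25e-9, veto_width_s = 6.25e-9 * (1 - 1e-9))
  dmv <- demultiplex(ev, wide, edges)
  expect_equal(sum(dmv$counts1) + sum(dmv$counts2), 0)
  expect_equal(dmv$n_veto + dmv$n_dropped, length(ev$times_s))
  expect_error(demux_gates(6.25e-9, veto_width_s = 7e-9), "veto")
})

test_that("Monte-Carlo misassignment converges to the closed-form crosstalk", {
  a <- pulse_train(80e6, 0, 5e5, source = 1L)
  b <- pulse_train(80e6, 6.25e-9, 5e5, source = 2L)
  ev <- simulate_emission(interleave_trains(a, b),
                         emission_model(3e-9, 0.1), seed = 6)
  expect_gt(length(ev$times_s), 9e4)
  dm <- demultiplex(ev, demux_gates(), c(0, 1))
  mis <- mean(dm$assigned != ev$true_source & dm$assigned != 0)
  expect_lt(abs(mis - crosstalk_fraction(3e-9, 6.25e-9)), 0.01)
})

test_that("crosstalk fraction has the right value and limits", {
  # frozen from a periodic-window numeric integration oracle
  expect_equal(crosstalk_fraction(3e-9, 6.25e-9), 0.1107273,
               tolerance = 1e-6)
  expect_lt(crosstalk_fraction(1e-12, 6.25e-9), 1e-10)
  expect_equal(crosstalk_fraction(1e-3, 6.25e-9), 0.5, tolerance = 1e-3)
  expect_true(all(diff(crosstalk_fraction(seq(0.5, 20, 0.5) * 1e-9,
                                          6.25e-9)) > 0))
})

test_that("single-pathway illumination leaks the crosstalk fraction", {
  sim <- simulate_demux_acquisition(rep(0, 3000), rep(4, 3000), seed = 7)
  expect_equal(sum(sim$truth1), 0)
  leak <- sum(sim$counts1) / (sum(sim$counts1) + sum(sim$counts2))
  expect_lt(abs(leak - crosstalk_fraction(3e-9, 6.25e-9)), 0.01)
  # both-pathway truth bookkeeping
  sim2 <- simulate_demux_acquisition(rep(2, 500), rep(2, 500), seed = 8)
  expect_equal(sum(sim2$truth1) + sum(sim2$truth2),
               length(sim2$events$times_s) - sim2$n_dropped)
})
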