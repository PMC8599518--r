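# Temporal multiplexing of two excitation pulse trains and event-level
# photon demultiplexing.  Two 80 MHz trains offset by half a pulse period
# (6.25 ns) interleave to an effective 160 MHz comb; detected photons are
# assigned back to an excitation pathway by their arrival phase.  Photons
# emitted late in the fluorescence-lifetime tail spill into the other
# pathway's time gate, producing crosstalk.

#' Vacuum speed of light (m/s)
#' @keywords internal
SPEED_OF_LIGHT_M_S <- 299792458

#' Excitation pulse train
#'
#' Regular comb of laser pulses: `times = offset + k / rep_rate`,
#' `k = 0 .. n_pulses - 1`.
#'
#' @param rep_rate_hz Repetition rate in Hz (default 80 MHz).
#' @param offset_s Temporal offset of the first pulse (s).
#' @param n_pulses Number of pulses.
#' @param source Integer pathway label carried through to emitted photons.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(rep_rate_hz = 80e6, offset_s = 0, n_pulses,
                        source = 1L) {
  stopifnot(rep_rate_hz > 0, n_pulses >= 0)
  structure(
    list(rep_rate_hz = rep_rate_hz, offset_s = offset_s,
         n_pulses = as.integer(n_pulses), source = as.integer(source)),
    class = "pulse_train")
}

#' Pulse times of a train
#' @param train A [pulse_train()].
#' @return Strictly increasing numeric vector of pulse times (s).
#' @export
pulse_times <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  train$offset_s + (seq_len(train$n_pulses) - 1L) / train$rep_rate_hz
}

#' Optical delay from extra path length
#'
#' Delay imparted by routing one beam through an additional free-space path:
#' `length / c`.  A 1.875 m delay arm yields 6.25 ns, half of an 80 MHz
#' pulse period.
#'
#' @param extra_path_m Additional path length in metres (>= 0).
#' @return Delay in seconds.
#' @examples
#' delay_from_path_length(1.875) * 1e9   # 6.25 ns
#' @export
delay_from_path_length <- function(extra_path_m) {
  if (any(extra_path_m < 0)) stop("path length must be non-negative")
  extra_path_m / SPEED_OF_LIGHT_M_S
}

#' Interleave two pulse trains
#'
#' Merges two equal-rate trains into a single sorted comb with source
#' labels.  When the offset difference equals half the pulse period the
#' merged comb is evenly spaced at twice the repetition rate (two 80 MHz
#' trains offset 6.25 ns give 160 MHz); any other offset leaves alternating
#' unequal gaps, flagged as uneven.
#'
#' @param a,b [pulse_train()] objects with equal repetition rates.
#' @param tol Even-spacing tolerance as a fraction of the pulse period
#'   (default 0.01: a delay arm within 1% of the half period counts as
#'   evenly interleaved).
#' @return List with `times_s`, `source` (per pulse), `effective_rate_hz`,
#'   `evenly_spaced` flag and `gap_s` (the distinct inter-pulse gaps).
#' @export
interleave_trains <- function(a, b, tol = 0.01) {
  stopifnot(inherits(a, "pulse_train"), inherits(b, "pulse_train"))
  if (abs(a$rep_rate_hz - b$rep_rate_hz) >
      1e-9 * max(a$rep_rate_hz, b$rep_rate_hz)) {
    stop("pulse trains must share a repetition rate to interleave")
  }
  ta <- pulse_times(a); tb <- pulse_times(b)
  times <- c(ta, tb)
  source <- c(rep(a$source, length(ta)), rep(b$source, length(tb)))
  ord <- order(times)
  times <- times[ord]; source <- source[ord]
  period <- 1 / a$rep_rate_hz
  doff <- abs(b$offset_s - a$offset_s) %% period
  even <- abs(doff - period / 2) <= tol * period
  eff <- if (even) 2 * a$rep_rate_hz else a$rep_rate_hz
  gaps <- if (length(times) > 1L) unique(round(diff(times), 15)) else numeric()
  list(times_s = times, source = source,
       effective_rate_hz = eff, evenly_spaced = even, gap_s = gaps)
}

#' Fluorescence emission model
#'
#' Single-exponential fluorescence decay with lifetime `tau` and a mean
#' photon yield per excitation pulse.  The default lifetime, 3.0 ns, is
#' typical of GFP-family indicators such as GCaMP.
#'
#' @param lifetime_s Fluorescence decay constant tau (s), > 0.
#' @param rate_per_pulse Mean detected photons per excitation pulse, >= 0.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(lifetime_s = 3e-9, rate_per_pulse = 0.1) {
  stopifnot(lifetime_s > 0, rate_per_pulse >= 0)
  structure(list(lifetime_s = lifetime_s, rate_per_pulse = rate_per_pulse),
            class = "emission_model")
}

#' Simulate stochastic fluorescence photon events
#'
#' For each excitation pulse, draws `Poisson(rate_per_pulse)` photons, each
#' detected at the pulse time plus an `Exp(tau)` fluorescence delay.  The
#' originating pathway of every photon is recorded as ground truth.
#'
#' @param pulses Merged train as returned by [interleave_trains()], or a
#'   single [pulse_train()].
#' @param model An [emission_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `photon_event_list`: list with sorted
#'   `times_s` and integer `true_source` per event.
#' @export
simulate_emission <- function(pulses, model, seed = NULL) {
  stopifnot(inherits(model, "emission_model"))
  if (inherits(pulses, "pulse_train")) {
    pulses <- list(times_s = pulse_times(pulses),
                   source = rep(pulses$source, pulses$n_pulses))
  }
  if (!is.null(seed)) set.seed(seed)
  n_pulse <- length(pulses$times_s)
  counts <- stats::rpois(n_pulse, model$rate_per_pulse)
  n_ev <- sum(counts)
  if (n_ev == 0L) {
    return(structure(list(times_s = numeric(), true_source = integer()),
                     class = "photon_event_list"))
  }
  t0 <- rep(pulses$times_s, counts)
  src <- rep(pulses$source, counts)
  times <- t0 + stats::rexp(n_ev, rate = 1 / model$lifetime_s)
  ord <- order(times)
  structure(list(times_s = times[ord], true_source = src[ord]),
            class = "photon_event_list")
}

#' Demultiplexing gate definition
#'
#' Time gates that tile each `2 * delta` excitation period with two
#' channel windows of width `delta`, anchored at `t0` (a pathway-1 pulse
#' time).  Within each window, the final `veto_width` seconds are blanked
#' (vetoed): photons arriving there — where lifetime-tail spillover is
#' concentrated near the next pulse — are counted in neither channel.
#'
#' @param delta_s Inter-train offset / channel window width (default
#'   6.25 ns).
#' @param veto_width_s Blanked window width, `0 <= veto < delta`.
#' @param t0_s Gate phase reference (pathway-1 pulse time).
#' @return An object of class `demux_gates`.
#' @export
demux_gates <- function(delta_s = 6.25e-9, veto_width_s = 0, t0_s = 0) {
  stopifnot(delta_s > 0)
  if (veto_width_s < 0 || veto_width_s >= delta_s) {
    stop("veto width must satisfy 0 <= veto_width < delta")
  }
  structure(list(delta_s = delta_s, veto_width_s = veto_width_s, t0_s = t0_s),
            class = "demux_gates")
}

#' Demultiplex photon events into two channels
#'
#' Assigns each detected photon to channel 1 or 2 by the parity of
#' `floor((t - t0) / delta)` within the `2 * delta` pulse period, vetoing
#' photons inside the blanked sub-window, and bins assigned photons into
#' per-pixel counts using a pixel clock.  Events are conserved:
#' `ch1 + ch2 + vetoed + dropped = total`.
#'
#' @param events A `photon_event_list` (see [simulate_emission()]).
#' @param gates A [demux_gates()].
#' @param pixel_edges Strictly increasing numeric vector of pixel-bin edges
#'   (s); `length(pixel_edges) - 1` pixels.  Events outside the clock are
#'   dropped and counted.
#' @return List with integer vectors `counts1`, `counts2` (per pixel),
#'   scalars `n_veto`, `n_dropped`, and `assigned` (per-event channel:
#'   1, 2, or 0 for vetoed; dropped events keep their channel label but are
#'   excluded from the count images).
#' @export
demultiplex <- function(events, gates, pixel_edges) {
  stopifnot(inherits(events, "photon_event_list"),
            inherits(gates, "demux_gates"))
  if (length(pixel_edges) < 2L || any(diff(pixel_edges) <= 0)) {
    stop("pixel_edges must be strictly increasing with at least two edges")
  }
  n_px <- length(pixel_edges) - 1L
  t <- events$times_s
  n <- length(t)
  if (n == 0L) {
    return(list(counts1 = integer(n_px), counts2 = integer(n_px),
                n_veto = 0L, n_dropped = 0L, assigned = integer()))
  }
  phase <- (t - gates$t0_s) %% (2 * gates$delta_s)
  win <- ifelse(phase < gates$delta_s, 1L, 2L)
  in_window <- phase %% gates$delta_s
  veto <- in_window >= gates$delta_s - gates$veto_width_s
  assigned <- ifelse(veto, 0L, win)
  px <- findInterval(t, pixel_edges, rightmost.closed = TRUE)
  inside <- px >= 1L & px <= n_px
  dropped <- !inside
  keep1 <- inside & assigned == 1L
  keep2 <- inside & assigned == 2L
  counts1 <- tabulate(px[keep1], nbins = n_px)
  counts2 <- tabulate(px[keep2], nbins = n_px)
  list(counts1 = counts1, counts2 = counts2,
       n_veto = sum(veto & inside), n_dropped = sum(dropped),
       assigned = as.integer(assigned))
}

#' Steady-state lifetime crosstalk between channels
#'
#' Probability that a photon excited at a channel's pulse, with exponential
#' decay constant `tau`, is detected inside the other channel's window of
#' the periodic `2 * delta` gate structure:
#' \deqn{(e^{-\Delta/\tau} - e^{-2\Delta/\tau}) / (1 - e^{-2\Delta/\tau}).}
#' Tends to 0 for instantaneous decay and to 1/2 (uniform phase) as
#' `tau` grows.
#'
#' @param tau_s Fluorescence lifetime (s), > 0.
#' @param delta_s Channel window width (s), > 0.
#' @return Crosstalk fraction in `[0, 0.5)`.
#' @examples
#' crosstalk_fraction(3e-9, 6.25e-9)   # ~0.111
#' @export
crosstalk_fraction <- function(tau_s, delta_s) {
  stopifnot(all(tau_s > 0), all(delta_s > 0))
  r <- exp(-delta_s / tau_s)
  r2 <- exp(-2 * delta_s / tau_s)
  (r - r2) / (1 - r2)
}
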