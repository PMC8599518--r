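# Calcium trace analysis on segmented ROIs: extraction with annulus
# neuropil estimates, neuropil subtraction, dF/F, transient SNR,
# non-negative AR(2) spike deconvolution, and distance-binned pairwise
# Pearson correlations.  Segmentation itself is out of scope: ROI masks
# are inputs (for phantom sessions they come from the ground truth).

#' ROI set
#'
#' Per-neuron soma pixel masks and neuropil annulus masks over an image
#' grid.  Annuli must exclude every soma mask.
#'
#' @param masks List of integer vectors: linear pixel indices (column-major
#'   into an `ny x nx` image) of each soma.
#' @param annuli List of integer vectors: annulus pixel indices per neuron.
#' @param centroids_um Matrix n x 2 of centroid positions (um).
#' @param dim_yx Length-2 image dimensions `c(ny, nx)`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, annuli, centroids_um, dim_yx) {
  stopifnot(length(masks) == length(annuli),
            nrow(centroids_um) == length(masks), length(dim_yx) == 2L)
  npx <- prod(dim_yx)
  all_px <- unlist(c(masks, annuli))
  if (length(all_px) && (min(all_px) < 1L || max(all_px) > npx)) {
    stop("mask pixels outside the image bounds")
  }
  if (any(lengths(masks) == 0L)) stop("empty soma mask")
  soma_all <- unique(unlist(masks))
  if (any(unlist(annuli) %in% soma_all)) {
    stop("annulus masks must exclude all soma masks")
  }
  structure(list(masks = masks, annuli = annuli,
                 centroids_um = centroids_um, dim_yx = as.integer(dim_yx)),
            class = "roi_set")
}

#' Ground-truth ROI set for a neuron-field phantom
#'
#' Builds soma masks (pixels within the soma radius of each centroid) and
#' neuropil annuli (a ring beyond a gap around the soma, excluding every
#' soma pixel in the field) on the rendering pixel grid.
#'
#' @param phantom A `neuron_field_phantom`.
#' @param pixel_pitch_um Rendering pixel pitch (um).
#' @param annulus_gap_um Gap between soma edge and annulus inner radius
#'   (default 4 um).
#' @param annulus_width_um Annulus radial width (default 10 um).
#' @return A [roi_set()].
#' @export
phantom_roi_set <- function(phantom, pixel_pitch_um = 4,
                            annulus_gap_um = 4, annulus_width_um = 10) {
  stopifnot(inherits(phantom, "neuron_field_phantom"))
  nx <- ceiling(phantom$area_um[1] / pixel_pitch_um)
  ny <- ceiling(phantom$area_um[2] / pixel_pitch_um)
  xs <- (seq_len(nx) - 0.5) * pixel_pitch_um
  ys <- (seq_len(ny) - 0.5) * pixel_pitch_um
  n <- nrow(phantom$positions_um)
  soma_occupied <- logical(ny * nx)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom$positions_um[i, ]; r <- phantom$radii_um[i]
    ix <- which(abs(xs - p[1]) <= r + pixel_pitch_um)
    iy <- which(abs(ys - p[2]) <= r + pixel_pitch_um)
    d2 <- outer((ys[iy] - p[2])^2, (xs[ix] - p[1])^2, "+")
    pix <- outer(iy, (ix - 1L) * ny, "+")[d2 <= r^2]
    if (length(pix) == 0L) {           # sub-pixel soma: take nearest pixel
      pix <- which.min(abs(ys - p[2])) +
        (which.min(abs(xs - p[1])) - 1L) * ny
    }
    masks[[i]] <- sort(pix)
    soma_occupied[pix] <- TRUE
  }
  annuli <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom$positions_um[i, ]; r <- phantom$radii_um[i]
    r_in <- r + annulus_gap_um
    r_out <- r_in + annulus_width_um
    ix <- which(abs(xs - p[1]) <= r_out + pixel_pitch_um)
    iy <- which(abs(ys - p[2]) <= r_out + pixel_pitch_um)
    d2 <- outer((ys[iy] - p[2])^2, (xs[ix] - p[1])^2, "+")
    sel <- d2 > r_in^2 & d2 <= r_out^2
    pix <- outer(iy, (ix - 1L) * ny, "+")[sel]
    annuli[[i]] <- sort(pix[!soma_occupied[pix]])
  }
  roi_set(masks, annuli, phantom$positions_um, c(ny, nx))
}

#' Extract raw and neuropil fluorescence traces
#'
#' Per-frame mean over each soma mask and each annulus.
#'
#' @param movie Array `[ny, nx, frames]` (or a matrix `pixels x frames`
#'   in column-major pixel order).
#' @param rois A [roi_set()].
#' @param frame_rate_hz Frame rate stored with the traces (default 1).
#' @return An object of class `trace_set`: list with `raw`, `neuropil`
#'   (n x frames matrices), `frame_rate_hz`, `corrected = NULL`.
#' @export
extract_traces <- function(movie, rois, frame_rate_hz = 1) {
  stopifnot(inherits(rois, "roi_set"))
  if (length(dim(movie)) == 3L) {
    d <- dim(movie)
    if (!all(d[1:2] == rois$dim_yx)) {
      stop("movie dimensions do not match the ROI set")
    }
    dim(movie) <- c(d[1] * d[2], d[3])
  }
  n <- length(rois$masks)
  raw <- matrix(0, n, ncol(movie))
  np <- matrix(0, n, ncol(movie))
  for (i in seq_len(n)) {
    raw[i, ] <- colMeans(movie[rois$masks[[i]], , drop = FALSE])
    ai <- rois$annuli[[i]]
    np[i, ] <- if (length(ai)) colMeans(movie[ai, , drop = FALSE]) else 0
  }
  structure(list(raw = raw, neuropil = np, corrected = NULL,
                 frame_rate_hz = frame_rate_hz),
            class = "trace_set")
}

#' Neuropil subtraction
#'
#' Removes the annulus-estimated neuropil contamination from each soma
#' trace: `corrected = raw - r * neuropil`, elementwise (linear in both
#' inputs).
#'
#' @param traces A `trace_set` (or a matrix; then `neuropil` must be a
#'   matching matrix).
#' @param r Contamination coefficient in `[0, 1]` (default 0.7).
#' @param neuropil Neuropil matrix when `traces` is a matrix.
#' @return The `trace_set` with `corrected` filled (or the corrected
#'   matrix).
#' @export
neuropil_subtract <- function(traces, r = 0.7, neuropil = NULL) {
  stopifnot(r >= 0, r <= 1)
  if (inherits(traces, "trace_set")) {
    traces$corrected <- traces$raw - r * traces$neuropil
    traces$neuropil_r <- r
    return(traces)
  }
  if (is.null(neuropil) || !all(dim(traces) == dim(neuropil))) {
    stop("matrix input requires a neuropil matrix of identical shape")
  }
  traces - r * neuropil
}

#' Fractional fluorescence change (dF/F)
#'
#' `(F - F0) / F0` with a rolling low-percentile baseline `F0` (default
#' the 20th percentile over a 60 s window).  The rolling quantile is
#' evaluated on a decimated grid and linearly interpolated.
#'
#' @param traces Matrix n x frames (e.g. the `corrected` field of a
#'   `trace_set`), or a `trace_set` (uses `corrected` if present, else
#'   `raw`).
#' @param frame_rate_hz Frame rate (Hz).
#' @param baseline_quantile Baseline percentile (default 0.2).
#' @param window_s Rolling window length (default 60 s).
#' @param step_frames Decimation step for the rolling quantile (default
#'   25).
#' @return Matrix of dF/F values, with the baseline in attribute
#'   `"baseline"`.
#' @export
delta_f_over_f <- function(traces, frame_rate_hz,
                           baseline_quantile = 0.2, window_s = 60,
                           step_frames = 25L) {
  if (inherits(traces, "trace_set")) {
    frame_rate_hz <- traces$frame_rate_hz
    traces <- if (!is.null(traces$corrected)) traces$corrected else traces$raw
  }
  traces <- as.matrix(traces)
  T_ <- ncol(traces)
  w <- max(3L, round(window_s * frame_rate_hz))
  centers <- unique(c(seq(1L, T_, by = step_frames), T_))
  f0 <- matrix(0, nrow(traces), T_)
  for (i in seq_len(nrow(traces))) {
    q <- vapply(centers, function(ct) {
      lo <- max(1L, ct - w %/% 2L); hi <- min(T_, ct + w %/% 2L)
      stats::quantile(traces[i, lo:hi], baseline_quantile, names = FALSE)
    }, numeric(1))
    f0[i, ] <- if (length(centers) > 1L) {
      stats::approx(centers, q, xout = seq_len(T_), rule = 2)$y
    } else rep(q, T_)
  }
  f0 <- pmax(f0, 1e-9)
  out <- (traces - f0) / f0
  attr(out, "baseline") <- f0
  out
}

#' Detect calcium transients in a dF/F trace
#'
#' Frames where dF/F exceeds `threshold_sd` robust noise SDs (noise from
#' the median absolute deviation of first differences).  Runs shorter
#' than `min_frames` are discarded: indicator transients persist for many
#' frames (GCaMP6s decays over ~1.5 s), whereas isolated suprathreshold
#' frames are noise.
#'
#' @param dff Numeric dF/F trace.
#' @param threshold_sd Detection threshold in noise SDs (default 3).
#' @param min_frames Minimum transient duration in frames (default 3).
#' @return Logical transient mask with the noise SD in attribute
#'   `"noise_sd"`.
#' @export
detect_transients <- function(dff, threshold_sd = 3, min_frames = 3L) {
  sd_n <- stats::mad(diff(dff)) / sqrt(2)
  mask <- dff > threshold_sd * sd_n
  if (min_frames > 1L && any(mask)) {
    runs <- rle(as.vector(mask))
    runs$values[runs$values & runs$lengths < min_frames] <- FALSE
    mask <- inverse.rle(runs)
  }
  attr(mask, "noise_sd") <- sd_n
  mask
}

#' Transient signal-to-noise ratio
#'
#' Mean transient peak amplitude divided by the robust (MAD-based) SD of
#' the non-transient samples.  A trace with no detected transient yields
#' `NA` with a warning (flagged).
#'
#' @param dff Numeric dF/F trace.
#' @param transient_mask Logical mask of transient frames; detected via
#'   [detect_transients()] when missing.
#' @return SNR (dimensionless), or flagged `NA`.
#' @export
compute_snr <- function(dff, transient_mask = NULL) {
  if (is.null(transient_mask)) transient_mask <- detect_transients(dff)
  stopifnot(length(transient_mask) == length(dff))
  if (!any(transient_mask)) {
    warning("no transients detected; SNR undefined")
    return(NA_real_)
  }
  runs <- rle(as.vector(transient_mask))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- mapply(function(s, e) max(dff[s:e]),
                  starts[runs$values], ends[runs$values])
  noise <- dff[!transient_mask]
  sd_n <- stats::mad(noise, center = stats::median(noise))
  if (sd_n <= 0) {
    warning("degenerate noise estimate; SNR undefined")
    return(NA_real_)
  }
  mean(peaks) / sd_n
}

#' Second-order autoregressive indicator kernel
#'
#' Discrete AR(2) impulse response equivalent to a double-exponential
#' calcium indicator (rise `rise_s`, decay `decay_s`) sampled at
#' `frame_rate_hz`: coefficients `g1 = d + r`, `g2 = -d r` with
#' `d = exp(-1 / (rate * decay))`, `r = exp(-1 / (rate * rise))`.
#'
#' @param frame_rate_hz Frame rate (Hz), > 0.
#' @param rise_s Rise time constant (default 0.18 s, GCaMP6s-like).
#' @param decay_s Decay time constant (default 1.5 s).
#' @param length_out Kernel length in frames (default: until the response
#'   falls below 0.1% of its peak).
#' @return List with `g1`, `g2`, `h` (impulse response, `h[1] = 1`),
#'   `peak` (max of `h`) and `peak_lag`.
#' @export
ar2_kernel <- function(frame_rate_hz, rise_s = 0.18, decay_s = 1.5,
                       length_out = NULL) {
  stopifnot(frame_rate_hz > 0, rise_s > 0, decay_s > rise_s)
  d <- exp(-1 / (frame_rate_hz * decay_s))
  r <- exp(-1 / (frame_rate_hz * rise_s))
  if (is.null(length_out)) {
    length_out <- max(10L, ceiling(frame_rate_hz * decay_s * 8))
  }
  k <- seq_len(length_out)
  h <- (d^k - r^k) / (d - r)
  h <- h / 1                     # h[1] = 1 by construction
  list(g1 = d + r, g2 = -d * r, h = h, peak = max(h),
       peak_lag = which.max(h), d = d, r = r)
}

#' Calcium traces from spike trains
#'
#' Convolves per-frame spike counts with the AR(2) double-exponential
#' indicator kernel (via the AR recursion), scaled so one spike produces a
#' peak response of `amplitude`.
#'
#' @param spikes Matrix n x frames of spike counts (or a vector).
#' @param frame_rate_hz Frame rate (Hz).
#' @param rise_s,decay_s Indicator kinetics (s).
#' @param amplitude Peak response per spike (default 1).
#' @return Matrix (or vector) of calcium responses.
#' @export
calcium_traces_from_spikes <- function(spikes, frame_rate_hz,
                                       rise_s = 0.18, decay_s = 1.5,
                                       amplitude = 1) {
  ker <- ar2_kernel(frame_rate_hz, rise_s, decay_s)
  vec <- is.null(dim(spikes))
  spikes <- rbind(spikes)
  scale <- amplitude / ker$peak
  out <- t(apply(spikes * scale, 1L, function(s) {
    as.numeric(stats::filter(s, c(ker$g1, ker$g2), method = "recursive"))
  }))
  if (vec) out[1, ] else out
}

#' Non-negative AR(2) spike deconvolution
#'
#' Deterministic sparse deconvolution of dF/F traces against the AR(2)
#' indicator impulse response: greedy matching pursuit that repeatedly
#' places a non-negative spike at the position of maximum correlation
#' between the residual and the kernel, until the best amplitude falls
#' below `threshold_sd` times the amplitude noise level (robust noise from
#' first differences).  Nearby events (within `merge_frames`) are merged.
#'
#' @param traces Matrix n x frames of dF/F (or corrected) traces, or a
#'   vector.
#' @param frame_rate_hz Frame rate (Hz), > 0.
#' @param rise_s,decay_s Indicator kinetics (s).
#' @param threshold_sd Stopping threshold in amplitude noise SDs
#'   (default 3).
#' @param merge_frames Merge window for adjacent events (default 1).
#' @param refine_passes Cyclic refinement passes: each placed event is
#'   removed and re-localized against the residual, which corrects the
#'   timing errors greedy pursuit makes on overlapping transients
#'   (default 3).
#' @param min_rel_amplitude Events smaller than this fraction of the
#'   largest placed event are discarded (default 0.05).
#' @param max_events Safety cap on events per trace.
#' @return An object of class `spike_set`: list with `amplitudes`
#'   (n x frames, non-negative), `ar` (kernel parameters),
#'   `r_squared` (per-trace variance explained by the reconstruction).
#' @export
infer_spikes <- function(traces, frame_rate_hz, rise_s = 0.18,
                         decay_s = 1.5, threshold_sd = 3,
                         merge_frames = 1L, refine_passes = 3L,
                         min_rel_amplitude = 0.05, max_events = NULL) {
  stopifnot(frame_rate_hz > 0)
  vec <- is.null(dim(traces))
  traces <- rbind(traces)
  if (any(!is.finite(traces))) stop("traces contain non-finite values")
  n <- nrow(traces); T_ <- ncol(traces)
  ker <- ar2_kernel(frame_rate_hz, rise_s, decay_s)
  h <- ker$h / ker$peak          # unit-peak kernel: amplitudes are in dF/F
  L <- length(h)
  h2 <- sum(h^2)
  # kernel autocorrelation for local cross-correlation updates
  ac <- vapply(-(L - 1L):(L - 1L), function(dl) {
    i <- seq_len(L); j <- i + dl
    ok <- j >= 1L & j <= L
    sum(h[i[ok]] * h[j[ok]])
  }, numeric(1))
  if (is.null(max_events)) max_events <- max(10L, T_ %/% 2L)
  amps <- matrix(0, n, T_)
  r2 <- numeric(n)
  for (i in seq_len(n)) {
    y <- traces[i, ]
    sd_amp <- (stats::mad(diff(y)) / sqrt(2)) / sqrt(h2)
    thr <- threshold_sd * sd_amp
    # cross-correlation c[t] = sum_j h[j] y[t + j - 1]
    ypad <- c(y, rep(0, L))
    cc <- rev(stats::filter(rev(ypad), h, method = "convolution",
                            sides = 1))[seq_len(T_)]
    cc[!is.finite(cc)] <- -Inf
    a_vec <- numeric(T_)
    place <- function(j, a) {         # add an event, updating cc locally
      a_vec[j] <<- a_vec[j] + a
      lo <- max(1L, j - L + 1L); hi <- min(T_, j + L - 1L)
      cc[lo:hi] <<- cc[lo:hi] - a * ac[(lo:hi) - j + L]
    }
    greedy <- function() {
      for (it in seq_len(max_events)) {
        j <- which.max(cc)
        a <- cc[j] / h2
        if (!is.finite(a) || a <= 0 || a < thr) break
        place(j, a)
      }
    }
    greedy()
    # cyclic refinement: remove each event and re-localize it against the
    # residual; rescan for events freed up by the corrected placements
    for (pass in seq_len(refine_passes)) {
      ev <- which(a_vec > 0)
      if (length(ev) == 0L) break
      changed <- FALSE
      for (j in ev[order(-a_vec[ev])]) {
        a <- a_vec[j]
        if (a <= 0) next
        place(j, -a)                  # take the event out
        lo <- max(1L, j - L + 1L); hi <- min(T_, j + L - 1L)
        jj <- lo + which.max(cc[lo:hi]) - 1L
        a2 <- cc[jj] / h2
        if (is.finite(a2) && a2 >= thr) {
          place(jj, a2)
          if (jj != j) changed <- TRUE
        } else changed <- TRUE        # event dropped
      }
      greedy()
      if (!changed) break
    }
    if (any(a_vec > 0) && min_rel_amplitude > 0) {
      a_vec[a_vec < min_rel_amplitude * max(a_vec)] <- 0
    }
    # merge events closer than merge_frames (keep amplitude-weighted frame)
    ev <- which(a_vec > 0)
    if (length(ev) > 1L && merge_frames > 0L) {
      grp <- cumsum(c(1L, diff(ev) > merge_frames))
      merged <- numeric(T_)
      for (g in unique(grp)) {
        e <- ev[grp == g]
        w <- a_vec[e]
        merged[e[which.max(w)]] <- sum(w)
      }
      a_vec <- merged
    }
    amps[i, ] <- a_vec
    recon <- calcium_traces_from_spikes(a_vec, frame_rate_hz, rise_s,
                                        decay_s, amplitude = 1)
    ssr <- sum((y - recon)^2)
    sst <- sum((y - mean(y))^2)
    r2[i] <- if (sst > 0) 1 - ssr / sst else NA_real_
  }
  structure(list(amplitudes = if (vec) amps[1, , drop = TRUE] else amps,
                 ar = ker, frame_rate_hz = frame_rate_hz,
                 threshold_sd = threshold_sd, r_squared = r2),
            class = "spike_set")
}

#' Spike detection F1 score against ground truth
#'
#' Greedy one-to-one matching of inferred events to true spikes within a
#' frame tolerance, aggregated over neurons (micro-averaged).
#'
#' @param inferred `spike_set` or amplitude matrix n x frames.
#' @param truth Matrix n x frames of true spike counts.
#' @param tol_frames Matching window (default 2 frames).
#' @param min_amplitude Amplitude below which inferred events are ignored
#'   (default 0: all events count).
#' @param split_by_amplitude Treat an event of amplitude `a` as
#'   `round(a / unit)` coincident spikes, where `unit` is the neuron's
#'   median event amplitude, so merged multi-spike transients can match
#'   several true spikes (default TRUE).
#' @return List with `f1`, `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
spike_f1 <- function(inferred, truth, tol_frames = 2L, min_amplitude = 0,
                     split_by_amplitude = TRUE) {
  if (inherits(inferred, "spike_set")) inferred <- inferred$amplitudes
  inferred <- rbind(inferred); truth <- rbind(truth)
  stopifnot(all(dim(inferred) == dim(truth)))
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    ev <- which(inferred[i, ] > min_amplitude)
    if (split_by_amplitude && length(ev)) {
      unit <- stats::median(inferred[i, ev])
      # conservative split: a second token needs ~1.75x the unit amplitude
      mult <- pmax(1L, round(inferred[i, ev] / unit - 0.25))
      ev <- rep(ev, mult)
    }
    ev <- ev[order(-inferred[i, ev])]
    tr <- rep(which(truth[i, ] > 0), truth[i, truth[i, ] > 0])
    used <- logical(length(tr))
    for (e in ev) {
      d <- abs(tr - e)
      d[used] <- Inf
      if (length(d) && min(d) <= tol_frames) {
        used[which.min(d)] <- TRUE
        tp <- tp + 1L
      } else fp <- fp + 1L
    }
    fn <- fn + sum(!used)
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  list(f1 = f1, precision = prec, recall = rec, tp = tp, fp = fp, fn = fn)
}

#' Distance-binned pairwise correlation profile
#'
#' Pearson correlations between all unordered pairs of spike trains,
#' binned by centroid distance.  Pairs with a constant train (undefined
#' correlation) or beyond the last bin edge are excluded and counted, so
#' binned pair counts plus exclusions always total `n (n - 1) / 2`.
#'
#' A `spike_set` is converted to per-frame event trains (1 where an event
#' was inferred): the deconvolution returns discrete spike events, and
#' correlating event trains rather than amplitude-weighted vectors avoids
#' attenuating coincidences by amplitude noise.
#'
#' @param spikes `spike_set`, or matrix n x frames of spike counts /
#'   amplitudes.
#' @param positions_um Matrix n x 2 of neuron positions (um).
#' @param bin_edges_um Distance bin edges (default 0 to 4000 um in 40 um
#'   bins).
#' @param coincidence_frames Half-width (frames) of the coincidence
#'   window (default 0: strict frame resolution, plain Pearson).  With a
#'   window of `w`, the statistic is the cross-correlogram area
#'   `sum_{|l| <= w} cov(x_i(t), x_j(t + l))` normalized by the raw
#'   standard deviations (symmetrized).  For trains whose coincidences
#'   are exactly synchronous this equals the plain Pearson correlation;
#'   it additionally gives full credit to coincidences jittered by up to
#'   `w` frames, making the profile robust to spike-timing errors of the
#'   deconvolution.
#' @return An object of class `correlation_profile`: data.frame with
#'   `bin_lo_um`, `bin_hi_um`, `bin_mid_um`, `mean_corr`, `sd_corr`,
#'   `n_pairs`; attributes `n_excluded_constant`, `n_excluded_range`,
#'   `n_total_pairs`.
#' @export
correlation_profile <- function(spikes, positions_um,
                                bin_edges_um = seq(0, 4000, by = 40),
                                coincidence_frames = 0L) {
  if (inherits(spikes, "spike_set")) {
    spikes <- (rbind(spikes$amplitudes) > 0) * 1L
  }
  spikes <- rbind(spikes)
  n <- nrow(spikes)
  if (n < 2L) stop("at least two neurons are required")
  stopifnot(nrow(positions_um) == n, length(bin_edges_um) >= 2L)
  if (coincidence_frames > 0L) {
    T_ <- ncol(spikes)
    Xc <- spikes - rowMeans(spikes)
    sm <- t(apply(spikes, 1L, function(x) {
      s <- as.numeric(stats::filter(x, rep(1, 2L * coincidence_frames + 1L),
                                    sides = 2))
      s[is.na(s)] <- 0
      s
    }))
    Sc <- sm - rowMeans(sm)
    sds <- sqrt(rowSums(Xc^2) / (T_ - 1))
    M <- (Xc %*% t(Sc)) / (T_ - 1)
    denom <- outer(sds, sds)
    R <- (M + t(M)) / (2 * denom)
    R[!is.finite(R)] <- NA_real_
  } else {
    sds <- apply(spikes, 1L, stats::sd)
    R <- suppressWarnings(stats::cor(t(spikes)))
  }
  D <- as.matrix(stats::dist(positions_um))
  iu <- which(upper.tri(R))
  rr <- R[iu]; dd <- D[iu]
  bad <- !is.finite(rr)
  n_total <- n * (n - 1L) / 2L
  bin <- findInterval(dd, bin_edges_um, rightmost.closed = TRUE)
  in_range <- bin >= 1L & bin <= length(bin_edges_um) - 1L
  n_excl_range <- sum(in_range & bad) * 0L + sum(!in_range & !bad)
  use <- in_range & !bad
  nb <- length(bin_edges_um) - 1L
  mean_c <- sd_c <- rep(NA_real_, nb)
  counts <- tabulate(bin[use], nbins = nb)
  for (b in which(counts > 0L)) {
    v <- rr[use & bin == b]
    mean_c[b] <- mean(v)
    sd_c[b] <- stats::sd(v)
  }
  out <- data.frame(
    bin_lo_um = bin_edges_um[-length(bin_edges_um)],
    bin_hi_um = bin_edges_um[-1],
    bin_mid_um = (bin_edges_um[-1] + bin_edges_um[-length(bin_edges_um)]) / 2,
    mean_corr = mean_c, sd_corr = sd_c, n_pairs = counts)
  attr(out, "n_excluded_constant") <- sum(bad)
  attr(out, "n_excluded_range") <- sum(!in_range & !bad)
  attr(out, "n_total_pairs") <- n_total
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Number of unordered neuron pairs
#' @param n Neuron count.
#' @return `n * (n - 1) / 2`.
#' @export
n_pairwise <- function(n) n * (n - 1) / 2

#' Rebin spike trains into coarser count bins
#'
#' Sums per-frame counts over consecutive groups of `b` frames (trailing
#' frames that do not fill a bin are dropped).  For trains whose
#' correlations live at zero lag, Pearson correlations of the binned
#' counts are unchanged in expectation.
#'
#' @param spikes Matrix n x frames.
#' @param b Frames per bin (>= 1).
#' @return Matrix n x floor(frames / b).
#' @export
bin_spike_counts <- function(spikes, b) {
  spikes <- rbind(spikes)
  b <- as.integer(b)
  stopifnot(b >= 1L)
  if (b == 1L) return(spikes)
  nb <- ncol(spikes) %/% b
  if (nb < 2L) stop("fewer than two bins; reduce the bin width")
  arr <- array(spikes[, seq_len(nb * b)], dim = c(nrow(spikes), b, nb))
  apply(arr, c(1, 3), sum)
}

#' Run a full phantom calcium session
#'
#' End-to-end pipeline on a neuron-field phantom: render the movie in
#' chunks (streaming, so the full movie is never held in memory), extract
#' soma and annulus traces, neuropil-subtract, compute dF/F, deconvolve
#' spikes, and bin pairwise correlations by distance.
#'
#' @param phantom A `neuron_field_phantom`.
#' @param pixel_pitch_um Rendering pixel pitch (default 4 um).
#' @param r_neuropil Neuropil subtraction coefficient (default 0.7).
#' @param soma_peak_counts,baseline_counts,dff_per_spike,neuropil_frac
#'   Rendering parameters, see the neuron-field [render_movie()] method.
#' @param bin_edges_um Distance bins for the correlation profile (default
#'   0 to the field diagonal in 40 um steps).
#' @param threshold_sd Deconvolution threshold (default 3).
#' @param count_bin_s Width (s) of the spike-count bins used for the
#'   pairwise correlations (default 1 s, the standard window for cortical
#'   spike-count correlations).  Counting inferred events in ~1 s bins
#'   absorbs the deconvolution's one-frame timing ambiguity; for
#'   frame-synchronous trains the binned Pearson correlation is unbiased.
#' @param seed Optional integer seed for the rendering noise.
#' @return List with `traces` (`trace_set`), `dff`, `spikes`
#'   (`spike_set`), `profile` (`correlation_profile`), `rois`, `snr`
#'   (per-neuron transient SNR), and the phantom.
#' @export
run_phantom_session <- function(phantom, pixel_pitch_um = 4,
                                r_neuropil = 0.7, soma_peak_counts = 20,
                                baseline_counts = 1, dff_per_spike = 1,
                                neuropil_frac = 0.3,
                                bin_edges_um = NULL, threshold_sd = 3,
                                count_bin_s = 1, seed = NULL) {
  stopifnot(inherits(phantom, "neuron_field_phantom"))
  rois <- phantom_roi_set(phantom, pixel_pitch_um)
  n <- length(rois$masks)
  n_frames <- ncol(phantom$spikes)
  raw <- matrix(0, n, n_frames)
  np <- matrix(0, n, n_frames)
  grab <- function(idx, chunk) {
    ts <- extract_traces(chunk, rois, phantom$frame_rate_hz)
    raw[, idx] <<- ts$raw
    np[, idx] <<- ts$neuropil
  }
  render_movie(phantom, pixel_pitch_um = pixel_pitch_um,
               baseline_counts = baseline_counts,
               soma_peak_counts = soma_peak_counts,
               dff_per_spike = dff_per_spike,
               neuropil_frac = neuropil_frac,
               frame_callback = grab, seed = seed)
  traces <- structure(list(raw = raw, neuropil = np, corrected = NULL,
                           frame_rate_hz = phantom$frame_rate_hz),
                      class = "trace_set")
  traces <- neuropil_subtract(traces, r_neuropil)
  dff <- delta_f_over_f(traces$corrected, phantom$frame_rate_hz)
  spikes <- infer_spikes(dff, phantom$frame_rate_hz,
                         threshold_sd = threshold_sd)
  if (is.null(bin_edges_um)) {
    diag_um <- sqrt(sum(phantom$area_um^2))
    bin_edges_um <- seq(0, 40 * ceiling(diag_um / 40), by = 40)
  }
  events <- (spikes$amplitudes > 0) * 1L
  b <- max(1L, round(phantom$frame_rate_hz * count_bin_s))
  binned <- bin_spike_counts(events, b)
  profile <- correlation_profile(binned, phantom$positions_um, bin_edges_um)
  snr <- vapply(seq_len(n), function(i) {
    suppressWarnings(compute_snr(dff[i, ]))
  }, numeric(1))
  list(traces = traces, dff = dff, spikes = spikes, profile = profile,
       rois = rois, snr = snr, phantom = phantom,
       pixel_pitch_um = pixel_pitch_um)
}
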