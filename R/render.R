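# Image formation: phantom brightness fields convolved with the Gaussian
# PSF, weighted by per-pixel excitation (pulses per pixel along the
# resonant axis), and Poisson shot-noise sampled.  Images are matrices
# indexed [y, x]; movies and stacks are arrays with frames / planes on the
# last dimension unless stated otherwise.

#' Per-pixel excitation weights for a raster job
#'
#' Expected laser pulses delivered to each x pixel of a line.  In
#' `"resonant"` scan mode this is the sinusoidal pulses-per-pixel profile
#' (minimal at the line centre); in `"galvo"` mode the same total number
#' of active-line pulses is spread uniformly.
#'
#' @param job A [raster_job()].
#' @param cfg A [resonant_config()].
#' @param rep_rate_hz Laser repetition rate (default 80 MHz).
#' @return Numeric vector of length `pixels_xy[1]`.
#' @export
pixel_pulse_weights <- function(job, cfg, rep_rate_hz = 80e6) {
  N <- job$pixels_xy[1]
  if (job$scan_mode == "resonant") {
    pulses_per_pixel(seq_len(N), cfg, N, rep_rate_hz)
  } else {
    total <- rep_rate_hz * asin(cfg$fill_fraction) / (pi * cfg$frequency)
    rep(total / N, N)
  }
}

#' Render raster frames of a static brightness field
#'
#' Pixel means are `brightness * rate_per_pulse * pulses_per_pixel`, then
#' Poisson sampled per frame.
#'
#' @param brightness Either a `[ny, nx]` matrix of relative brightness
#'   (already PSF-smoothed) or a function `f(x_mm, y_mm)` returning one,
#'   where the arguments are the pixel-centre coordinate vectors.
#' @param job A [raster_job()].
#' @param cfg A [resonant_config()].
#' @param emission An [emission_model()]; `rate_per_pulse` scales counts.
#' @param frames Number of frames (default `job$frames`).
#' @param rep_rate_hz Laser repetition rate (default 80 MHz).
#' @param seed Optional integer seed.
#' @return Array `[ny, nx, frames]` of photon counts, with the noise-free
#'   mean image attached as attribute `"mean_image"`.
#' @export
render_raster_frames <- function(brightness, job, cfg = default_scan_config(),
                                 emission = emission_model(),
                                 frames = job$frames, rep_rate_hz = 80e6,
                                 seed = NULL) {
  stopifnot(inherits(job, "raster_job"))
  if (!is.null(seed)) set.seed(seed)
  xs <- raster_pixel_centers_x(job)
  ys <- raster_pixel_centers_y(job)
  B <- if (is.function(brightness)) brightness(xs, ys) else brightness
  B <- as.matrix(B)
  if (!all(dim(B) == c(length(ys), length(xs)))) {
    stop("brightness must have dimensions [pixels_y, pixels_x]")
  }
  w <- pixel_pulse_weights(job, cfg, rep_rate_hz)
  mean_img <- B * emission$rate_per_pulse *
    matrix(w, nrow(B), ncol(B), byrow = TRUE)
  out <- array(stats::rpois(length(mean_img) * frames, rep(mean_img, frames)),
               dim = c(nrow(B), ncol(B), frames))
  attr(out, "mean_image") <- mean_img
  out
}

#' Render a movie of a phantom
#'
#' Generic image-formation entry point dispatching on the phantom class.
#' See [render_raster_frames()] (static fields),
#' [render_bead_stack()] (bead z-stacks) and the neuron-field method for
#' the underlying machinery.
#'
#' @param phantom A phantom object.
#' @param ... Method-specific arguments.
#' @return Method-dependent; see the individual methods.
#' @export
render_movie <- function(phantom, ...) UseMethod("render_movie")

#' @describeIn render_movie Renders the calibration grid through a raster
#'   job: the rectangular line pattern is convolved analytically with the
#'   lateral PSF, then sampled.  The grid spans the FOV centred on the
#'   origin.
#' @param job A [raster_job()].
#' @param psf A [psf_model()].
#' @param cfg A [resonant_config()].
#' @param emission An [emission_model()].
#' @param seed Optional integer seed.
#' @export
render_movie.line_grid_phantom <- function(phantom, job,
                                           psf = psf_model(),
                                           cfg = default_scan_config(),
                                           emission = emission_model(),
                                           seed = NULL, ...) {
  half <- phantom$extent_mm / 2
  brightness <- function(xs, ys) {
    if (phantom$orientation == "x") {
      prof <- line_grid_profile(phantom, xs + half, psf)
      matrix(prof, length(ys), length(xs), byrow = TRUE)
    } else {
      prof <- line_grid_profile(phantom, ys + half, psf)
      matrix(prof, length(ys), length(xs), byrow = FALSE)
    }
  }
  render_raster_frames(brightness, job, cfg, emission, seed = seed)
}

#' @describeIn render_movie Renders one focal plane through the bead
#'   volume (beads as PSF-shaped Gaussian spots over the background).
#' @param z_um Focal plane depth (um).
#' @param pixel_pitch_um Lateral pixel pitch (um).
#' @param peak_counts Mean counts at the centre of an in-focus bead.
#' @param background_counts Mean background counts per pixel.
#' @export
render_movie.bead_phantom <- function(phantom, z_um, pixel_pitch_um = 0.5,
                                      psf = psf_model(), peak_counts = 50,
                                      background_counts = 0.5,
                                      frames = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(pixel_pitch_um / 2, phantom$extent_um[1], by = pixel_pitch_um)
  ys <- seq(pixel_pitch_um / 2, phantom$extent_um[2], by = pixel_pitch_um)
  mean_img <- matrix(background_counts, length(ys), length(xs))
  for (b in seq_len(nrow(phantom$positions_um))) {
    p <- phantom$positions_um[b, ]
    axial <- exp(-(z_um - p[3])^2 / (2 * psf$axial_sigma_um^2))
    if (axial < 1e-6) next
    gx <- exp(-(xs - p[1])^2 / (2 * psf$lateral_sigma_um^2))
    gy <- exp(-(ys - p[2])^2 / (2 * psf$lateral_sigma_um^2))
    mean_img <- mean_img + peak_counts * axial * outer(gy, gx)
  }
  out <- array(stats::rpois(length(mean_img) * frames,
                            rep(mean_img, frames)),
               dim = c(length(ys), length(xs), frames))
  attr(out, "mean_image") <- mean_img
  out
}

#' Render a bead z-stack acquisition
#'
#' Emulates the bead-stack measurement protocol: the stage moves in
#' `stage_step_um` increments, the focal plane inside the specimen moves
#' `focus_factor` times further, and at each plane `frames_per_plane`
#' Poisson frames are acquired and averaged.  The PSF may be tilted in the
#' x-z plane to emulate a tilted focal shift.
#'
#' @param bead_xyz_um Length-3 true bead position (um).
#' @param psf A [psf_model()] (ground-truth widths).
#' @param pixel_pitch_um Lateral pixel pitch (default 0.2 um).
#' @param roi_half_um Lateral ROI half-width around the bead (default 4 um).
#' @param stage_step_um Stage step (default 0.5 um).
#' @param n_planes Number of planes (default 61, spanning ~ +/-10 um of
#'   focus travel about the bead).
#' @param focus_factor Focus-per-stage displacement factor (default 1.38).
#' @param frames_per_plane Frames averaged per plane (default 30).
#' @param peak_counts Mean single-frame counts at the bead centre.
#' @param background_counts Mean background counts per pixel per frame.
#' @param tilt_deg Tilt of the PSF's long (axial) axis in the x-z plane,
#'   degrees (default 0).
#' @param seed Optional integer seed.
#' @return A `bead_stack` object: list with `voxels` (array `[z, y, x]`
#'   of averaged counts), `stage_step_um`, `pixel_pitch_um`,
#'   `frames_averaged`, and ground-truth attributes `truth` (bead
#'   position, FWHMs, tilt).
#' @export
render_bead_stack <- function(bead_xyz_um = c(0, 0, 250),
                              psf = psf_model(), pixel_pitch_um = 0.2,
                              roi_half_um = 4, stage_step_um = 0.5,
                              n_planes = 61, focus_factor = 1.38,
                              frames_per_plane = 30, peak_counts = 50,
                              background_counts = 0.5, tilt_deg = 0,
                              seed = NULL) {
  stopifnot(n_planes >= 2, stage_step_um > 0, focus_factor > 0)
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(bead_xyz_um[1] - roi_half_um, bead_xyz_um[1] + roi_half_um,
            by = pixel_pitch_um)
  ys <- seq(bead_xyz_um[2] - roi_half_um, bead_xyz_um[2] + roi_half_um,
            by = pixel_pitch_um)
  k <- seq_len(n_planes) - (n_planes + 1) / 2
  zs <- bead_xyz_um[3] + k * stage_step_um * focus_factor
  th <- tilt_deg * pi / 180
  vox <- array(0, dim = c(n_planes, length(ys), length(xs)))
  gy <- exp(-(ys - bead_xyz_um[2])^2 / (2 * psf$lateral_sigma_um^2))
  for (iz in seq_len(n_planes)) {
    dx <- xs - bead_xyz_um[1]
    dz <- zs[iz] - bead_xyz_um[3]
    # rotate the PSF frame: positive tilt leans the axial axis toward +x
    u <- dx * cos(th) - dz * sin(th)     # lateral axis of the tilted PSF
    v <- dx * sin(th) + dz * cos(th)     # axial axis of the tilted PSF
    gx <- exp(-u^2 / (2 * psf$lateral_sigma_um^2) -
              v^2 / (2 * psf$axial_sigma_um^2))
    mean_img <- background_counts + peak_counts * outer(gy, gx)
    acc <- matrix(0, length(ys), length(xs))
    for (f in seq_len(frames_per_plane)) {
      acc <- acc + stats::rpois(length(mean_img), mean_img)
    }
    vox[iz, , ] <- acc / frames_per_plane
  }
  structure(
    list(voxels = vox, stage_step_um = stage_step_um,
         pixel_pitch_um = pixel_pitch_um,
         frames_averaged = as.integer(frames_per_plane),
         x_um = xs, y_um = ys, stage_index = k,
         truth = list(position_um = bead_xyz_um,
                      lateral_fwhm_um = psf$lateral_fwhm_um,
                      axial_fwhm_um = psf$axial_fwhm_um,
                      tilt_deg = tilt_deg, focus_factor = focus_factor)),
    class = "bead_stack")
}

#' @describeIn render_movie Renders a calcium-imaging movie of the neuron
#'   field.  Somatic footprints are Gaussian blobs (soma size convolved
#'   with the lateral PSF) modulated by each neuron's calcium trace
#'   (spikes convolved with a double-exponential indicator kernel); a
#'   smooth neuropil field at `neuropil_frac` of soma brightness,
#'   co-modulated by the population calcium signal, contaminates the whole
#'   frame.  Photon counts are Poisson.  For long sessions pass a
#'   `frame_callback` to stream chunks instead of storing the whole movie.
#' @param pixel_pitch_um Pixel pitch (um), default 4.
#' @param baseline_counts Mean background counts per pixel per frame.
#' @param soma_peak_counts Mean resting counts at a soma centre.
#' @param dff_per_spike Peak fractional fluorescence change per spike.
#' @param neuropil_frac Neuropil brightness relative to somata (default
#'   0.3).
#' @param rise_s,decay_s Indicator kinetics (defaults 0.18 s and 1.5 s,
#'   GCaMP6s-like).
#' @param chunk_frames Frames rendered per chunk (default 250).
#' @param frame_callback Optional `function(frame_indices, chunk_array)`
#'   called per chunk; when supplied the movie is not accumulated.
#' @export
render_movie.neuron_field_phantom <- function(phantom, pixel_pitch_um = 4,
                                              psf = psf_model(),
                                              baseline_counts = 1,
                                              soma_peak_counts = 10,
                                              dff_per_spike = 1,
                                              neuropil_frac = 0.3,
                                              rise_s = 0.18, decay_s = 1.5,
                                              chunk_frames = 250,
                                              frame_callback = NULL,
                                              seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  geo <- neuron_field_geometry(phantom, pixel_pitch_um, psf)
  n <- nrow(phantom$positions_um)
  n_frames <- ncol(phantom$spikes)
  C <- calcium_traces_from_spikes(phantom$spikes, phantom$frame_rate_hz,
                                  rise_s, decay_s,
                                  amplitude = dff_per_spike)
  pop <- colMeans(C)
  np_gain <- neuropil_frac * soma_peak_counts
  base_vec <- baseline_counts + np_gain * as.vector(geo$neuropil_map)
  soma_amp <- soma_peak_counts * geo$w_all
  keep <- is.null(frame_callback)
  movie <- if (keep) array(0L, dim = c(geo$ny, geo$nx, n_frames)) else NULL
  n_px <- geo$ny * geo$nx
  for (start in seq(1L, n_frames, by = chunk_frames)) {
    idx <- start:min(start + chunk_frames - 1L, n_frames)
    chunk <- array(0L, dim = c(geo$ny, geo$nx, length(idx)))
    for (j in seq_along(idx)) {
      t <- idx[j]
      mu <- base_vec * (1 + 0.5 * pop[t])
      mu[geo$px_all] <- mu[geo$px_all] +
        soma_amp * (1 + C[geo$id_all, t])
      chunk[, , j] <- stats::rpois(n_px, mu)
    }
    if (keep) movie[, , idx] <- chunk else frame_callback(idx, chunk)
  }
  structure(
    list(movie = movie, pixel_pitch_um = pixel_pitch_um,
         geometry = geo, calcium = C, phantom = phantom,
         soma_peak_counts = soma_peak_counts,
         baseline_counts = baseline_counts,
         dff_per_spike = dff_per_spike),
    class = "rendered_session")
}

#' Pixel-grid geometry of a neuron field
#'
#' Maps phantom neurons onto a pixel grid: per-neuron Gaussian footprint
#' pixels and weights (soma size convolved with the lateral PSF), plus a
#' smooth static neuropil field (unit mean) generated from the phantom's
#' positions-independent coarse noise.
#'
#' @param phantom A `neuron_field_phantom`.
#' @param pixel_pitch_um Pixel pitch (um).
#' @param psf A [psf_model()].
#' @return List with grid sizes (`nx`, `ny`), pixel-centre coordinates,
#'   concatenated footprint pixel indices `px_all` / neuron ids `id_all` /
#'   weights `w_all`, per-neuron footprint index list `footprints`, and
#'   `neuropil_map`.
#' @export
neuron_field_geometry <- function(phantom, pixel_pitch_um = 4,
                                  psf = psf_model()) {
  stopifnot(inherits(phantom, "neuron_field_phantom"))
  nx <- ceiling(phantom$area_um[1] / pixel_pitch_um)
  ny <- ceiling(phantom$area_um[2] / pixel_pitch_um)
  xs <- (seq_len(nx) - 0.5) * pixel_pitch_um
  ys <- (seq_len(ny) - 0.5) * pixel_pitch_um
  n <- nrow(phantom$positions_um)
  sig <- sqrt((phantom$radii_um / 1.5)^2 + psf$lateral_sigma_um^2)
  px_list <- vector("list", n); w_list <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- phantom$positions_um[i, 1]; cy <- phantom$positions_um[i, 2]
    r <- 3 * sig[i]
    ix <- which(abs(xs - cx) <= r); iy <- which(abs(ys - cy) <= r)
    if (length(ix) == 0L || length(iy) == 0L) next
    d2 <- outer((ys[iy] - cy)^2, (xs[ix] - cx)^2, "+")
    w <- exp(-d2 / (2 * sig[i]^2))
    keep <- w >= 0.05
    pix <- outer(iy, (ix - 1L) * ny, "+")   # column-major linear indices
    px_list[[i]] <- pix[keep]
    w_list[[i]] <- w[keep]
  }
  # smooth neuropil field: coarse lognormal-ish noise, bilinear upsampled
  coarse_pitch <- 50
  cgx <- seq(0, phantom$area_um[1] + coarse_pitch, by = coarse_pitch)
  cgy <- seq(0, phantom$area_um[2] + coarse_pitch, by = coarse_pitch)
  cz <- matrix(stats::rnorm(length(cgx) * length(cgy), 1, 0.25),
               length(cgy), length(cgx))
  fx <- findInterval(xs, cgx, all.inside = TRUE)
  fy <- findInterval(ys, cgy, all.inside = TRUE)
  tx <- (xs - cgx[fx]) / coarse_pitch
  ty <- (ys - cgy[fy]) / coarse_pitch
  np <- (1 - ty) %o% (1 - tx) * cz[cbind(rep(fy, nx), rep(fx, each = ny))] +
        (1 - ty) %o% tx       * cz[cbind(rep(fy, nx), rep(fx + 1L, each = ny))] +
        ty %o% (1 - tx)       * cz[cbind(rep(fy + 1L, nx), rep(fx, each = ny))] +
        ty %o% tx             * cz[cbind(rep(fy + 1L, nx), rep(fx + 1L, each = ny))]
  np <- matrix(pmax(np, 0.2), ny, nx)
  list(nx = nx, ny = ny, x_um = xs, y_um = ys,
       px_all = unlist(px_list), w_all = unlist(w_list),
       id_all = rep(seq_len(n), lengths(px_list)),
       footprints = px_list, footprint_weights = w_list,
       neuropil_map = np)
}

#' Simulate a temporally multiplexed two-pathway acquisition
#'
#' Event-level simulation tying image formation to the demultiplexer: for
#' each pixel, pathway-1 and pathway-2 photons are drawn as Poisson counts
#' with the given per-pixel means, attached to excitation pulses of the
#' interleaved 2-train comb inside that pixel's dwell window, delayed by
#' exponential lifetime draws, and passed through [demultiplex()].
#'
#' @param mean1,mean2 Per-pixel mean photon counts for pathway 1 and 2
#'   (equal-length numeric vectors).
#' @param gates A [demux_gates()].
#' @param model An [emission_model()] (only the lifetime is used).
#' @param pixel_dwell_s Pixel dwell time (default 100 ns, several pulse
#'   periods).
#' @param rep_rate_hz Per-train repetition rate (default 80 MHz).
#' @param seed Optional integer seed.
#' @return The [demultiplex()] result plus `truth1`, `truth2` (per-pixel
#'   true source counts) and `events`.
#' @export
simulate_demux_acquisition <- function(mean1, mean2, gates = demux_gates(),
                                       model = emission_model(),
                                       pixel_dwell_s = 1e-7,
                                       rep_rate_hz = 80e6, seed = NULL) {
  stopifnot(length(mean1) == length(mean2))
  if (!is.null(seed)) set.seed(seed)
  n_px <- length(mean1)
  edges <- (0:n_px) * pixel_dwell_s
  period <- 1 / rep_rate_hz
  pulses_per_px <- max(1L, floor(pixel_dwell_s / period))
  times <- numeric(0); src <- integer(0)
  for (s in 1:2) {
    mu <- if (s == 1L) mean1 else mean2
    counts <- stats::rpois(n_px, mu)
    tot <- sum(counts)
    if (tot == 0L) next
    px <- rep(seq_len(n_px), counts)
    pulse_k <- sample.int(pulses_per_px, tot, replace = TRUE) - 1L
    t0 <- edges[px] + pulse_k * period + (s - 1L) * gates$delta_s
    times <- c(times, t0 + stats::rexp(tot, 1 / model$lifetime_s))
    src <- c(src, rep(s, tot))
  }
  ord <- order(times)
  events <- structure(list(times_s = times[ord], true_source = src[ord]),
                      class = "photon_event_list")
  out <- demultiplex(events, gates, edges)
  px_of <- findInterval(events$times_s, edges, rightmost.closed = TRUE)
  inside <- px_of >= 1L & px_of <= n_px
  out$truth1 <- tabulate(px_of[inside & events$true_source == 1L], n_px)
  out$truth2 <- tabulate(px_of[inside & events$true_source == 2L], n_px)
  out$events <- events
  out
}
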