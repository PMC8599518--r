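# Seeded synthetic phantoms: sub-resolution bead volumes, the 5 lines/mm
# calibration grid, and fields of GCaMP6s-like neurons with
# distance-dependent pairwise spike correlations.  Every generator is
# reproducible under a seed and stores its ground truth.

#' Gaussian point-spread-function model
#'
#' Separable Gaussian excitation PSF parameterized by lateral and axial
#' FWHM (defaults 1.0 um and 8.0 um, the system's nominal resolution).
#'
#' @param lateral_fwhm_um Lateral FWHM (um), > 0.
#' @param axial_fwhm_um Axial FWHM (um), > 0.
#' @return An object of class `psf_model` with the FWHMs and the derived
#'   Gaussian sigmas.
#' @export
psf_model <- function(lateral_fwhm_um = 1.0, axial_fwhm_um = 8.0) {
  stopifnot(lateral_fwhm_um > 0, axial_fwhm_um > 0)
  k <- 2 * sqrt(2 * log(2))
  structure(
    list(lateral_fwhm_um = lateral_fwhm_um, axial_fwhm_um = axial_fwhm_um,
         lateral_sigma_um = lateral_fwhm_um / k,
         axial_sigma_um = axial_fwhm_um / k),
    class = "psf_model")
}

#' FWHM of a Gaussian with standard deviation sigma
#' @param sigma Standard deviation (same units as the returned FWHM).
#' @return `2 * sqrt(2 * log(2)) * sigma`.
#' @export
gaussian_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' Sub-resolution bead phantom
#'
#' Random sub-resolution fluorescent beads (0.2 um diameter, well below
#' the ~1 um lateral PSF) embedded in a thick gel, placed uniformly in x-y
#' at each of the requested depths (defaults 50, 250 and 500 um, the
#' standard measurement depths).
#'
#' @param n_beads Beads per depth (default 8).
#' @param extent_um Length-2 lateral extent of the volume (um).
#' @param depths_um Depths (um) at which beads are placed.
#' @param diameter_um Bead diameter (default 0.2 um).
#' @param background Relative background fluorescence level.
#' @param seed Optional integer seed.
#' @return An object of class `bead_phantom` with `positions_um`
#'   (columns x, y, z), `diameter_um`, `extent_um`, `background`.
#' @export
make_bead_volume <- function(n_beads = 8, extent_um = c(50, 50),
                             depths_um = c(50, 250, 500),
                             diameter_um = 0.2, background = 0,
                             seed = NULL) {
  if (n_beads < 1) stop("at least one bead is required")
  stopifnot(length(extent_um) == 2L, all(extent_um > 0),
            length(depths_um) >= 1L, diameter_um > 0)
  if (!is.null(seed)) set.seed(seed)
  # area needed for n non-overlapping beads (loose disk-packing bound)
  if (n_beads * pi * (diameter_um / 2)^2 > 0.25 * prod(extent_um)) {
    warning("volume extent is small for the requested bead count; overlaps likely")
  }
  pos <- do.call(rbind, lapply(depths_um, function(z) {
    cbind(x = stats::runif(n_beads, 0, extent_um[1]),
          y = stats::runif(n_beads, 0, extent_um[2]),
          z = rep(z, n_beads))
  }))
  structure(
    list(positions_um = pos, diameter_um = diameter_um,
         extent_um = as.numeric(extent_um), depths_um = as.numeric(depths_um),
         background = background),
    class = "bead_phantom")
}

#' Calibration line-grid phantom
#'
#' Periodic fluorescent line target (default 5 lines per mm, i.e. a 0.2 mm
#' period).  Line centres sit at `(k + 0.5) * period` from the field edge,
#' so exactly `floor(extent / period)` lines lie strictly inside the
#' field: 25 lines across the full 5 mm scan.
#'
#' @param period_mm Line period (default 0.2 mm).
#' @param line_width_mm Width of each fluorescent line (default a quarter
#'   period).
#' @param extent_mm Field extent covered by the grid (default the FOV
#'   side).
#' @param orientation `"x"`: the pattern repeats along x (lines run along
#'   y); `"y"`: the converse.
#' @return An object of class `line_grid_phantom` with `centers_mm` (line
#'   centre offsets from the field edge), `n_lines`, and the geometry.
#' @export
make_line_grid <- function(period_mm = 0.2, line_width_mm = period_mm / 4,
                           extent_mm = FOV_SIDE_MM,
                           orientation = c("x", "y")) {
  orientation <- match.arg(orientation)
  stopifnot(period_mm > 0, line_width_mm > 0, line_width_mm < period_mm,
            extent_mm > 0)
  n_lines <- floor(extent_mm / period_mm)
  centers <- if (n_lines >= 1) (seq_len(n_lines) - 0.5) * period_mm
             else numeric()
  structure(
    list(period_mm = period_mm, line_width_mm = line_width_mm,
         extent_mm = extent_mm, orientation = orientation,
         centers_mm = centers, n_lines = as.integer(n_lines)),
    class = "line_grid_phantom")
}

#' Line-grid brightness profile smoothed by the lateral PSF
#'
#' Analytic convolution of the rectangular line pattern with the Gaussian
#' lateral PSF, evaluated at sample positions along the grid's repeat
#' axis.  Positions are measured from the field edge (same frame as
#' `centers_mm`).
#'
#' @param grid A `line_grid_phantom`.
#' @param pos_mm Positions along the repeat axis (mm from field edge).
#' @param psf A [psf_model()].
#' @return Brightness in `[0, 1]` at each position.
#' @export
line_grid_profile <- function(grid, pos_mm, psf = psf_model()) {
  stopifnot(inherits(grid, "line_grid_phantom"))
  sigma_mm <- psf$lateral_sigma_um * 1e-3
  hw <- grid$line_width_mm / 2
  out <- numeric(length(pos_mm))
  for (c_k in grid$centers_mm) {
    out <- out + stats::pnorm((pos_mm - c_k + hw) / sigma_mm) -
                 stats::pnorm((pos_mm - c_k - hw) / sigma_mm)
  }
  out
}

#' Distance-dependent pairwise spike-correlation kernel
#'
#' Target Pearson correlation between two neurons' per-frame spike counts
#' as a function of their distance `d`: a sum of a near-field and a
#' far-field Gaussian component,
#' `rho(d) = a_near * exp(-d^2 / (2 L_near^2)) + a_far * exp(-d^2 / (2 L_far^2))`.
#' The defaults keep correlations relatively high (~0.25) below a ~40 um
#' knee and decay slowly to ~0.05 at 2 mm; the kernel is non-increasing
#' everywhere.
#'
#' `a_far` is solved so the kernel equals `rho_far` at `far_um`, and
#' `a_near = rho0 - a_far`.
#'
#' @param rho0 Correlation at zero distance (default 0.25).
#' @param knee_um Knee distance below which correlation stays high
#'   (default 40 um; descriptive, not a kernel break point).
#' @param rho_far Correlation at `far_um` (default 0.05).
#' @param far_um Far reference distance (default 2000 um).
#' @param L_near_um Near-component length scale (default 120 um).
#' @param L_far_um Far-component length scale (default 2500 um).
#' @return An object of class `correlation_kernel`; call it via
#'   [kernel_rho()].
#' @export
correlation_kernel <- function(rho0 = 0.25, knee_um = 40, rho_far = 0.05,
                               far_um = 2000, L_near_um = 120,
                               L_far_um = 2500) {
  stopifnot(rho0 >= 0, rho0 < 1, rho_far >= 0, rho_far <= rho0,
            L_near_um > 0, L_far_um > 0, far_um > 0)
  a_far <- if (rho0 == 0) 0 else rho_far / exp(-far_um^2 / (2 * L_far_um^2))
  a_near <- rho0 - a_far
  if (a_near < 0) stop("rho_far too large for the given far distance and L_far")
  structure(
    list(rho0 = rho0, knee_um = knee_um, a_near = a_near, a_far = a_far,
         L_near_um = L_near_um, L_far_um = L_far_um),
    class = "correlation_kernel")
}

#' Evaluate a correlation kernel
#' @param kernel A [correlation_kernel()].
#' @param d_um Distances (um).
#' @return Target correlations `rho(d)`.
#' @export
kernel_rho <- function(kernel, d_um) {
  stopifnot(inherits(kernel, "correlation_kernel"))
  kernel$a_near * exp(-d_um^2 / (2 * kernel$L_near_um^2)) +
    kernel$a_far * exp(-d_um^2 / (2 * kernel$L_far_um^2))
}

# Shared latent Poisson drives with Gaussian spatial footprints.
# One component: sources on a grid with spacing sigma/1.5, extended 3*sigma
# beyond the neuron field; neuron i receives each source-k event with
# probability g * exp(-d_ik^2 / (2 sigma^2)).  For a pair at distance d the
# shared-event covariance is exactly proportional to exp(-d^2 / (4 sigma^2)),
# i.e. a Gaussian correlation component with length L = sigma * sqrt(2).
.latent_component <- function(positions_um, area_um, amplitude, L_um,
                              lambda_frame, g = 0.65) {
  sigma <- L_um / sqrt(2)
  h <- sigma / 1.5
  pad <- 3 * sigma
  sx <- seq(-pad, area_um[1] + pad, by = h)
  sy <- seq(-pad, area_um[2] + pad, by = h)
  S <- cbind(rep(sx, times = length(sy)), rep(sy, each = length(sx)))
  # calibration: discrete Gaussian mass at the domain centre
  ctr <- area_um / 2
  Tm <- sum(exp(-((S[, 1] - ctr[1])^2 + (S[, 2] - ctr[2])^2) / sigma^2))
  lambda_src <- amplitude * lambda_frame / (g^2 * Tm)
  d2 <- outer(positions_um[, 1], S[, 1], "-")^2 +
        outer(positions_um[, 2], S[, 2], "-")^2
  P <- g * exp(-d2 / (2 * sigma^2))
  list(sources = S, P = P, lambda_src = lambda_src,
       shared_rate = lambda_src * rowSums(P))
}

# Draw the shared-event contribution of one latent component: an n x T
# integer matrix of delivered events.
.draw_component <- function(comp, n_frames) {
  n <- nrow(comp$P); K <- ncol(comp$P)
  n_events_k <- stats::rpois(K, comp$lambda_src * n_frames)
  E <- sum(n_events_k)
  X <- matrix(0L, n, n_frames)
  if (E == 0L) return(X)
  src <- rep(seq_len(K), n_events_k)
  frames <- sample.int(n_frames, E, replace = TRUE)
  probs <- comp$P[, src, drop = FALSE]          # n x E
  D <- matrix(stats::rbinom(n * E, 1L, as.vector(probs)), nrow = n)
  agg <- rowsum(t(D), group = frames)           # frames-with-events x n
  fidx <- as.integer(rownames(agg))
  X[, fidx] <- X[, fidx] + t(agg)
  X
}

#' Neuron-field phantom with distance-dependent spike correlations
#'
#' Generates a field of non-overlapping somata with per-frame spike counts
#' whose pairwise Pearson correlations follow a target distance kernel.
#' Spikes arise from shared latent Poisson drives with Gaussian spatial
#' footprints plus an independent Poisson component; each Gaussian kernel
#' component is realized exactly (in expectation) by one grid of latent
#' sources, so the expected count correlation of a pair at distance `d` is
#' `kernel_rho(kernel, d)` and the marginal rate of every neuron is
#' `rate_hz`.
#'
#' @param n_neurons Number of neurons (default 200).
#' @param area_um Length-2 field extent (um), default `c(2400, 800)`.
#' @param rate_hz Mean firing rate per neuron (default 0.5 Hz).
#' @param frame_rate_hz Acquisition frame rate (default 3.85 Hz, the
#'   frame rate of a full-height 4096-line dual-engine acquisition).
#' @param n_frames Number of frames (default 5000).
#' @param kernel A [correlation_kernel()].
#' @param radius_um Soma radius (default 6 um).
#' @param min_separation_um Minimum centre-to-centre separation (default
#'   15 um).
#' @param seed Optional integer seed.
#' @return An object of class `neuron_field_phantom`: `positions_um`
#'   (n x 2), `radii_um`, `spikes` (n x n_frames integer counts, the
#'   ground truth), `kernel`, `rate_hz`, `frame_rate_hz`, `area_um`.
#' @export
make_neuron_field <- function(n_neurons = 200, area_um = c(2400, 800),
                              rate_hz = 0.5, frame_rate_hz = 3.85,
                              n_frames = 5000,
                              kernel = correlation_kernel(),
                              radius_um = 6, min_separation_um = 15,
                              seed = NULL) {
  stopifnot(n_neurons >= 1, length(area_um) == 2L, all(area_um > 0),
            rate_hz >= 0, frame_rate_hz > 0, n_frames >= 1,
            inherits(kernel, "correlation_kernel"))
  if (!is.null(seed)) set.seed(seed)
  if (n_neurons * min_separation_um^2 > prod(area_um)) {
    stop("infeasible neuron density for the requested minimum separation")
  }
  # dart-throwing placement with minimum separation
  pos <- matrix(NA_real_, n_neurons, 2L)
  placed <- 0L; tries <- 0L
  while (placed < n_neurons) {
    cand <- c(stats::runif(1, 0, area_um[1]), stats::runif(1, 0, area_um[2]))
    ok <- placed == 0L ||
      min((pos[seq_len(placed), 1] - cand[1])^2 +
          (pos[seq_len(placed), 2] - cand[2])^2) >= min_separation_um^2
    if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
    tries <- tries + 1L
    if (tries > 200L * n_neurons) stop("could not place neurons; density too high")
  }
  lambda <- rate_hz / frame_rate_hz
  spikes <- matrix(0L, n_neurons, n_frames)
  shared_rate <- numeric(n_neurons)
  if (lambda > 0 && kernel$rho0 > 0) {
    comps <- list()
    if (kernel$a_near > 0) {
      comps <- c(comps, list(.latent_component(pos, area_um, kernel$a_near,
                                               kernel$L_near_um, lambda)))
    }
    if (kernel$a_far > 0) {
      comps <- c(comps, list(.latent_component(pos, area_um, kernel$a_far,
                                               kernel$L_far_um, lambda)))
    }
    for (comp in comps) {
      spikes <- spikes + .draw_component(comp, n_frames)
      shared_rate <- shared_rate + comp$shared_rate
    }
  }
  lambda_ind <- lambda - shared_rate
  if (any(lambda_ind < -1e-9)) {
    warning("shared drive exceeds the target rate for some neurons; clamping")
  }
  lambda_ind <- pmax(lambda_ind, 0)
  spikes <- spikes +
    matrix(stats::rpois(n_neurons * n_frames, rep(lambda_ind, n_frames)),
           n_neurons, n_frames)
  structure(
    list(positions_um = pos, radii_um = rep(radius_um, n_neurons),
         spikes = spikes, kernel = kernel, rate_hz = rate_hz,
         frame_rate_hz = frame_rate_hz, area_um = as.numeric(area_um)),
    class = "neuron_field_phantom")
}

#' Pairwise distances of phantom neurons
#' @param phantom A `neuron_field_phantom`.
#' @return Full n x n distance matrix (um).
#' @export
neuron_distances <- function(phantom) {
  stopifnot(inherits(phantom, "neuron_field_phantom"))
  as.matrix(stats::dist(phantom$positions_um))
}

#' Count peaks in a 1-D intensity profile
#'
#' Counts contiguous runs of samples at or above a threshold (default
#' half of the profile maximum).  Run counting is robust to shot noise on
#' the flat tops of wide lines, where local-maximum counting would split
#' one line into several peaks.  Used to count rendered calibration-grid
#' lines.
#'
#' @param profile Numeric vector.
#' @param threshold Minimum peak height (default `max(profile) / 2`).
#' @return Integer peak count.
#' @export
count_profile_peaks <- function(profile, threshold = max(profile) / 2) {
  if (length(profile) < 2L) return(0L)
  above <- profile >= threshold
  sum(diff(c(FALSE, above)) == 1L)
}
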