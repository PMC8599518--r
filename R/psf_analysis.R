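# Bead z-stack PSF measurement: stage-to-focus coordinate correction,
# Gaussian FWHM fits of line profiles, tilt-searched axial profiles, and
# grouped mean +/- SD summaries.

#' Bead z-stack container
#'
#' @param voxels Numeric array `[z, y, x]` of (frame-averaged) counts.
#' @param stage_step_um Stage increment between planes (default 0.5 um).
#' @param pixel_pitch_um Lateral pixel pitch (um).
#' @param frames_averaged Frames averaged per plane.
#' @param x_um,y_um Optional lateral pixel-centre coordinates.
#' @return An object of class `bead_stack`.
#' @export
bead_stack <- function(voxels, stage_step_um = 0.5, pixel_pitch_um,
                       frames_averaged = 1L, x_um = NULL, y_um = NULL) {
  stopifnot(length(dim(voxels)) == 3L, dim(voxels)[1] >= 2L,
            stage_step_um > 0, pixel_pitch_um > 0)
  d <- dim(voxels)
  if (is.null(x_um)) x_um <- (seq_len(d[3]) - 0.5) * pixel_pitch_um
  if (is.null(y_um)) y_um <- (seq_len(d[2]) - 0.5) * pixel_pitch_um
  structure(
    list(voxels = voxels, stage_step_um = stage_step_um,
         pixel_pitch_um = pixel_pitch_um,
         frames_averaged = as.integer(frames_averaged),
         x_um = x_um, y_um = y_um,
         stage_index = seq_len(d[1]) - (d[1] + 1) / 2),
    class = "bead_stack")
}

#' Stage-to-focus axial coordinate correction
#'
#' The objective is air-immersed while the specimen is aqueous, so a stage
#' move of `stage_step` displaces the focus inside the specimen by
#' `factor * stage_step` (1.38 for this system from full-field modelling;
#' the paraxial index ratio would give 1.33, see
#' [paraxial_focal_shift()]).
#'
#' @param stack A `bead_stack`, or a numeric vector of plane indices
#'   (interpreted as multiples of `stage_step_um`).
#' @param factor Focus-per-stage factor (default 1.38), > 0.
#' @param stage_step_um Stage step when `stack` is an index vector.
#' @return Focus-space z positions (um), relative to the stack centre for
#'   a `bead_stack` input.
#' @export
correct_axial_coordinates <- function(stack, factor = 1.38,
                                      stage_step_um = 0.5) {
  stopifnot(factor > 0)
  if (inherits(stack, "bead_stack")) {
    stack$stage_index * stack$stage_step_um * factor
  } else {
    as.numeric(stack) * stage_step_um * factor
  }
}

#' Gaussian FWHM fit of a 1-D intensity profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 /
#' (2 sigma^2))`, with `FWHM = 2 sqrt(2 ln 2) sigma`.  Starting values
#' come from profile moments.  A profile without a peak (constant, or
#' amplitude indistinguishable from noise) raises an error; a fit that
#' fails to converge returns a flagged estimate (`converged = FALSE`,
#' moment-based FWHM).
#'
#' @param position Numeric positions (>= 5 samples).
#' @param intensity Intensities, same length.
#' @return List with `fwhm`, `sigma`, `center`, `amplitude`, `offset`,
#'   `converged`.
#' @examples
#' x <- seq(-3, 3, by = 0.1)
#' fit_fwhm(x, exp(-x^2 / (2 * 0.425^2)))$fwhm   # ~1.0
#' @export
fit_fwhm <- function(position, intensity) {
  stopifnot(length(position) == length(intensity))
  ok <- is.finite(position) & is.finite(intensity)
  position <- position[ok]; intensity <- intensity[ok]
  if (length(position) < 5L) stop("at least 5 finite samples are required")
  rng <- diff(range(intensity))
  if (rng <= 0) stop("profile has no peak: intensity is constant")
  off0 <- min(intensity)
  amp0 <- max(intensity) - off0
  w <- pmax(intensity - off0, 0)
  c0 <- sum(position * w) / sum(w)
  s0 <- sqrt(sum((position - c0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(position)) / 6
  df <- data.frame(pos_ = position, int_ = intensity)
  try_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(
      int_ ~ off + amp * exp(-(pos_ - ctr)^2 / (2 * sig^2)),
      data = df, start = start,
      lower = c(-Inf, 0, -Inf, 1e-9 * max(abs(position), 1)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- try_fit(list(off = off0, amp = amp0, ctr = c0, sig = s0))
  if (is.null(fit)) {
    # a zero-residual start (noiseless data) breaks the nls machinery;
    # retry from a perturbed start
    fit <- try_fit(list(off = off0, amp = 0.9 * amp0, ctr = c0,
                        sig = 1.25 * s0))
  }
  k <- 2 * sqrt(2 * log(2))
  if (is.null(fit)) {
    # flagged moment-based estimate; exact if the residual is negligible
    resid <- intensity - (off0 + amp0 * exp(-(position - c0)^2 / (2 * s0^2)))
    exact <- sqrt(mean(resid^2)) < 1e-8 * rng
    return(list(fwhm = k * s0, sigma = s0, center = c0, amplitude = amp0,
                offset = off0, converged = exact))
  }
  cf <- stats::coef(fit)
  list(fwhm = k * abs(cf[["sig"]]), sigma = abs(cf[["sig"]]),
       center = cf[["ctr"]], amplitude = cf[["amp"]],
       offset = cf[["off"]], converged = TRUE)
}

# Bilinear interpolation of matrix M sampled at (r, c) in the coordinate
# frames rc_r, rc_c; points outside return NA.
.bilinear <- function(M, rr, cc, r_coord, c_coord) {
  fr <- findInterval(rr, r_coord)
  fc <- findInterval(cc, c_coord)
  out <- rep(NA_real_, length(rr))
  ok <- fr >= 1L & fr < length(r_coord) & fc >= 1L & fc < length(c_coord)
  if (!any(ok)) return(out)
  fr <- fr[ok]; fc <- fc[ok]
  tr <- (rr[ok] - r_coord[fr]) / (r_coord[fr + 1L] - r_coord[fr])
  tc <- (cc[ok] - c_coord[fc]) / (c_coord[fc + 1L] - c_coord[fc])
  out[ok] <-
    (1 - tr) * (1 - tc) * M[cbind(fr, fc)] +
    (1 - tr) * tc       * M[cbind(fr, fc + 1L)] +
    tr * (1 - tc)       * M[cbind(fr + 1L, fc)] +
    tr * tc             * M[cbind(fr + 1L, fc + 1L)]
  out
}

#' Tilt-searched axial line profile
#'
#' Builds the XZ (or YZ) image through the brightest voxel of a bead
#' stack, then extracts line profiles through the peak over a grid of
#' angles about the z axis and keeps the one maximizing the fitted FWHM.
#' Tilted focal shifts make the straight-z profile underestimate the
#' axial PSF; taking the angle of maximum spread prevents that.  Ties are
#' broken toward 0 degrees.
#'
#' @param stack A `bead_stack`.
#' @param plane `"xz"` or `"yz"`.
#' @param angles_deg Angle search grid (default -20..20 in 1-degree
#'   steps).
#' @param focus_factor Stage-to-focus factor for the axial coordinate
#'   (default 1.38).
#' @param sample_step_um Sampling step along the profile (default the
#'   lateral pixel pitch).
#' @return List with `angle_deg`, `position_um`, `intensity`, `fwhm_um`
#'   and the winning `fit`.
#' @export
axial_profile <- function(stack, plane = c("xz", "yz"),
                          angles_deg = seq(-20, 20, by = 1),
                          focus_factor = 1.38, sample_step_um = NULL) {
  stopifnot(inherits(stack, "bead_stack"))
  plane <- match.arg(plane)
  v <- stack$voxels
  pk <- arrayInd(which.max(v), dim(v))
  iz <- pk[1]; iy <- pk[2]; ix <- pk[3]
  d <- dim(v)
  if (iz <= 1L || iz >= d[1] || iy <= 1L || iy >= d[2] ||
      ix <= 1L || ix >= d[3]) {
    stop("bead peak lies at the stack edge; enlarge the acquisition volume")
  }
  z_um <- correct_axial_coordinates(stack, focus_factor)
  if (plane == "xz") {
    M <- v[, iy, ]                      # rows z, cols x
    lat <- stack$x_um; lat0 <- lat[ix]
  } else {
    M <- v[, , ix]                      # rows z, cols y
    lat <- stack$y_um; lat0 <- lat[iy]
  }
  z0 <- z_um[iz]
  if (is.null(sample_step_um)) sample_step_um <- stack$pixel_pitch_um
  half_len <- sqrt(diff(range(z_um))^2 + diff(range(lat))^2) / 2
  s <- seq(-half_len, half_len, by = sample_step_um)
  best <- NULL
  for (a in angles_deg[order(abs(angles_deg))]) {
    th <- a * pi / 180
    zz <- z0 + s * cos(th)
    ll <- lat0 + s * sin(th)
    prof <- .bilinear(M, zz, ll, z_um, lat)
    keep <- !is.na(prof)
    if (sum(keep) < 5L) next
    fit <- tryCatch(fit_fwhm(s[keep], prof[keep]), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    if (is.null(best) || fit$fwhm > best$fwhm_um * (1 + 1e-9)) {
      best <- list(angle_deg = a, position_um = s[keep],
                   intensity = prof[keep], fwhm_um = fit$fwhm, fit = fit)
    }
  }
  if (is.null(best)) stop("no axial profile could be fit")
  best
}

#' Full PSF estimate from one bead stack
#'
#' Reproduces the measurement recipe: the radial FWHM is the mean of
#' Gaussian fits to the X and Y line scans through the bead at its axial
#' intensity maximum; the axial FWHM is the mean of the tilt-searched XZ
#' and YZ profile fits.
#'
#' @param stack A `bead_stack`.
#' @param focus_factor Stage-to-focus factor (default 1.38).
#' @param angles_deg Axial tilt search grid.
#' @return A one-row data.frame (class `psf_estimate`): `radial_fwhm_um`,
#'   `axial_fwhm_um`, the four individual fits, the axial tilt angles,
#'   and convergence flags.
#' @export
measure_bead_psf <- function(stack, focus_factor = 1.38,
                             angles_deg = seq(-20, 20, by = 1)) {
  stopifnot(inherits(stack, "bead_stack"))
  v <- stack$voxels
  pk <- arrayInd(which.max(v), dim(v))
  iz <- pk[1]; iy <- pk[2]; ix <- pk[3]
  fx <- fit_fwhm(stack$x_um, v[iz, iy, ])
  fy <- fit_fwhm(stack$y_um, v[iz, , ix])
  axz <- axial_profile(stack, "xz", angles_deg, focus_factor)
  ayz <- axial_profile(stack, "yz", angles_deg, focus_factor)
  out <- data.frame(
    radial_fwhm_um = (fx$fwhm + fy$fwhm) / 2,
    axial_fwhm_um = (axz$fwhm_um + ayz$fwhm_um) / 2,
    x_fwhm_um = fx$fwhm, y_fwhm_um = fy$fwhm,
    xz_fwhm_um = axz$fwhm_um, yz_fwhm_um = ayz$fwhm_um,
    xz_angle_deg = axz$angle_deg, yz_angle_deg = ayz$angle_deg,
    converged = fx$converged && fy$converged)
  class(out) <- c("psf_estimate", class(out))
  out
}

#' Grouped mean +/- SD summary of PSF estimates
#'
#' @param estimates A data.frame of per-bead estimates (e.g. rows of
#'   [measure_bead_psf()] results plus grouping columns).
#' @param by Character vector of grouping column names (may be empty for
#'   a single group).
#' @param measures Numeric columns to summarize (default the radial and
#'   axial FWHM columns present).
#' @return A data.frame with one row per group: `n` and
#'   `<measure>_mean` / `<measure>_sd` columns.
#' @export
summarize_psf <- function(estimates, by = character(),
                          measures = intersect(
                            c("radial_fwhm_um", "axial_fwhm_um"),
                            names(estimates))) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0L) stop("no estimates to summarize")
  if (length(measures) == 0L) stop("no measure columns found")
  if (length(by) == 0L) {
    groups <- list(seq_len(nrow(estimates)))
    key <- data.frame(row.names = 1L)
  } else {
    fac <- interaction(estimates[by], drop = TRUE, lex.order = TRUE)
    groups <- split(seq_len(nrow(estimates)), fac)
    key <- unique(estimates[by])
    key <- key[order(interaction(key, drop = TRUE, lex.order = TRUE)), ,
               drop = FALSE]
  }
  rows <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 2L) {
      warning("group with fewer than 2 beads; SD is NA")
    }
    vals <- lapply(measures, function(m) {
      x <- estimates[idx, m]
      c(mean(x), stats::sd(x))
    })
    stats_row <- as.data.frame(as.list(unlist(vals)))
    names(stats_row) <- as.vector(rbind(paste0(measures, "_mean"),
                                        paste0(measures, "_sd")))
    row <- cbind(n = length(idx), stats_row)
    if (length(by)) {
      kk <- key[g, , drop = FALSE]
      rownames(kk) <- NULL
      row <- cbind(kk, row)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
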