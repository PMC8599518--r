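# First-order optical bookkeeping for the mesoscope and the sensorless
# adaptive-optics optimization.  No ray tracing: the scan-to-sample scale
# is a calibrated mm/degree constant anchored to the measured line-grid
# field of view, with the first-order f*tan(theta) estimate reported
# alongside for comparison.

#' Optical prescription
#'
#' First-order description of the excitation path: effective focal lengths
#' of scan lens, tube lens and objective, the maximum scan half-angle at
#' the objective back aperture, the calibrated scan-to-sample scale, and
#' the nominal point-spread-function widths.
#'
#' @param efl_scan_mm Scan lens EFL (default 61 mm).
#' @param efl_tube_mm Tube lens EFL (default 243 mm).
#' @param efl_objective_mm Objective EFL (default 30 mm).
#' @param max_half_angle_deg Maximum scan half-angle at the objective back
#'   aperture (default 5 degrees).
#' @param mm_per_deg_sample Calibrated sample displacement per degree of
#'   scan angle (default 0.50 mm/deg, anchored to the 5 mm measured FOV).
#' @param lateral_resolution_um Nominal lateral FWHM (default 1.0 um).
#' @param axial_resolution_um Nominal axial FWHM (default 8.0 um).
#' @return An object of class `optical_prescription`.
#' @export
optical_prescription <- function(efl_scan_mm = 61, efl_tube_mm = 243,
                                 efl_objective_mm = 30,
                                 max_half_angle_deg = 5,
                                 mm_per_deg_sample = 0.50,
                                 lateral_resolution_um = 1.0,
                                 axial_resolution_um = 8.0) {
  vals <- c(efl_scan_mm, efl_tube_mm, efl_objective_mm, max_half_angle_deg,
            mm_per_deg_sample, lateral_resolution_um, axial_resolution_um)
  stopifnot(all(vals > 0))
  structure(
    list(efl_scan_mm = efl_scan_mm, efl_tube_mm = efl_tube_mm,
         efl_objective_mm = efl_objective_mm,
         max_half_angle_deg = max_half_angle_deg,
         mm_per_deg_sample = mm_per_deg_sample,
         lateral_resolution_um = lateral_resolution_um,
         axial_resolution_um = axial_resolution_um),
    class = "optical_prescription")
}

#' Field-of-view extent
#'
#' Calibrated side length `2 * max_half_angle * mm_per_deg` (5.0 mm with
#' defaults) and the first-order estimate `2 * efl_objective *
#' tan(max_half_angle)` for comparison.
#'
#' @param p An [optical_prescription()].
#' @return List with `calibrated_mm`, `first_order_mm`, `area_mm2`.
#' @export
fov_extent <- function(p) {
  stopifnot(inherits(p, "optical_prescription"))
  cal <- 2 * p$max_half_angle_deg * p$mm_per_deg_sample
  fo <- 2 * p$efl_objective_mm * tan(p$max_half_angle_deg * pi / 180)
  list(calibrated_mm = cal, first_order_mm = fo, area_mm2 = cal^2)
}

#' Scan-tube telescope magnification
#'
#' @param p An [optical_prescription()].
#' @return List with `magnification` (`efl_tube / efl_scan`) and `nominal`
#'   (integer-rounded report, e.g. "4x" for 243/61).
#' @export
telescope_magnification <- function(p) {
  stopifnot(inherits(p, "optical_prescription"))
  m <- p$efl_tube_mm / p$efl_scan_mm
  list(magnification = m, nominal = round(m))
}

#' Space-bandwidth product
#'
#' Number of resolvable pixels: field area divided by the square of the
#' lateral resolution.
#'
#' @param p An [optical_prescription()].
#' @param fov_area_mm2 Field area (mm^2); defaults to the calibrated FOV.
#' @return Resolvable pixel count (dimensionless).
#' @examples
#' space_bandwidth_product(optical_prescription())   # 25e6
#' @export
space_bandwidth_product <- function(p, fov_area_mm2 = fov_extent(p)$area_mm2) {
  stopifnot(inherits(p, "optical_prescription"), fov_area_mm2 >= 0)
  (fov_area_mm2 * 1e6) / p$lateral_resolution_um^2
}

#' Square versus inscribed-circle field area
#'
#' Compares a square field of given side with a circular field of given
#' diameter: a 5 mm square exceeds the 5 mm circle (~19.6 mm^2) by ~27%.
#'
#' @param square_side_mm Side of the square field (mm).
#' @param circle_diam_mm Diameter of the circular field (mm).
#' @return List with `square_area_mm2`, `circle_area_mm2`,
#'   `excess_fraction` (square / circle - 1).
#' @export
fov_area_comparison <- function(square_side_mm, circle_diam_mm) {
  stopifnot(square_side_mm > 0, circle_diam_mm > 0)
  sq <- square_side_mm^2
  ci <- pi * circle_diam_mm^2 / 4
  list(square_area_mm2 = sq, circle_area_mm2 = ci,
       excess_fraction = sq / ci - 1)
}

#' Paraxial focal-shift factor
#'
#' Paraxial ratio of focal displacement inside the specimen to stage
#' displacement when the immersion and specimen refractive indices differ:
#' `n_specimen / n_immersion` (1.33 for air into water).  Full-field
#' models give slightly different factors (1.38 for this system); see
#' [correct_axial_coordinates()].
#'
#' @param n_immersion Immersion-medium refractive index (>= 1).
#' @param n_specimen Specimen refractive index (>= 1).
#' @return Dimensionless factor.
#' @export
paraxial_focal_shift <- function(n_immersion, n_specimen) {
  stopifnot(n_immersion >= 1, n_specimen >= 1)
  n_specimen / n_immersion
}

#' Deformable mirror specification
#'
#' Stroke and defocus sensitivity of the deformable mirror used for remote
#' focusing: with a 3.5 um maximum stroke and the default sensitivity
#' (120 / 3.5 ~ 34.3 um of sample defocus per um of stroke) the total
#' defocus range is 120 um (+/- 60 um about the middle plane).
#'
#' @param stroke_um Maximum stroke (default 3.5 um).
#' @param defocus_sensitivity_um_per_um Sample defocus per unit stroke
#'   (default 120 / 3.5).
#' @return An object of class `deformable_mirror_spec`.
#' @export
deformable_mirror_spec <- function(stroke_um = 3.5,
                                   defocus_sensitivity_um_per_um = 120 / 3.5) {
  stopifnot(stroke_um >= 0, defocus_sensitivity_um_per_um > 0)
  structure(
    list(stroke_um = stroke_um,
         defocus_sensitivity_um_per_um = defocus_sensitivity_um_per_um),
    class = "deformable_mirror_spec")
}

#' Remote-focus defocus range
#'
#' Total axial defocus range `stroke * sensitivity` (linear in stroke),
#' optionally compared against a reference mirror's stroke.
#'
#' @param dm A [deformable_mirror_spec()].
#' @param reference_stroke_um Optional reference stroke for the fold-change
#'   report (e.g. an 80 um stroke unit vs the 3.5 um default is ~23-fold).
#' @return List with `range_um`, `half_range_um`, and `fold_vs_reference`
#'   (`NA` when no reference is given).
#' @export
defocus_range <- function(dm, reference_stroke_um = NULL) {
  stopifnot(inherits(dm, "deformable_mirror_spec"))
  rng <- dm$stroke_um * dm$defocus_sensitivity_um_per_um
  fold <- if (is.null(reference_stroke_um)) NA_real_
          else dm$stroke_um / reference_stroke_um
  list(range_um = rng, half_range_um = rng / 2, fold_vs_reference = fold)
}

#' Zernike coefficient state
#'
#' Wavefront state over Noll-indexed Zernike modes 1..15.  Modes 1-4
#' (piston, tip, tilt, defocus) are never touched by the aberration
#' optimizer; the 11 modes 5-15 are adjustable.
#'
#' @param coefficients Numeric vector of 15 Noll coefficients (default all
#'   zero).
#' @param adjustable Indices of adjustable modes (default 5:15).
#' @return An object of class `zernike_state`.
#' @export
zernike_state <- function(coefficients = numeric(15), adjustable = 5:15) {
  stopifnot(length(coefficients) == 15L, is.numeric(coefficients))
  adjustable <- as.integer(adjustable)
  if (any(adjustable < 5L) || any(adjustable > 15L)) {
    stop("piston, tip, tilt and defocus (Noll 1-4) are never adjustable")
  }
  structure(list(coefficients = as.numeric(coefficients),
                 adjustable = adjustable),
            class = "zernike_state")
}

#' Sensorless adaptive-optics optimization
#'
#' Coordinate-wise image-brightness maximization over the adjustable
#' Zernike modes, emulating sequential manual correction: each sweep
#' visits the 11 adjustable modes in order and maximizes the metric along
#' one coefficient at a time with a bracketed golden-section line search;
#' three sweeps typically reach a plateau.  A step is accepted only if it
#' improves the metric, so the best-so-far metric is non-decreasing, and
#' modes 1-4 are never modified.
#'
#' @param metric Function mapping a length-15 coefficient vector to a
#'   scalar brightness (higher is better).
#' @param state A [zernike_state()] starting point.
#' @param sweeps Number of passes over the adjustable modes (default 3).
#' @param span Half-width of the line-search bracket around the current
#'   coefficient (default 1).
#' @param tol Line-search convergence tolerance on the coefficient
#'   (default `span / 100`, roughly a dozen metric evaluations per mode).
#' @return List with `state` (optimized [zernike_state()]), `metric_trace`
#'   (best-so-far metric after each accepted step) and `n_evaluations`.
#' @export
sensorless_ao_optimize <- function(metric, state, sweeps = 3, span = 1,
                                   tol = span / 100) {
  stopifnot(is.function(metric), inherits(state, "zernike_state"),
            sweeps >= 1, span > 0)
  coef <- state$coefficients
  n_eval <- 0L
  wrap <- function(x) { n_eval <<- n_eval + 1L; metric(x) }
  best <- wrap(coef)
  trace <- best
  for (s in seq_len(sweeps)) {
    for (j in state$adjustable) {
      f1 <- function(v) { cc <- coef; cc[j] <- v; wrap(cc) }
      opt <- stats::optimize(f1, interval = c(coef[j] - span, coef[j] + span),
                             maximum = TRUE, tol = tol)
      if (opt$objective > best) {
        coef[j] <- opt$maximum
        best <- opt$objective
      }
      trace <- c(trace, best)
    }
  }
  out_state <- zernike_state(coef, state$adjustable)
  list(state = out_state, metric_trace = trace, n_evaluations = n_eval)
}

#' Field-flatness check
#'
#' Tests whether the focal surface sampled across the FOV deviates from a
#' best-fit plane by less than a tolerance (default 30 um over the 5 mm
#' field).
#'
#' @param z_surface_um Matrix (or data.frame `x`, `y`, `z`) of focal
#'   z-displacements (um) sampled on a grid covering the FOV.
#' @param tol_um Allowed maximum sag about the best-fit plane (default 30).
#' @return List with `pass`, `max_sag_um` (max abs residual from the plane
#'   fit), and `plane_coef`.
#' @export
field_flatness_check <- function(z_surface_um, tol_um = 30) {
  if (is.matrix(z_surface_um)) {
    if (length(z_surface_um) == 0L) stop("empty focal-surface grid")
    nx <- ncol(z_surface_um); ny <- nrow(z_surface_um)
    df <- data.frame(
      x = rep(seq_len(nx), each = ny),
      y = rep(seq_len(ny), times = nx),
      z = as.numeric(z_surface_um))
  } else {
    df <- as.data.frame(z_surface_um)
    if (!all(c("x", "y", "z") %in% names(df)) || nrow(df) == 0L) {
      stop("z_surface_um must be a matrix or a data.frame with x, y, z")
    }
  }
  fit <- stats::lm(z ~ x + y, data = df)
  sag <- max(abs(stats::residuals(fit)))
  list(pass = sag < tol_um, max_sag_um = sag,
       plane_coef = stats::coef(fit))
}

#' One-line optical summary
#'
#' JSON-ready summary of the prescription: FOV, telescope magnification,
#' space-bandwidth product, and remote-focus range.
#'
#' @param p An [optical_prescription()].
#' @param dm A [deformable_mirror_spec()].
#' @return A named list.
#' @export
optics_report <- function(p = optical_prescription(),
                          dm = deformable_mirror_spec()) {
  fov <- fov_extent(p)
  list(
    fov_side_mm = fov$calibrated_mm,
    fov_side_first_order_mm = fov$first_order_mm,
    fov_area_mm2 = fov$area_mm2,
    telescope_magnification = telescope_magnification(p)$magnification,
    space_bandwidth_product = space_bandwidth_product(p),
    defocus_range_um = defocus_range(dm)$range_um)
}
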