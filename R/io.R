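# File I/O: multi-page 16-bit TIFF count images, CSV tables, YAML/JSON
# scan-plan configs, and run manifests.

#' Write photon-count images as a multi-page 16-bit TIFF
#'
#' One page per frame/plane, plain grayscale, counts clipped to the
#' 16-bit range.
#'
#' @param counts Matrix, 3-D array (pages on dim 3), or list of matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tiff <- function(counts, path) {
  if (is.list(counts)) {
    pages <- counts
  } else if (length(dim(counts)) == 3L) {
    pages <- lapply(seq_len(dim(counts)[3]), function(k) counts[, , k])
  } else {
    pages <- list(as.matrix(counts))
  }
  pages <- lapply(pages, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page count TIFF written by [write_counts_tiff()]
#'
#' @param path TIFF file path.
#' @return Array `[ny, nx, pages]` of integer counts.
#' @export
read_counts_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                           length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Read a scan-plan configuration
#'
#' Parses a YAML or JSON scan plan: a `resonant` section (passed to
#' [resonant_config()]) and an `engines` list, each engine holding
#' `engine_id`, optional `jump_time_s`, and a `jobs` list.  Raster jobs
#' have `type: raster`, `origin_mm`, `size_mm`, `pixels`, and optional
#' `bidirectional`, `frames`, `z_offset_um`, `scan_mode`; random-access
#' jobs have `type: random_access`, `points_mm`, `dwell_time_s`,
#' `transition_time_s`.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`) or an already-parsed
#'   list.
#' @return List with `cfg` (a [resonant_config()]) and `schedules` (list
#'   of [engine_schedule()]).
#' @export
read_scan_plan <- function(path) {
  spec <- if (is.list(path)) path
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                 simplifyVector = TRUE)
          else yaml::read_yaml(path)
  res <- spec$resonant
  cfg <- resonant_config(
    frequency = res$frequency %||% 8000,
    fill_fraction = res$fill_fraction %||% 0.9,
    amplitude_mm = res$amplitude_mm %||% (MAX_RESONANT_SCAN_MM / 2),
    effective_line_rate = res$effective_line_rate)
  schedules <- lapply(spec$engines, function(e) {
    jobs <- lapply(e$jobs, function(j) {
      if (identical(j$type, "random_access")) {
        random_access_job(matrix(unlist(j$points_mm), ncol = 2L,
                                 byrow = TRUE),
                          j$dwell_time_s,
                          j$transition_time_s %||% 0)
      } else {
        raster_job(unlist(j$origin_mm), unlist(j$size_mm),
                   unlist(j$pixels),
                   z_offset_um = j$z_offset_um %||% 0,
                   bidirectional = j$bidirectional %||% TRUE,
                   frames = j$frames %||% 1L,
                   scan_mode = j$scan_mode %||% "resonant")
      }
    })
    engine_schedule(jobs, jump_time_s = e$jump_time_s %||% 0.005,
                    engine_id = e$engine_id %||% 1L)
  })
  list(cfg = cfg, schedules = schedules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Timing and throughput summary of a scan plan
#'
#' One row per job: engine, job type, geometry, frame rate, and pixel
#' rate; plus the aggregate throughput and, for engines with multiple
#' jobs, the sequential dead-time fraction at the engine's jump time.
#'
#' @param plan A list as returned by [read_scan_plan()].
#' @return List with `jobs` (data.frame), `megapixels_per_s`, and
#'   `dead_time` (data.frame per multi-job engine, possibly empty).
#' @export
plan_summary <- function(plan) {
  rows <- list(); dead <- list()
  for (sch in plan$schedules) {
    periods <- c()
    for (j in seq_along(sch$jobs)) {
      job <- sch$jobs[[j]]
      if (inherits(job, "raster_job")) {
        ft <- frame_timing(job, plan$cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          engine = sch$engine_id, job = j, type = "raster",
          pixels_x = job$pixels_xy[1], pixels_y = job$pixels_xy[2],
          frame_rate_hz = ft$frame_rate_hz,
          pixels_per_s = ft$pixels_per_frame * ft$frame_rate_hz)
        periods <- c(periods, ft$frame_period_s)
      } else {
        pr <- plan_random_access(job)
        rows[[length(rows) + 1L]] <- data.frame(
          engine = sch$engine_id, job = j, type = "random_access",
          pixels_x = pr$n_points, pixels_y = 1L,
          frame_rate_hz = pr$per_point_rate_hz,
          pixels_per_s = pr$n_points * pr$per_point_rate_hz)
        periods <- c(periods, pr$cycle_period_s)
      }
    }
    if (length(sch$jobs) >= 2L) {
      dead[[length(dead) + 1L]] <- data.frame(
        engine = sch$engine_id,
        jump_time_s = sch$jump_time_s,
        dead_fraction = sequential_dead_fraction(periods, sch$jump_time_s))
    }
  }
  tp <- session_throughput(plan$schedules, plan$cfg)
  list(jobs = do.call(rbind, rows),
       megapixels_per_s = tp$megapixels_per_s,
       dead_time = if (length(dead)) do.call(rbind, dead)
                   else data.frame())
}

#' Write a run manifest
#'
#' JSON sidecar recording the seed, configuration hash, package version
#' and produced artifacts, so any run can be reproduced.
#'
#' @param path Output JSON path.
#' @param seed Seed used.
#' @param config The configuration object (hashed into the manifest).
#' @param outputs Character vector of artifact paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config = NULL, outputs = character()) {
  manifest <- list(
    package = "mesoscan",
    version = as.character(utils::packageVersion("mesoscan")),
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else
      sprintf("%08x", sum(utf8ToInt(paste(deparse(config),
                                          collapse = ""))) %%
                .Machine$integer.max),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
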