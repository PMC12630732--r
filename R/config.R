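# Session configuration: one serializable description of the scene, the
# controller and the calibration procedure, from which every run can be
# reproduced bit for bit given its seed.

#' Default session configuration
#'
#' The shipped scenario: four fiducial markers (184 nm spot width, 1e5
#' counts/frame) near the corners of an 80 x 80 px field at 80 nm/px, the
#' focus reflection (320 nm width, 5e5 counts/frame, tilt gain 2 nm/nm) at
#' the center, 50 ms exposures with shot noise, baseline 100 and 2 counts
#' read noise, a 15-bit / 20 um open-loop stage (0.61 nm quantum), drift of
#' ~1 nm/s with a small diffusive component, and a proportional-dominant
#' controller (kp = 0.8, ki = 0) at a 54 ms correction period.
#'
#' @param seed session seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulator = list(
      drift = list(velocity = c(0.7, -0.5, 0.4),
                   diffusion = c(0.05, 0.05, 0.05)),
      fiducials = list(
        positions_nm = list(c(960, 960), c(960, 5360),
                            c(5360, 960), c(5360, 5360)),
        spot_sigma_nm = 184,
        photons_per_frame = 1e5),
      focus = list(gain = 2, spot_sigma_nm = 320,
                   photons_per_frame = 5e5,
                   base_position_nm = c(3200, 3200)),
      camera = list(pixel_size_nm = 80, shape = c(80L, 80L), baseline = 100,
                    read_noise_sigma = 2, shot_noise = TRUE,
                    exposure_ms = 50),
      stage = list(travel_um = c(20, 20, 20), bit_depth = 15L,
                   settle_lag = 0L)),
    control = list(kp = 0.8, ki = 0, mode = "XYZ", period_s = 0.054,
                   output_limit_nm = 50, deadband = "auto"),
    rois = list(fiducial_size = 11L, focus_size = 31L),
    calibration = list(pixel_steps_nm = c(0, 100, 200, 300, 400),
                       z_steps_nm = c(-100, -50, 0, 50, 100),
                       axis = "x")
  )
}

config_skeleton <- function() {
  list(seed = NULL,
       simulator = list(
         drift = list(velocity = NULL, diffusion = NULL),
         fiducials = list(positions_nm = NULL, spot_sigma_nm = NULL,
                          photons_per_frame = NULL),
         focus = list(gain = NULL, spot_sigma_nm = NULL,
                      photons_per_frame = NULL, base_position_nm = NULL),
         camera = list(pixel_size_nm = NULL, shape = NULL, baseline = NULL,
                       read_noise_sigma = NULL, shot_noise = NULL,
                       exposure_ms = NULL),
         stage = list(travel_um = NULL, bit_depth = NULL, settle_lag = NULL)),
       control = list(kp = NULL, ki = NULL, mode = NULL, period_s = NULL,
                      output_limit_nm = NULL, deadband = NULL),
       rois = list(fiducial_size = NULL, focus_size = NULL),
       calibration = list(pixel_steps_nm = NULL, z_steps_nm = NULL,
                          axis = NULL))
}

missing_keys <- function(skel, cfg, prefix = "") {
  out <- character()
  for (nm in names(skel)) {
    path <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.null(cfg[[nm]])) {
      out <- c(out, path)
    } else if (is.list(skel[[nm]])) {
      out <- c(out, missing_keys(skel[[nm]], cfg[[nm]], path))
    }
  }
  out
}

#' Validate a session configuration
#'
#' @param config configuration list.
#' @return the config, invisibly; a schema error lists every missing key.
#' @export
validate_config <- function(config) {
  miss <- missing_keys(config_skeleton(), config)
  if (length(miss)) {
    stop("invalid config; missing keys: ", paste(miss, collapse = ", "))
  }
  invisible(config)
}

#' Read / write a session configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML; every run logs the
#' exact configuration used.
#'
#' @param path file path.
#' @return for `read_config`, the validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a virtual scope from a configuration
#'
#' @param config configuration list (see [default_config()]).
#' @param seed optional seed overriding `config$seed`.
#' @return a [virtual_scope()].
#' @export
build_scope <- function(config, seed = NULL) {
  validate_config(config)
  sim <- config$simulator
  pos <- do.call(rbind, lapply(sim$fiducials$positions_nm, as.numeric))
  virtual_scope(
    drift = drift_model(sim$drift$velocity, sim$drift$diffusion),
    field = fiducial_field(pos, sim$fiducials$spot_sigma_nm,
                           sim$fiducials$photons_per_frame),
    focus = focus_beam_model(sim$focus$gain, sim$focus$spot_sigma_nm,
                             sim$focus$photons_per_frame,
                             sim$focus$base_position_nm),
    camera = camera_model(sim$camera$pixel_size_nm, sim$camera$shape,
                          sim$camera$baseline, sim$camera$read_noise_sigma,
                          sim$camera$shot_noise, sim$camera$exposure_ms),
    stage = virtual_stage(sim$stage$travel_um, sim$stage$bit_depth,
                          settle_lag = sim$stage$settle_lag),
    seed = if (is.null(seed)) config$seed else seed,
    period = config$control$period_s)
}

#' ROIs implied by a configuration
#'
#' One fiducial ROI centered on each configured marker position and one
#' focus ROI centered on the reflection's base position, at the configured
#' sizes (defaults 11 x 11 px for fiducials, >= +/- 2 sigma at the default
#' spot width, and 31 x 31 px for the larger focus spot).
#'
#' @param config configuration list.
#' @return list of [roi()].
#' @export
rois_from_config <- function(config) {
  validate_config(config)
  ps <- config$simulator$camera$pixel_size_nm
  fs <- as.integer(config$rois$fiducial_size)
  zs <- as.integer(config$rois$focus_size)
  shape <- as.integer(config$simulator$camera$shape)
  rois <- lapply(config$simulator$fiducials$positions_nm, function(p) {
    cpx <- as.numeric(p) / ps  # (x, y) px
    recenter_roi(cpx, c(fs, fs), shape, "fiducial")
  })
  base <- as.numeric(config$simulator$focus$base_position_nm) / ps
  c(rois, list(recenter_roi(base, c(zs, zs), shape, "focus")))
}

#' Build a stabilization session from a configuration
#'
#' @param config configuration list.
#' @param calibration optional list with elements `xy` ([calibrate_pixel_size()]
#'   result) and `z` ([calibrate_z_response()] result); when supplied the
#'   recovered pixel size and axial response are used instead of the
#'   configured ground truth.
#' @return a [stabilization_session()].
#' @export
session_from_config <- function(config, calibration = NULL) {
  validate_config(config)
  sim <- config$simulator
  ps <- if (!is.null(calibration$xy)) calibration$xy$pixel_size
        else sim$camera$pixel_size_nm
  if (!is.null(calibration$z)) {
    zr <- calibration$z$z_response
    za <- calibration$z$z_axis
  } else {
    zr <- sim$camera$pixel_size_nm / abs(sim$focus$gain)
    za <- c(sign(sim$focus$gain), 0)
  }
  db <- config$control$deadband
  stabilization_session(
    rois = rois_from_config(config),
    pixel_size = ps, z_response = zr, z_axis = za,
    mode = config$control$mode,
    period = config$control$period_s,
    kp = config$control$kp, ki = config$control$ki,
    output_limit = config$control$output_limit_nm,
    deadband = if (identical(db, "auto")) NULL else as.numeric(db))
}

#' Auto-detect ROIs from a frame
#'
#' Convenience brightest-spot search: picks the `n_fiducials + 1` brightest
#' well-separated local maxima, classifies the widest spot (largest
#' second-moment width) as the focus reflection, and returns centered ROIs.
#'
#' @param fr a [frame()].
#' @param n_fiducials number of fiducial markers expected.
#' @param fiducial_size,focus_size ROI sizes, px.
#' @param min_separation_px minimum peak separation.
#' @return list of [roi()] (fiducials first, focus last).
#' @export
auto_detect_rois <- function(fr, n_fiducials, fiducial_size = 11L,
                             focus_size = 31L, min_separation_px = 12) {
  stopifnot(inherits(fr, "vm_frame"), n_fiducials >= 1)
  px <- fr$pixels
  d <- dim(px)
  centers <- matrix(NA_real_, n_fiducials + 1L, 2L)
  widths <- rep(NA_real_, n_fiducials + 1L)
  work <- px
  for (i in seq_len(n_fiducials + 1L)) {
    idx <- which.max(work)
    r0 <- (idx - 1L) %% d[1]        # 0-based row
    c0 <- (idx - 1L) %/% d[1]       # 0-based col
    # refine with a local moment estimate
    win <- 7L
    rr <- max(0L, r0 - win):min(d[1] - 1L, r0 + win)
    cc <- max(0L, c0 - win):min(d[2] - 1L, c0 + win)
    sub <- px[rr + 1L, cc + 1L, drop = FALSE]
    w <- pmax(sub - stats::median(sub), 0)
    m <- sum(w)
    cx <- sum(w * (col(sub) - 1)) / m + cc[1]
    cy <- sum(w * (row(sub) - 1)) / m + rr[1]
    sw <- sqrt((sum(w * (col(sub) - 1 + cc[1] - cx)^2) +
                sum(w * (row(sub) - 1 + rr[1] - cy)^2)) / (2 * m))
    centers[i, ] <- c(cx, cy)
    widths[i] <- sw
    # mask out a disc around the peak before the next search
    mask_r <- abs(row(work) - 1 - cy) <= min_separation_px
    mask_c <- abs(col(work) - 1 - cx) <= min_separation_px
    work[mask_r & mask_c] <- -Inf
  }
  focus_i <- which.max(widths)
  out <- vector("list", n_fiducials + 1L)
  j <- 1L
  for (i in seq_len(n_fiducials + 1L)) {
    if (i == focus_i) next
    out[[j]] <- recenter_roi(centers[i, ], c(fiducial_size, fiducial_size),
                             d, "fiducial")
    j <- j + 1L
  }
  out[[n_fiducials + 1L]] <- recenter_roi(centers[focus_i, ],
                                          c(focus_size, focus_size),
                                          d, "focus")
  out
}
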