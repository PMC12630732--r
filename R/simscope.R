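# Pixel convention used throughout: 0-based indices; a spot coordinate of
# (x, y) = (j, i) means the center of the pixel stored at matrix element
# [i + 1, j + 1] (row = y, column = x); pixel i spans [i - 0.5, i + 0.5].

# ---- drift process -------------------------------------------------------

#' Ground-truth sample drift model
#'
#' Thermo-mechanical sample drift is modeled as a deterministic velocity
#' (advection) plus an independent Gaussian random walk per axis. Typical
#' worst-case drift speeds on research microscopes are of order 1 nm/s.
#'
#' @param velocity 3-vector, nm/s.
#' @param diffusion 3-vector, nm^2/s random-walk variance rate; must be >= 0.
#' @return object of class `drift_model`.
#' @export
drift_model <- function(velocity = c(0, 0, 0), diffusion = c(0, 0, 0)) {
  velocity <- as.numeric(velocity)
  diffusion <- as.numeric(diffusion)
  stopifnot(length(velocity) == 3L, length(diffusion) == 3L,
            all(is.finite(velocity)), all(is.finite(diffusion)))
  if (any(diffusion < 0)) {
    stop("diffusion variance rates must be >= 0")
  }
  structure(list(velocity = velocity, diffusion = diffusion),
            class = "drift_model")
}

#' Advance the drift state by one time step
#'
#' @param model a [drift_model()].
#' @param state current 3-vector position, nm.
#' @param dt time step, s (> 0).
#' @param rng optional `rng_stream` to draw the diffusive step from.
#' @return new 3-vector position, nm.
#' @export
advance_drift <- function(model, state, dt, rng = NULL) {
  stopifnot(inherits(model, "drift_model"), length(state) == 3L)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive finite scalar")
  }
  step <- with_stream(rng, stats::rnorm(3L, 0, sqrt(model$diffusion * dt)))
  as.numeric(state) + model$velocity * dt + step
}

#' Full drift trajectory over n equal steps
#'
#' Draws the same increment sequence as `n` successive calls to
#' [advance_drift()] on the same stream, so the stepwise and the whole-path
#' views of the process agree draw for draw.
#'
#' @param model a [drift_model()].
#' @param n number of steps.
#' @param dt step duration, s.
#' @param state starting position, nm.
#' @param rng optional `rng_stream`.
#' @return n x 3 matrix of positions after steps 1..n, nm.
#' @export
drift_path <- function(model, n, dt, state = c(0, 0, 0), rng = NULL) {
  stopifnot(inherits(model, "drift_model"), n >= 1, dt > 0)
  steps <- with_stream(rng, matrix(
    stats::rnorm(3L * n, 0, sqrt(model$diffusion * dt)),
    ncol = 3L, byrow = TRUE))
  incr <- steps + matrix(rep(model$velocity * dt, each = n), ncol = 3L)
  path <- apply(incr, 2L, cumsum)
  if (is.null(dim(path))) path <- matrix(path, nrow = 1L)
  sweep(path, 2L, as.numeric(state), "+")
}

# ---- scene models --------------------------------------------------------

#' Field of fiducial markers
#'
#' Bright immobile scatterers (e.g. 200 nm gold nanoparticles) whose image
#' positions report sample drift. Each is rendered as a pixel-integrated 2D
#' Gaussian of width `spot_sigma`.
#'
#' @param positions_nm k x 2 matrix (x, y) of marker positions in the sample
#'   plane, nm.
#' @param spot_sigma image-plane Gaussian width, nm (> 0). Default 184 nm,
#'   a typical measured width for 200 nm AuNPs in NIR dark-field detection.
#' @param photons_per_frame expected integrated counts per marker per
#'   exposure (> 0).
#' @return object of class `fiducial_field`.
#' @export
fiducial_field <- function(positions_nm, spot_sigma = 184,
                           photons_per_frame = 1e5) {
  positions_nm <- matrix(as.numeric(positions_nm), ncol = 2L)
  stopifnot(nrow(positions_nm) >= 1L, all(is.finite(positions_nm)),
            spot_sigma > 0, photons_per_frame > 0)
  structure(list(positions_nm = positions_nm, spot_sigma = spot_sigma,
                 photons_per_frame = photons_per_frame),
            class = "fiducial_field")
}

#' Reflected focus-beam model
#'
#' The tilted, totally internally reflected auxiliary beam maps an axial
#' sample displacement dz into a lateral displacement dr = gain * dz of its
#' image on the camera; this linear gain is the whole optical lever embodied
#' by the simulator. The spot itself is modeled as a Gaussian.
#'
#' @param gain nm of lateral image shift per nm of defocus (non-zero). The
#'   shift is along the +x image direction for positive gain.
#' @param spot_sigma Gaussian width of the reflected spot, nm.
#' @param photons_per_frame expected integrated counts per exposure.
#' @param base_position_nm 2-vector (x, y), image-plane position at zero
#'   defocus, nm.
#' @return object of class `focus_beam_model`.
#' @export
focus_beam_model <- function(gain = 2, spot_sigma = 320,
                             photons_per_frame = 5e5,
                             base_position_nm = c(3200, 3200)) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain),
            spot_sigma > 0, photons_per_frame > 0,
            length(base_position_nm) == 2L)
  if (gain == 0) stop("focus gain must be non-zero")
  structure(list(gain = gain, spot_sigma = spot_sigma,
                 photons_per_frame = photons_per_frame,
                 base_position_nm = as.numeric(base_position_nm)),
            class = "focus_beam_model")
}

#' Camera model
#'
#' @param pixel_size sample-plane-equivalent pixel size, nm/px (> 0).
#' @param shape (rows, cols) of the sensor.
#' @param baseline constant offset added to every pixel, counts.
#' @param read_noise_sigma Gaussian read noise, counts (0 disables).
#' @param shot_noise logical; apply Poisson noise to the photon signal.
#' @param exposure_ms exposure time, ms (> 0).
#' @return object of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 80, shape = c(80L, 80L), baseline = 100,
                         read_noise_sigma = 2, shot_noise = TRUE,
                         exposure_ms = 50) {
  stopifnot(pixel_size > 0, length(shape) == 2L, all(shape >= 4),
            baseline >= 0, read_noise_sigma >= 0, exposure_ms > 0)
  structure(list(pixel_size = pixel_size, shape = as.integer(shape),
                 baseline = baseline, read_noise_sigma = read_noise_sigma,
                 shot_noise = isTRUE(shot_noise), exposure_ms = exposure_ms),
            class = "camera_model")
}

#' Camera frame
#'
#' @param pixels 2D non-negative intensity matrix (rows = y, cols = x).
#' @param timestamp acquisition time, s.
#' @param pixel_size nm/px.
#' @return object of class `vm_frame`.
#' @export
frame <- function(pixels, timestamp = 0, pixel_size = 80) {
  pixels <- as.matrix(pixels)
  stopifnot(all(is.finite(pixels)), all(pixels >= 0), pixel_size > 0)
  structure(list(pixels = pixels, timestamp = as.numeric(timestamp),
                 pixel_size = pixel_size), class = "vm_frame")
}

# pixel-integrated Gaussian contribution of one spot over the full sensor
integrated_spot <- function(rows, cols, cx, cy, sigma_px, photons) {
  px <- diff(stats::pnorm(((0:cols) - 0.5 - cx) / sigma_px))
  py <- diff(stats::pnorm(((0:rows) - 0.5 - cy) / sigma_px))
  photons * outer(py, px)
}

#' Render one camera frame of the virtual scene
#'
#' Each fiducial is rendered as a pixel-integrated 2D Gaussian displaced
#' laterally by the sample offset; the focus-reflection spot is displaced
#' laterally by `gain * offset_z` from its base position (and is insensitive
#' to lateral sample motion, which is what decouples the XY and Z channels).
#' Poisson shot noise is applied to the photon signal if enabled, then the
#' camera baseline and Gaussian read noise are added and negative values are
#' clipped to zero.
#'
#' @param field a [fiducial_field()].
#' @param focus a [focus_beam_model()], or NULL to render fiducials only.
#' @param camera a [camera_model()].
#' @param sample_offset 3-vector (x, y, z) ground-truth offset, nm.
#' @param rng optional `rng_stream` for the noise draws.
#' @param timestamp frame timestamp, s.
#' @param fiducial_extra optional k x 2 matrix of per-fiducial extra lateral
#'   displacements, nm (used to emulate a detaching marker).
#' @return a [frame()].
#' @export
render_frame <- function(field, focus, camera, sample_offset = c(0, 0, 0),
                         rng = NULL, timestamp = 0, fiducial_extra = NULL) {
  stopifnot(inherits(field, "fiducial_field"),
            is.null(focus) || inherits(focus, "focus_beam_model"),
            inherits(camera, "camera_model"),
            length(sample_offset) == 3L)
  rows <- camera$shape[1]; cols <- camera$shape[2]
  ps <- camera$pixel_size
  off <- as.numeric(sample_offset)

  k <- nrow(field$positions_nm)
  extra <- if (is.null(fiducial_extra)) matrix(0, k, 2L) else
    matrix(as.numeric(fiducial_extra), ncol = 2L)
  stopifnot(nrow(extra) == k)

  centers <- cbind((field$positions_nm[, 1] + off[1] + extra[, 1]) / ps,
                   (field$positions_nm[, 2] + off[2] + extra[, 2]) / ps)
  sigmas <- rep(field$spot_sigma / ps, k)
  photons <- rep(field$photons_per_frame, k)
  labels <- paste0("fiducial ", seq_len(k))
  if (!is.null(focus)) {
    centers <- rbind(centers,
                     c((focus$base_position_nm[1] + focus$gain * off[3]) / ps,
                       focus$base_position_nm[2] / ps))
    sigmas <- c(sigmas, focus$spot_sigma / ps)
    photons <- c(photons, focus$photons_per_frame)
    labels <- c(labels, "focus reflection")
  }

  for (i in seq_along(labels)) {
    m <- 3 * sigmas[i]
    if (centers[i, 1] < m || centers[i, 1] > cols - 1 - m ||
        centers[i, 2] < m || centers[i, 2] > rows - 1 - m) {
      stop(sprintf(
        "spot '%s' at (%.1f, %.1f) px is closer than 3 sigma to the frame edge",
        labels[i], centers[i, 1], centers[i, 2]))
    }
  }

  mu <- matrix(0, rows, cols)
  for (i in seq_along(labels)) {
    mu <- mu + integrated_spot(rows, cols, centers[i, 1], centers[i, 2],
                               sigmas[i], photons[i])
  }

  pix <- with_stream(rng, {
    v <- as.numeric(mu)
    if (camera$shot_noise) v <- as.numeric(stats::rpois(length(v), v))
    v <- v + camera$baseline
    if (camera$read_noise_sigma > 0) {
      v <- v + stats::rnorm(length(v), 0, camera$read_noise_sigma)
    }
    v
  })
  pix <- pmax(pix, 0)
  frame(matrix(pix, rows, cols), timestamp = timestamp, pixel_size = ps)
}

# ---- stage ---------------------------------------------------------------

#' Minimum realizable stage step
#'
#' Open-loop piezo drivers realize positions on a lattice set by the DAC bit
#' depth: quantum = travel / 2^bit_depth. A 15-bit driver over 20 um travel
#' gives 0.61 nm, the floor for position corrections.
#'
#' @param travel_um stage travel, um (> 0). Vectorized.
#' @param bit_depth DAC bit depth (integer >= 1).
#' @return minimum step, nm.
#' @export
min_step <- function(travel_um, bit_depth) {
  stopifnot(all(travel_um > 0), all(bit_depth >= 1),
            all(bit_depth == as.integer(bit_depth)))
  travel_um * 1000 / 2^bit_depth
}

#' Axis map between software and stage coordinates
#'
#' Camera and stage axes may be permuted or inverted relative to each other;
#' `map_apply` sends a software-frame vector to stage coordinates as
#' `sign * v[perm]`.
#'
#' @param perm permutation of 1:3.
#' @param sign 3-vector of +/- 1.
#' @return object of class `axis_map`.
#' @export
axis_map <- function(perm = 1:3, sign = c(1, 1, 1)) {
  perm <- as.integer(perm)
  stopifnot(length(perm) == 3L, setequal(perm, 1:3),
            length(sign) == 3L, all(abs(sign) == 1))
  structure(list(perm = perm, sign = as.numeric(sign)), class = "axis_map")
}

#' @rdname axis_map
#' @param map an `axis_map`.
#' @param v 3-vector.
#' @export
map_apply <- function(map, v) {
  stopifnot(inherits(map, "axis_map"), length(v) == 3L)
  map$sign * as.numeric(v)[map$perm]
}

#' @rdname axis_map
#' @export
map_invert <- function(map) {
  stopifnot(inherits(map, "axis_map"))
  invp <- order(map$perm)
  axis_map(perm = invp, sign = map$sign[invp])
}

#' Quantized open-loop virtual piezo stage
#'
#' Commanded positions are realized only on the quantization lattice
#' `travel / 2^bit_depth` (round-half-to-even, to avoid directional bias),
#' after mapping software axes to stage axes. Positions are centered on zero,
#' so |position| <= travel/2 per axis; out-of-travel targets are clamped and
#' the event recorded. `settle_lag` delays the full effect of a command by
#' that many acquisition ticks (default 0: the command is fully realized
#' before the next frame, matching triggered-mode sequencing in which the
#' stage is only moved between exposures).
#'
#' @param travel_um 3-vector travel, um.
#' @param bit_depth DAC bit depth.
#' @param map an [axis_map()].
#' @param settle_lag integer number of ticks before a command takes effect.
#' @return environment of class `virtual_stage`.
#' @export
virtual_stage <- function(travel_um = c(20, 20, 20), bit_depth = 15L,
                          map = axis_map(), settle_lag = 0L) {
  stopifnot(length(travel_um) == 3L, all(travel_um > 0), settle_lag >= 0)
  e <- new.env(parent = emptyenv())
  e$travel_nm <- as.numeric(travel_um) * 1000
  e$bit_depth <- as.integer(bit_depth)
  e$quantum <- min_step(as.numeric(travel_um), bit_depth)
  e$map <- map
  e$settle_lag <- as.integer(settle_lag)
  e$position <- c(0, 0, 0)      # realized, stage coordinates
  e$pending <- list()
  e$events <- character()
  class(e) <- "virtual_stage"
  e
}

#' Command the virtual stage to an absolute target
#'
#' @param stage a [virtual_stage()].
#' @param target 3-vector absolute target in software coordinates, nm.
#' @return realized 3-vector in stage coordinates (quantized), nm.
#' @export
apply_move <- function(stage, target) {
  stopifnot(inherits(stage, "virtual_stage"), length(target) == 3L,
            all(is.finite(target)))
  t_stage <- map_apply(stage$map, as.numeric(target))
  lim <- stage$travel_nm / 2
  if (any(abs(t_stage) > lim)) {
    msg <- sprintf("target (%.2f, %.2f, %.2f) nm outside travel; clamped",
                   t_stage[1], t_stage[2], t_stage[3])
    stage$events <- c(stage$events, msg)
    warning(msg)
    t_stage <- pmin(pmax(t_stage, -lim), lim)
  }
  realized <- stage$quantum * round(t_stage / stage$quantum)
  if (stage$settle_lag <= 0L) {
    stage$position <- realized
  } else {
    stage$pending <- c(stage$pending,
                       list(list(pos = realized, lag = stage$settle_lag)))
  }
  realized
}

# advance pending (settling) commands by one acquisition tick
stage_tick <- function(stage) {
  if (!length(stage$pending)) return(invisible(NULL))
  keep <- list()
  for (p in stage$pending) {
    p$lag <- p$lag - 1L
    if (p$lag <= 0L) stage$position <- p$pos else keep <- c(keep, list(p))
  }
  stage$pending <- keep
  invisible(NULL)
}

#' Read the stage position
#'
#' @param stage a [virtual_stage()].
#' @param frame_of `"software"` (inverse axis map applied) or `"stage"`.
#' @return 3-vector, nm.
#' @export
stage_position <- function(stage, frame_of = c("software", "stage")) {
  frame_of <- match.arg(frame_of)
  if (frame_of == "stage") return(stage$position)
  map_apply(map_invert(stage$map), stage$position)
}

#' Remap a frame from camera axes to stage axes
#'
#' When camera x/y are permuted or inverted with respect to the stage, the
#' camera proxy must compensate by remapping the image before handing it to
#' the control loop. Only the lateral part of the map is used.
#'
#' @param fr a [frame()].
#' @param map an [axis_map()]; its z component is ignored.
#' @return remapped [frame()].
#' @export
frame_remap <- function(fr, map) {
  stopifnot(inherits(fr, "vm_frame"), inherits(map, "axis_map"))
  px <- fr$pixels
  if (map$perm[1] == 2L) px <- t(px)           # swap x <-> y
  if (map$sign[1] < 0) px <- px[, ncol(px):1]  # invert x (columns)
  if (map$sign[2] < 0) px <- px[nrow(px):1, ]  # invert y (rows)
  frame(px, timestamp = fr$timestamp, pixel_size = fr$pixel_size)
}

# ---- virtual scope + hardware proxies ------------------------------------

#' Assemble a virtual microscope
#'
#' Bundles the drift process, scene, camera and stage into one stateful
#' simulation with a virtual clock, and exposes the same camera/stage proxy
#' contracts the control loop would use with real hardware (see
#' [scope_camera()], [scope_stage()]). The sample offset seen by the camera
#' is ground-truth drift plus the realized stage position.
#'
#' @param drift a [drift_model()].
#' @param field a [fiducial_field()].
#' @param focus a [focus_beam_model()].
#' @param camera a [camera_model()].
#' @param stage a [virtual_stage()].
#' @param seed session seed for the component RNG streams.
#' @param period virtual acquisition period, s (time advanced per frame).
#' @return environment of class `virtual_scope`.
#' @export
virtual_scope <- function(drift, field, focus, camera, stage,
                          seed = 1L, period = 0.054) {
  stopifnot(period > 0)
  e <- new.env(parent = emptyenv())
  e$drift <- drift; e$field <- field; e$focus <- focus
  e$camera <- camera; e$stage <- stage
  e$period <- period
  e$time <- 0
  e$drift_state <- c(0, 0, 0)
  e$fiducial_extra <- matrix(0, nrow(field$positions_nm), 2L)
  st <- rng_streams(seed, 2L)
  e$drift_rng <- st[[1L]]
  e$noise_rng <- st[[2L]]
  e$cmd_target <- c(0, 0, 0)    # last commanded software-frame target
  class(e) <- "virtual_scope"
  e
}

#' Ground-truth sample offset of a virtual scope
#'
#' Drift plus realized stage position (software frame), i.e. the offset the
#' camera actually sees.
#'
#' @param scope a [virtual_scope()].
#' @return 3-vector, nm.
#' @export
sample_offset <- function(scope) {
  stopifnot(inherits(scope, "virtual_scope"))
  scope$drift_state + stage_position(scope$stage, "software")
}

scope_advance <- function(scope, dt) {
  scope$drift_state <- advance_drift(scope$drift, scope$drift_state, dt,
                                     rng = scope$drift_rng)
  scope$time <- scope$time + dt
  stage_tick(scope$stage)
  invisible(NULL)
}

scope_render <- function(scope) {
  render_frame(scope$field, scope$focus, scope$camera,
               sample_offset = sample_offset(scope),
               rng = scope$noise_rng, timestamp = scope$time,
               fiducial_extra = scope$fiducial_extra)
}

#' Camera proxy for a virtual scope
#'
#' Returns the minimal camera contract used by the control loop: `acquire()`
#' returns one triggered [frame()] (advancing the virtual clock by the scope
#' period first, so drift accrues between exposures), and `set_exposure(ms)`
#' adjusts the exposure. The returned frame is already expressed in stage
#' axes (identity map in the shipped simulator).
#'
#' @param scope a [virtual_scope()].
#' @return list with functions `acquire` and `set_exposure`.
#' @export
scope_camera <- function(scope) {
  stopifnot(inherits(scope, "virtual_scope"))
  list(
    acquire = function() {
      scope_advance(scope, scope$period)
      scope_render(scope)
    },
    set_exposure = function(ms) {
      stopifnot(ms > 0)
      scope$camera$exposure_ms <- ms
      invisible(ms)
    }
  )
}

#' Stage proxy for a virtual scope
#'
#' Minimal stage contract: read the current position and set the lateral
#' (x, y) and axial (z) positions independently, plus travel/step queries.
#' Commands are absolute software-frame targets in nm.
#'
#' @param scope a [virtual_scope()].
#' @return list with functions `get_position`, `set_xy`, `set_z`,
#'   `min_step`, `travel_nm`.
#' @export
scope_stage <- function(scope) {
  stopifnot(inherits(scope, "virtual_scope"))
  list(
    get_position = function() stage_position(scope$stage, "software"),
    set_xy = function(x, y) {
      scope$cmd_target[1:2] <- c(x, y)
      apply_move(scope$stage, scope$cmd_target)
    },
    set_z = function(z) {
      scope$cmd_target[3] <- z
      apply_move(scope$stage, scope$cmd_target)
    },
    min_step = function() min(scope$stage$quantum),
    travel_nm = function() scope$stage$travel_nm
  )
}
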