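# Shared fixtures, all built in code.

# pixel matrix of a pixel-integrated 2D Gaussian with peak amplitude A and
# constant offset b -- the model contract of fit_gaussian_2d, evaluated
# directly (independent of the fitting code path).
model_spot <- function(nr, nc, x0, y0, sx, sy, A, b = 0) {
  dx <- diff(pnorm(((0:nc) - 0.5 - x0) / sx))
  dy <- diff(pnorm(((0:nr) - 0.5 - y0) / sy))
  A * 2 * pi * sx * sy * outer(dy, dx) + b
}

# the default scenario with all stochastic elements switched off
noiseless_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$simulator$drift$velocity <- c(0, 0, 0)
  cfg$simulator$drift$diffusion <- c(0, 0, 0)
  cfg$simulator$camera$shot_noise <- FALSE
  cfg$simulator$camera$read_noise_sigma <- 0
  cfg
}

# single fiducial on a small sensor (optionally noiseless), for fit fixtures
single_spot_scene <- function(photons = 5000, baseline = 0, read_noise = 0,
                              shot_noise = TRUE, shape = c(21L, 21L),
                              pixel_size = 80, sigma_nm = 184,
                              center_px = c(10, 10)) {
  list(field = fiducial_field(matrix(center_px * pixel_size, ncol = 2),
                              spot_sigma = sigma_nm,
                              photons_per_frame = photons),
       camera = camera_model(pixel_size = pixel_size, shape = shape,
                             baseline = baseline,
                             read_noise_sigma = read_noise,
                             shot_noise = shot_noise))
}

make_scope <- function(cfg, seed = cfg$seed) build_scope(cfg, seed)

# a locked session + proxies for a scope built from cfg (ground-truth optics)
locked_session <- function(cfg, scope, enabled = TRUE, mode = "XYZ",
                           deadband = NULL) {
  cfg$control$mode <- mode
  ses <- session_from_config(cfg)
  ses$enabled <- enabled
  if (!is.null(deadband)) ses$deadband <- deadband
  cam <- scope_camera(scope)
  stg <- scope_stage(scope)
  lock(ses, cam$acquire())
  list(session = ses, camera = cam, stage = stg)
}
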