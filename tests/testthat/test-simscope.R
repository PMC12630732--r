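test_that("drift advances deterministically and diffusively as specified", {
  still <- drift_model()
  expect_equal(advance_drift(still, c(5, 5, 5), dt = 1), c(5, 5, 5))

  adv <- drift_model(velocity = c(1, 0, 0))
  expect_equal(advance_drift(adv, c(0, 0, 0), dt = 2), c(2, 0, 0))

  expect_error(advance_drift(still, c(0, 0, 0), dt = -1), "positive")
  expect_error(drift_model(diffusion = c(-1, 0, 0)), ">= 0")

  # Monte-Carlo vs closed form sqrt(D * dt): D = 0.25 nm^2/s, dt = 1 s
  dif <- drift_model(diffusion = c(0.25, 0, 0))
  set.seed(42)
  dx <- replicate(1e5, advance_drift(dif, c(0, 0, 0), dt = 1)[1])
  expect_equal(sd(dx), 0.5, tolerance = 0.02)
})

test_that("stepwise drift and the whole-path view agree draw for draw", {
  model <- drift_model(velocity = c(1, -0.5, 0.2),
                       diffusion = c(0.3, 0.1, 0))
  s1 <- rng_streams(7, 1)[[1]]
  s2 <- rng_streams(7, 1)[[1]]
  n <- 25
  state <- c(0, 0, 0)
  stepwise <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    state <- advance_drift(model, state, dt = 0.1, rng = s1)
    stepwise[i, ] <- state
  }
  expect_equal(drift_path(model, n, dt = 0.1, rng = s2), stepwise)
})

test_that("drift statistics match velocity and diffusion rates", {
  model <- drift_model(velocity = c(1, 0, 0), diffusion = c(0.25, 0.1, 0))
  n <- 5; dt <- 0.2; reps <- 1e4
  set.seed(99)
  finals <- t(replicate(reps, drift_path(model, n, dt)[n, ]))
  expect_equal(mean(finals[, 1]), 1 * n * dt, tolerance = 0.05)
  expect_equal(var(finals[, 1]), 0.25 * n * dt, tolerance = 0.05)
  expect_equal(var(finals[, 2]), 0.1 * n * dt, tolerance = 0.05)
  expect_equal(var(finals[, 3]), 0)
})

test_that("minimum stage step follows travel / 2^bits", {
  expect_equal(round(min_step(20, 15), 2), 0.61)
  expect_equal(min_step(20, 16), 20000 / 2^16)
  expect_equal(min_step(1, 10), 1000 / 1024)
  expect_error(min_step(-1, 10))
  expect_error(min_step(20, 0))
})

test_that("stage moves are quantized, mapped and clamped", {
  stg <- virtual_stage(travel_um = c(20, 20, 20), bit_depth = 15L)
  q <- stg$quantum[1]
  # lattice identity
  expect_equal(apply_move(stg, c(10 * q, -3 * q, 0)), c(10 * q, -3 * q, 0))
  # 1.0 nm rounds to 2 quanta = 1.2207 nm
  expect_equal(apply_move(stg, c(1, 0, 0))[1], 2 * q)
  expect_equal(round(2 * q, 4), 1.2207)

  # permuted/inverted axes: (a, b, c) -> (b, -a, c)
  m <- axis_map(perm = c(2L, 1L, 3L), sign = c(1, -1, 1))
  stg2 <- virtual_stage(map = m)
  q2 <- stg2$quantum[1]
  a <- 5 * q2; b <- 3 * q2; cc <- 7 * q2
  expect_equal(apply_move(stg2, c(a, b, cc)), c(b, -a, cc))
  # software-frame readback undoes the map
  expect_equal(stage_position(stg2, "software"), c(a, b, cc))

  # out-of-travel clamping with a recorded event (travel/2 = 10 um)
  expect_warning(apply_move(stg, c(3e7, 0, 0)), "clamped")
  expect_length(stg$events, 1)
  expect_equal(stg$position[1], 1e4)
})

test_that("axis maps invert exactly", {
  set.seed(1)
  for (i in 1:20) {
    m <- axis_map(perm = sample(1:3), sign = sample(c(-1, 1), 3, TRUE))
    v <- rnorm(3, sd = 100)
    expect_equal(map_apply(map_invert(m), map_apply(m, v)), v)
  }
})

test_that("settle lag delays command realization by whole ticks", {
  stg <- virtual_stage(settle_lag = 2L)
  q <- stg$quantum[1]
  apply_move(stg, c(10 * q, 0, 0))
  expect_equal(stg$position, c(0, 0, 0))
  nanolock:::stage_tick(stg)
  expect_equal(stg$position, c(0, 0, 0))
  nanolock:::stage_tick(stg)
  expect_equal(stg$position, c(10 * q, 0, 0))
})

test_that("rendered spots land where commanded", {
  sc <- single_spot_scene(photons = 1e4, shot_noise = FALSE,
                          center_px = c(10, 8))
  fr <- render_frame(sc$field, NULL, sc$camera)
  idx <- which(fr$pixels == max(fr$pixels), arr.ind = TRUE)
  # 0-based (row, col) = (y, x) = (8, 10)
  expect_equal(unname(idx[1, ]), c(8 + 1, 10 + 1))

  # moving by exactly one pixel size shifts the image by one column
  fr2 <- render_frame(sc$field, NULL, sc$camera,
                      sample_offset = c(sc$camera$pixel_size, 0, 0))
  nc <- ncol(fr$pixels)
  expect_identical(fr2$pixels[, 2:nc], fr$pixels[, 1:(nc - 1)])
})

test_that("defocus moves only the focus reflection, by gain * dz", {
  cfg <- noiseless_config()
  sim <- cfg$simulator
  field <- fiducial_field(do.call(rbind, sim$fiducials$positions_nm),
                          sim$fiducials$spot_sigma_nm,
                          sim$fiducials$photons_per_frame)
  focus <- focus_beam_model(gain = 2, spot_sigma = sim$focus$spot_sigma_nm,
                            photons_per_frame = sim$focus$photons_per_frame,
                            base_position_nm = sim$focus$base_position_nm)
  cam <- camera_model(shape = c(80L, 80L), baseline = 0,
                      read_noise_sigma = 0, shot_noise = FALSE)
  fr0 <- render_frame(field, focus, cam, c(0, 0, 0))
  fr1 <- render_frame(field, focus, cam, c(0, 0, 10))

  focus_roi <- roi(c(25L, 25L), c(31L, 31L), "focus")
  g0 <- fit_gaussian_2d(extract_roi(fr0, focus_roi))
  g1 <- fit_gaussian_2d(extract_roi(fr1, focus_roi))
  shift_nm <- (c(g1$x, g1$y) - c(g0$x, g0$y)) * cam$pixel_size
  expect_equal(shift_nm, c(20, 0), tolerance = 1e-6)
  # the thresholded CoM used by the focus channel sees the same shift
  c0 <- center_of_mass(extract_roi(fr0, focus_roi))
  c1 <- center_of_mass(extract_roi(fr1, focus_roi))
  expect_equal((c1$r - c0$r) * cam$pixel_size, c(20, 0), tolerance = 0.05)

  fid_roi <- roi(c(7L, 7L), c(11L, 11L), "fiducial")
  f0 <- fit_gaussian_2d(extract_roi(fr0, fid_roi))
  f1 <- fit_gaussian_2d(extract_roi(fr1, fid_roi))
  expect_equal(c(f1$x, f1$y), c(f0$x, f0$y), tolerance = 1e-9)
})

test_that("a spot too close to the frame edge is rejected by name", {
  sc <- single_spot_scene(center_px = c(2, 10), shot_noise = FALSE)
  expect_error(render_frame(sc$field, NULL, sc$camera), "fiducial 1")
})

test_that("photons are conserved in the noiseless image", {
  sc <- single_spot_scene(photons = 12345, baseline = 0, shot_noise = FALSE,
                          shape = c(41L, 41L), center_px = c(20, 20))
  fr <- render_frame(sc$field, NULL, sc$camera)
  expect_equal(sum(fr$pixels), 12345, tolerance = 1e-3)
})

test_that("identical seeds give bit-identical frame sequences", {
  cfg <- default_config()
  sc1 <- make_scope(cfg, seed = 11)
  sc2 <- make_scope(cfg, seed = 11)
  cam1 <- scope_camera(sc1); cam2 <- scope_camera(sc2)
  for (i in 1:5) {
    expect_identical(cam1$acquire()$pixels, cam2$acquire()$pixels)
  }
  sc3 <- make_scope(cfg, seed = 12)
  expect_false(identical(scope_camera(sc3)$acquire()$pixels,
                         make_scope(cfg, 11) |> scope_camera() |>
                           (\(cm) cm$acquire()$pixels)()))
})

test_that("frame remap compensates permuted or inverted camera axes", {
  sc <- single_spot_scene(center_px = c(12, 8), shot_noise = FALSE)
  fr <- render_frame(sc$field, NULL, sc$camera)
  m <- axis_map(perm = c(1L, 2L, 3L), sign = c(-1, 1, 1))
  fr_x <- frame_remap(fr, m)
  idx <- which(fr_x$pixels == max(fr_x$pixels), arr.ind = TRUE)
  expect_equal(unname(idx[1, 2]) - 1L, ncol(fr$pixels) - 1L - 12L)
})
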