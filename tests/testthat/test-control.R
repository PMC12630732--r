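test_that("the PI response follows its definition", {
  ctrl <- pi_controller(kp = 0.8, ki = 0)
  expect_equal(pi_response(ctrl, 0, 0.054), 0)
  expect_equal(pi_response(ctrl, 2, 0.054), -1.6)

  ctrl2 <- pi_controller(kp = 0, ki = 0.5)
  out <- NA
  for (i in 1:4) out <- pi_response(ctrl2, 1, 0.05)
  expect_equal(out, -0.5 * 4 * 1 * 0.05)

  # output clamp and anti-windup
  ctrl3 <- pi_controller(kp = 1, ki = 1, output_limit = 5)
  for (i in 1:100) out <- pi_response(ctrl3, 100, 1)
  expect_equal(out, -5)
  expect_lte(abs(ctrl3$ki * ctrl3$integral), ctrl3$output_limit)

  reset_controller(ctrl2)
  expect_equal(ctrl2$integral, 0)
  expect_equal(pi_response(ctrl2, 0, 0.05), 0)
})

test_that("locking defines the zero of displacement", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  expect_equal(nrow(h$session$setpoints$fiducials), 4)
  expect_length(h$session$setpoints$focus_r0, 2)

  # nothing moved since lock: displacement is zero
  rec <- stabilization_step(h$session, h$camera, h$stage)
  expect_equal(rec$avg, c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(rec$dz, 0, tolerance = 1e-8)

  # re-lock after a drift step resets the reference
  scope$drift_state <- c(3, 0, 0)
  lock(h$session, h$camera$acquire())
  rec2 <- stabilization_step(h$session, h$camera, h$stage)
  expect_equal(rec2$avg, c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("lock is refused when an ROI cannot localize, naming it", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  ses <- session_from_config(cfg)
  fr <- scope_camera(scope)$acquire()
  fr$pixels[1:18, 1:18] <- 50  # flatten the first fiducial's ROI
  expect_error(lock(ses, fr), "fiducial ROI 1")
})

test_that("a step disturbance decays geometrically under proportional control", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  scope$drift_state <- c(5, 0, 0)   # +5 nm step offset in x
  resid <- numeric(4)
  for (i in 1:4) resid[i] <- stabilization_step(h$session, h$camera, h$stage)$avg[1]
  expect_equal(resid[1], 5, tolerance = 0.01)
  expect_lt(abs(resid[4]), 1)
  expect_true(all(diff(abs(resid)) <= 1e-9))  # never grows back
})

test_that("XY and Z channels are fully decoupled", {
  cfg <- noiseless_config()
  cfg$simulator$drift$velocity <- c(3, 0, 0)   # lateral drift only
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope, mode = "Z")
  tr <- run_loop(h$session, h$camera, h$stage, 3)
  axes <- vapply(h$session$command_log, function(x) x$axis, character(1))
  expect_false(any(axes == "xy"))
  # lateral drift accumulates while z stays locked
  expect_gt(abs(tr$avg_dx_nm[nrow(tr)]), 5)
  expect_lt(max(abs(tr$dz_nm), na.rm = TRUE), 1)
})

test_that("residuals stay within one stage quantum with zero drift and noise", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  q <- h$stage$min_step()
  scope$drift_state <- c(2.0, -1.3, 1.1)
  tr <- run_loop(h$session, h$camera, h$stage, 2)
  late <- tr[20:nrow(tr), ]
  expect_lt(max(abs(late$avg_dx_nm)), q + 1e-9)
  expect_lt(max(abs(late$avg_dy_nm)), q + 1e-9)
  expect_lt(max(abs(late$dz_nm)), q + 1e-9)
})

test_that("with nothing to correct, the stage is never commanded beyond a quantum", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  run_loop(h$session, h$camera, h$stage, 2)
  expect_length(h$session$command_log, 0)
  expect_equal(h$stage$get_position(), c(0, 0, 0))
})

test_that("run_loop paces records at the configured period", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  tr <- run_loop(h$session, h$camera, h$stage, 10)
  expect_equal(nrow(tr), 185)  # floor(10 / 0.054)
  expect_true(all(diff(tr$t_s) > 0))
})

test_that("a disabled session tracks but never commands the stage", {
  cfg <- default_config()
  scope <- make_scope(cfg, seed = 3)
  h <- locked_session(cfg, scope, enabled = FALSE)
  tr <- run_loop(h$session, h$camera, h$stage, 3)
  expect_length(h$session$command_log, 0)
  expect_equal(h$stage$get_position(), c(0, 0, 0))
  expect_equal(nrow(tr), floor(3 / 0.054))
})

test_that("the loop output is independent of fiducial ordering", {
  run_perm <- function(perm) {
    cfg <- noiseless_config()
    cfg$simulator$drift$velocity <- c(0.8, -0.6, 0.5)
    cfg$simulator$fiducials$positions_nm <-
      cfg$simulator$fiducials$positions_nm[perm]
    scope <- make_scope(cfg)
    h <- locked_session(cfg, scope)
    run_loop(h$session, h$camera, h$stage, 2)
  }
  t1 <- run_perm(1:4)
  t2 <- run_perm(c(3, 1, 4, 2))
  for (col in c("avg_dx_nm", "avg_dy_nm", "dz_nm",
                "cmd_x_nm", "cmd_y_nm", "cmd_z_nm")) {
    expect_equal(t2[[col]], t1[[col]], tolerance = 1e-9)
  }
})

test_that("reference shifts move the sample under closed loop and invert cleanly", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  q <- h$stage$min_step()

  sp0 <- h$session$setpoints
  shift_reference(h$session, c(0, 0, 0))
  expect_equal(h$session$setpoints$fiducials, sp0$fiducials)

  shift_reference(h$session, c(10, 0, 0))
  run_loop(h$session, h$camera, h$stage, 1)
  expect_equal(sample_offset(scope)[1], 10, tolerance = 0.7)

  shift_reference(h$session, c(-10, 0, 0))
  run_loop(h$session, h$camera, h$stage, 1)
  expect_lt(abs(sample_offset(scope)[1]), 2 * q)

  # a shift that would push setpoints out of their ROIs is refused
  expect_error(shift_reference(h$session, c(500, 0, 0)), "refused")
  # disabled sessions cannot shift (the loop would never follow)
  h$session$enabled <- FALSE
  expect_error(shift_reference(h$session, c(1, 0, 0)), "not enabled")
})

test_that("axial reference shifts drive the sample in z", {
  cfg <- noiseless_config()
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  shift_reference(h$session, c(0, 0, 8))
  run_loop(h$session, h$camera, h$stage, 1)
  expect_equal(sample_offset(scope)[3], 8, tolerance = 0.7)
})

test_that("a detaching fiducial is flagged in the loop and stabilization recovers", {
  cfg <- default_config()
  scope <- make_scope(cfg, seed = 6)
  h <- locked_session(cfg, scope)
  v_rogue <- 60  # nm/s independent walk of fiducial 2
  n <- floor(4 / 0.054)
  for (i in seq_len(n)) {
    scope$fiducial_extra[2, 1] <- v_rogue * 0.054 * i
    stabilization_step(h$session, h$camera, h$stage)
  }
  expect_false(h$session$valid[2])
  expect_true(all(h$session$valid[c(1, 3, 4)]))

  # residuals after flagging stay sub-nm: run on and summarize
  tr <- run_loop(h$session, h$camera, h$stage, 20)
  expect_lt(sd(tr$avg_dx_nm, na.rm = TRUE), 1)
  expect_lt(sd(tr$avg_dy_nm, na.rm = TRUE), 1)
  # invalidation is sticky even after the rogue stops moving
  scope$fiducial_extra[2, 1] <- 0
  stabilization_step(h$session, h$camera, h$stage)
  expect_false(h$session$valid[2])
})

test_that("losing every fiducial pauses lateral correction while Z continues", {
  cfg <- noiseless_config()
  cfg$simulator$fiducials$positions_nm <-
    cfg$simulator$fiducials$positions_nm[1:2]
  scope <- make_scope(cfg)
  h <- locked_session(cfg, scope)
  scope$drift_state <- c(0, 0, 4)
  # push both fiducials far out of their ROIs (but still inside the frame)
  scope$fiducial_extra[, 1] <- 1200
  rec <- stabilization_step(h$session, h$camera, h$stage)
  expect_true(all(is.na(rec$avg)))
  expect_match(rec$note, "paused")
  expect_false(rec$sent[["xy"]])
  expect_true(is.finite(rec$dz))
  expect_true(rec$sent[["z"]])
})
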