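# Calibration against commanded stage motion, and Gaussian-fit precision
# summaries of stabilization traces.

# re-center an ROI of given size on a (x, y) frame-pixel position
recenter_roi <- function(center_xy, size, frame_dim, kind = "fiducial") {
  half <- (as.integer(size) - 1L) %/% 2L
  orow <- round(center_xy[2]) - half[1]
  ocol <- round(center_xy[1]) - half[2]
  orow <- min(max(orow, 0L), frame_dim[1] - size[1])
  ocol <- min(max(ocol, 0L), frame_dim[2] - size[2])
  roi(c(orow, ocol), size, kind)
}

#' Calibrate the camera pixel size against stage motion
#'
#' Steps the stage through `steps_nm` along one lateral axis, localizes a
#' tracked fiducial at each position, and fits the stage's read-back
#' (realized, quantized) position against the measured pixel coordinate;
#' the slope is the pixel size in nm/px, with its standard error and R^2
#' from the linear fit. The tracking ROI follows the fiducial between steps.
#' Run with stabilization disabled - the loop would fight the calibration
#' motion.
#'
#' @param camera,stage hardware proxies (see [scope_camera()],
#'   [scope_stage()]).
#' @param steps_nm >= 3 distinct commanded absolute positions, nm.
#' @param axis `"x"` or `"y"`.
#' @param start_roi [roi()] containing the fiducial at the first position.
#' @return object of class `calibration_xy`: `pixel_size`, `pixel_size_se`
#'   (nm/px), `r2`, `axis`, `data`.
#' @export
calibrate_pixel_size <- function(camera, stage, steps_nm = seq(0, 400, 100),
                                 axis = c("x", "y"), start_roi) {
  axis <- match.arg(axis)
  steps_nm <- as.numeric(steps_nm)
  if (length(unique(steps_nm)) < 3L) {
    stop("calibration needs at least 3 distinct commanded positions")
  }
  ai <- if (axis == "x") 1L else 2L
  home <- stage$get_position()
  on.exit({
    stage$set_xy(home[1], home[2])
  }, add = TRUE)

  r <- start_roi
  measured <- realized <- rep(NA_real_, length(steps_nm))
  last_fit <- NULL
  for (s in seq_along(steps_nm)) {
    cur <- stage$get_position()
    if (axis == "x") stage$set_xy(steps_nm[s], cur[2])
    else stage$set_xy(cur[1], steps_nm[s])
    fr <- camera$acquire()
    ft <- fit_gaussian_2d(extract_roi(fr, r), seed = last_fit)
    if (!isTRUE(ft$converged)) {
      stop(sprintf("calibration rejected: localization failed at step %d (%s)",
                   s, ft$message))
    }
    pos_px <- c(r$origin[2] + ft$x, r$origin[1] + ft$y)
    measured[s] <- pos_px[ai]
    realized[s] <- stage$get_position()[ai]
    r <- recenter_roi(pos_px, r$size, dim(fr$pixels), "fiducial")
    last_fit <- NULL  # ROI moved; reseed from moments
  }

  ord <- order(realized)
  dmeas <- diff(measured[ord])
  if (any(dmeas == 0) || (any(dmeas > 0) && any(dmeas < 0))) {
    stop("calibration rejected: measured positions not monotonic in stage position")
  }
  fit <- stats::lm(realized ~ measured)
  sm <- summary(fit)
  slope <- abs(stats::coef(fit)[["measured"]])
  structure(list(pixel_size = slope,
                 pixel_size_se = sm$coefficients["measured", "Std. Error"],
                 r2 = sm$r.squared, axis = axis,
                 data = data.frame(commanded_nm = steps_nm,
                                   realized_nm = realized,
                                   measured_px = measured)),
            class = "calibration_xy")
}

#' Calibrate the axial (focus) response against stage motion
#'
#' Steps the stage through `z_steps_nm`, records the center of mass of the
#' reflected focus spot at each position, extracts the direction of
#' reflection motion (principal component of the measured positions) and
#' fits the projected shift in px against the realized axial position in nm.
#' The axial response is the inverse slope, in nm of defocus per px of
#' reflection shift; the axis is oriented so that the response is positive,
#' preserving the sign of defocus downstream. Curvature of the physical
#' response over the calibration range shows up as a depressed R^2.
#'
#' @param camera,stage hardware proxies.
#' @param z_steps_nm >= 3 distinct commanded absolute Z positions, nm.
#' @param focus_roi [roi()] containing the reflection at every step.
#' @param com_threshold threshold fraction for [center_of_mass()].
#' @return object of class `calibration_z`: `z_response`, `z_response_se`
#'   (nm/px), `z_axis` (unit 2-vector), `r2`, `data`.
#' @export
calibrate_z_response <- function(camera, stage,
                                 z_steps_nm = c(-100, -50, 0, 50, 100),
                                 focus_roi, com_threshold = 0.2) {
  z_steps_nm <- as.numeric(z_steps_nm)
  if (length(unique(z_steps_nm)) < 3L) {
    stop("calibration needs at least 3 distinct commanded Z positions")
  }
  home <- stage$get_position()
  on.exit(stage$set_z(home[3]), add = TRUE)

  rx <- ry <- realized <- rep(NA_real_, length(z_steps_nm))
  for (s in seq_along(z_steps_nm)) {
    stage$set_z(z_steps_nm[s])
    fr <- camera$acquire()
    est <- tryCatch(center_of_mass(extract_roi(fr, focus_roi), com_threshold),
                    error = function(e) NULL)
    if (is.null(est)) {
      stop(sprintf("calibration rejected: focus localization failed at step %d", s))
    }
    rx[s] <- focus_roi$origin[2] + est$r[1]
    ry[s] <- focus_roi$origin[1] + est$r[2]
    realized[s] <- stage$get_position()[3]
  }

  M <- cbind(rx, ry)
  if (max(apply(M, 2L, function(v) diff(range(v)))) < 0.02) {
    stop("no measurable reflection shift; use larger Z steps or a larger tilt gain")
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  z_axis <- pc$rotation[, 1L]
  proj <- drop(sweep(M, 2L, colMeans(M)) %*% z_axis)
  fit <- stats::lm(proj ~ realized)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["realized"]]  # px of shift per nm of defocus
  if (!is.finite(slope) || slope == 0) {
    stop("no measurable reflection shift; use larger Z steps or a larger tilt gain")
  }
  if (slope < 0) {
    z_axis <- -z_axis
    slope <- -slope
  }
  se_slope <- sm$coefficients["realized", "Std. Error"]
  structure(list(z_response = 1 / slope,
                 z_response_se = se_slope / slope^2,
                 z_axis = as.numeric(z_axis), r2 = sm$r.squared,
                 data = data.frame(commanded_nm = z_steps_nm,
                                   realized_nm = realized,
                                   x_px = rx, y_px = ry)),
            class = "calibration_z")
}

#' Gaussian-fit precision of a displacement trace
#'
#' Histograms the displacements (Freedman-Diaconis bin width) and fits a
#' Gaussian to the bin counts; the fitted width is the headline precision,
#' with the plain sample standard deviation always co-reported because
#' histogram fits are binning-sensitive. For a Gaussian-like trace the two
#' agree within ~15%. A constant trace yields `sigma = NA` (fit rejected)
#' with `sample_sd = 0`.
#'
#' @param x numeric displacement samples, nm; needs >= `min_samples` finite
#'   values.
#' @param min_samples minimum sample count.
#' @return object of class `precision_stats`: `sigma` (Gaussian fit, NA if
#'   the fit is rejected), `sample_sd`, `mean`, `n`, `fit_ok`.
#' @export
precision_stats <- function(x, min_samples = 100L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < min_samples) {
    stop(sprintf("need at least %d finite samples, got %d",
                 min_samples, length(x)))
  }
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(list(sigma = NA_real_, sample_sd = 0, mean = x[1],
                          n = length(x), fit_ok = FALSE),
                     class = "precision_stats"))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  df <- data.frame(mid = h$mids, cnt = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(cnt ~ A * exp(-(mid - mu)^2 / (2 * sg^2)),
                      data = df,
                      start = list(A = max(df$cnt), mu = mean(x), sg = s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  sigma <- if (!is.null(fit)) abs(stats::coef(fit)[["sg"]]) else NA_real_
  structure(list(sigma = sigma, sample_sd = s, mean = mean(x),
                 n = length(x), fit_ok = is.finite(sigma)),
            class = "precision_stats")
}

headline_sigma <- function(ps) {
  if (isTRUE(ps$fit_ok)) ps$sigma else ps$sample_sd
}

#' Combined localization precision in quadrature
#'
#' `sqrt(sigma_crb^2 + sigma_stab^2)`: the stabilization residual adds in
#' quadrature to the estimator's Cramer-Rao bound. Symmetric and monotone
#' non-decreasing in both arguments; the bound itself is an external input
#' (it requires the localization-estimator theory of the nanoscopy method).
#'
#' @param sigma_crb,sigma_stab non-negative precisions, nm. Vectorized.
#' @return combined precision, nm.
#' @export
sigma_total <- function(sigma_crb, sigma_stab) {
  if (any(!is.finite(sigma_crb)) || any(!is.finite(sigma_stab)) ||
      any(sigma_crb < 0) || any(sigma_stab < 0)) {
    stop("precisions must be finite and >= 0")
  }
  sqrt(sigma_crb^2 + sigma_stab^2)
}

#' Precision summary of a stabilization trace
#'
#' Per-axis Gaussian-fit widths of the displacement histograms, the lateral
#' stabilization precision `sigma_stab = sqrt(sigma_x^2 + sigma_y^2)`, and,
#' when a Cramer-Rao bound is supplied, the combined `sigma_total`.
#'
#' @param trace data.frame from [run_loop()] (or [read_trace_csv()]).
#' @param sigma_crb optional external Cramer-Rao bound, nm.
#' @return object of class `precision_summary`.
#' @export
precision_summary <- function(trace, sigma_crb = NULL) {
  need <- c("avg_dx_nm", "avg_dy_nm", "dz_nm")
  missing <- setdiff(need, names(trace))
  if (length(missing)) {
    stop("trace is missing columns: ", paste(missing, collapse = ", "))
  }
  sx <- precision_stats(trace$avg_dx_nm)
  sy <- precision_stats(trace$avg_dy_nm)
  sz <- precision_stats(trace$dz_nm)
  stab <- sqrt(headline_sigma(sx)^2 + headline_sigma(sy)^2)
  out <- list(x = sx, y = sy, z = sz,
              sigma_stabilization = stab,
              sigma_crb = sigma_crb,
              sigma_total = if (!is.null(sigma_crb))
                sigma_total(sigma_crb, stab) else NA_real_,
              n_samples = nrow(trace))
  structure(out, class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  fmt <- function(ps) {
    if (isTRUE(ps$fit_ok)) {
      sprintf("%.3f nm (Gaussian fit; sample sd %.3f nm, n = %d)",
              ps$sigma, ps$sample_sd, ps$n)
    } else {
      sprintf("fit rejected; sample sd %.3f nm (n = %d)", ps$sample_sd, ps$n)
    }
  }
  cat("Stabilization precision summary\n")
  cat("  sigma_x: ", fmt(x$x), "\n", sep = "")
  cat("  sigma_y: ", fmt(x$y), "\n", sep = "")
  cat("  sigma_z: ", fmt(x$z), "\n", sep = "")
  cat(sprintf("  sigma_stabilization (lateral, quadrature): %.3f nm\n",
              x$sigma_stabilization))
  if (!is.null(x$sigma_crb)) {
    cat(sprintf("  sigma_total (CRB %.2f nm in quadrature): %.3f nm\n",
                x$sigma_crb, x$sigma_total))
  }
  invisible(x)
}
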