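# Spot localization: seeded 2D Gaussian fitting for fiducials, center of
# mass for the focus reflection, and conversion to 3D displacements.

#' Region of interest
#'
#' @param origin (row, col) of the ROI's top-left pixel, 0-based.
#' @param size (rows, cols) in pixels; fiducial ROIs must be >= 5 x 5.
#' @param kind `"fiducial"` or `"focus"`.
#' @return object of class `roi`.
#' @export
roi <- function(origin, size, kind = c("fiducial", "focus")) {
  kind <- match.arg(kind)
  origin <- as.integer(origin); size <- as.integer(size)
  stopifnot(length(origin) == 2L, length(size) == 2L,
            all(origin >= 0), all(size >= 1))
  if (kind == "fiducial" && any(size < 5L)) {
    stop("fiducial ROIs must be at least 5 x 5 px")
  }
  structure(list(origin = origin, size = size, kind = kind), class = "roi")
}

#' Extract ROI pixels from a frame
#'
#' @param fr a [frame()].
#' @param r a [roi()]; must lie fully inside the frame.
#' @return pixel matrix of dimension `r$size`.
#' @export
extract_roi <- function(fr, r) {
  stopifnot(inherits(fr, "vm_frame"), inherits(r, "roi"))
  d <- dim(fr$pixels)
  if (r$origin[1] + r$size[1] > d[1] || r$origin[2] + r$size[2] > d[2]) {
    stop(sprintf("ROI at (%d, %d) size (%d, %d) extends outside the %d x %d frame",
                 r$origin[1], r$origin[2], r$size[1], r$size[2], d[1], d[2]))
  }
  fr$pixels[r$origin[1] + seq_len(r$size[1]),
            r$origin[2] + seq_len(r$size[2]), drop = FALSE]
}

spot_fit_failure <- function(msg) {
  structure(list(x = NA_real_, y = NA_real_, sigma_x = NA_real_,
                 sigma_y = NA_real_, amplitude = NA_real_, offset = NA_real_,
                 converged = FALSE, residual_norm = NA_real_, message = msg),
            class = "spot_fit")
}

# intensity-weighted centroid + second-moment widths as a fitting seed
moment_seed <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  border <- c(pixels[1, ], pixels[nr, ], pixels[, 1], pixels[, nc])
  b0 <- stats::median(border)
  w <- pmax(pixels - b0, 0)
  m <- sum(w)
  if (m <= 0) return(NULL)
  xs <- col(pixels) - 1; ys <- row(pixels) - 1
  cx <- sum(w * xs) / m
  cy <- sum(w * ys) / m
  sx <- sqrt(max(sum(w * (xs - cx)^2) / m, 0.25))
  sy <- sqrt(max(sum(w * (ys - cy)^2) / m, 0.25))
  c(x = cx, y = cy, sx = sx, sy = sy, A = max(pixels) - b0, b = b0)
}

#' Sub-pixel 2D Gaussian fit of a spot
#'
#' Least-squares fit of a pixel-integrated elliptical 2D Gaussian plus a free
#' additive offset; the pixel model is the analytic integral of
#' `A * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2)))` over each
#' pixel area (difference of normal CDFs), which stays correct when the spot
#' width approaches the pixel size. `A` is the peak amplitude of the
#' underlying continuous Gaussian. The optimizer is Levenberg-Marquardt with
#' box bounds keeping the center inside the ROI and the widths positive.
#'
#' The fit never throws on bad data: degenerate input (flat or empty ROI) or
#' optimizer failure yields `converged = FALSE` with a diagnostic message.
#'
#' @param pixels ROI intensity matrix.
#' @param seed optional previous `spot_fit` (ROI coordinates) to seed from,
#'   as done frame-to-frame in the control loop; the default seed is the
#'   intensity-weighted centroid with second-moment widths.
#' @return object of class `spot_fit` with fields `x`, `y`, `sigma_x`,
#'   `sigma_y` (px, 0-based ROI coordinates), `amplitude`, `offset`
#'   (counts), `converged`, `residual_norm`, `message`.
#' @export
fit_gaussian_2d <- function(pixels, seed = NULL) {
  pixels <- as.matrix(pixels)
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (nr < 3L || nc < 3L) return(spot_fit_failure("ROI smaller than 3 x 3"))
  if (!all(is.finite(pixels))) return(spot_fit_failure("non-finite pixels"))
  if (diff(range(pixels)) <= 0) return(spot_fit_failure("flat ROI"))

  init <- NULL
  if (!is.null(seed) && inherits(seed, "spot_fit") && isTRUE(seed$converged)) {
    init <- c(seed$x, seed$y, seed$sigma_x, seed$sigma_y,
              seed$amplitude, seed$offset)
  }
  if (is.null(init)) {
    ms <- moment_seed(pixels)
    if (is.null(ms)) return(spot_fit_failure("no signal above background"))
    init <- as.numeric(ms)
  }

  lower <- c(-0.5, -0.5, 0.2, 0.2, 0, -Inf)
  upper <- c(nc - 0.5, nr - 0.5, nc, nr, Inf, Inf)
  init <- pmin(pmax(init, lower + 1e-6), ifelse(is.finite(upper), upper - 1e-6, init))

  ex <- (0:nc) - 0.5
  ey <- (0:nr) - 0.5
  resid_fn <- function(p) {
    dx <- diff(stats::pnorm((ex - p[1]) / p[3]))
    dy <- diff(stats::pnorm((ey - p[2]) / p[4]))
    as.numeric(p[5] * 2 * pi * p[3] * p[4] * outer(dy, dx) + p[6] - pixels)
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(res) || !(res$info %in% 1:4) || !all(is.finite(res$par))) {
    return(spot_fit_failure(
      if (is.null(res)) "optimizer error" else paste("no convergence:", res$message)))
  }
  p <- res$par
  if (p[5] <= 0 || p[5] < 1e-4 * max(abs(pixels))) {
    return(spot_fit_failure("no significant spot amplitude in ROI"))
  }
  structure(list(x = p[1], y = p[2], sigma_x = p[3], sigma_y = p[4],
                 amplitude = p[5], offset = p[6], converged = TRUE,
                 residual_norm = sqrt(sum(res$fvec^2)) / max(1, sum(pixels)),
                 message = "ok"),
            class = "spot_fit")
}

#' Thresholded center of mass of the focus-reflection spot
#'
#' Intensity-weighted mean pixel coordinate over pixels at or above
#' `threshold_fraction * max`, after subtracting that threshold level (plain
#' center of mass is biased by the camera baseline; the subtraction removes
#' the bias to first order).
#'
#' @param pixels ROI intensity matrix.
#' @param threshold_fraction fraction of the ROI maximum, in `[0, 1)`.
#' @return object of class `focus_estimate` with `r = c(x, y)` (px, 0-based
#'   ROI coordinates) and `mass` (summed weight above threshold).
#' @export
center_of_mass <- function(pixels, threshold_fraction = 0.2) {
  pixels <- as.matrix(pixels)
  stopifnot(threshold_fraction >= 0, threshold_fraction < 1)
  m <- max(pixels)
  if (!is.finite(m) || m <= 0) stop("no signal in focus ROI")
  w <- pixels - threshold_fraction * m
  w[w < 0] <- 0
  mass <- sum(w)
  if (mass <= 0) stop("no pixels above the center-of-mass threshold")
  structure(list(r = c(sum(w * (col(pixels) - 1)) / mass,
                       sum(w * (row(pixels) - 1)) / mass),
                 mass = mass),
            class = "focus_estimate")
}

#' Lateral displacement of one fiducial from its setpoint
#'
#' @param fit a converged `spot_fit` (same coordinate frame as `setpoint`).
#' @param setpoint (x0, y0) setpoint, px.
#' @param pixel_size nm/px.
#' @return c(dx, dy) in nm, or c(NA, NA) when the fit did not converge (the
#'   marker is marked invalid for this frame; no value is produced).
#' @export
displacement_xy <- function(fit, setpoint, pixel_size) {
  stopifnot(inherits(fit, "spot_fit"), length(setpoint) == 2L, pixel_size > 0)
  if (!isTRUE(fit$converged)) return(c(NA_real_, NA_real_))
  (c(fit$x, fit$y) - as.numeric(setpoint)) * pixel_size
}

#' Axial displacement from the focus-reflection shift
#'
#' The reflection's displacement from its setpoint is projected (signed) onto
#' the calibrated shift axis and converted with the calibrated axial
#' response, preserving the sign of defocus.
#'
#' @param est a `focus_estimate`.
#' @param r0 setpoint (x, y), px.
#' @param z_axis unit 2-vector, direction of reflection motion for positive
#'   defocus (from [calibrate_z_response()]).
#' @param z_response nm of defocus per px of projected reflection shift.
#' @return dz in nm.
#' @export
displacement_z <- function(est, r0, z_axis, z_response) {
  stopifnot(inherits(est, "focus_estimate"), length(r0) == 2L,
            length(z_axis) == 2L, is.finite(z_response), z_response != 0)
  sum((est$r - as.numeric(r0)) * as.numeric(z_axis)) * z_response
}

#' Average lateral displacement over valid fiducials
#'
#' Unweighted mean; averaging K markers improves the lateral precision by
#' sqrt(K) relative to a single marker.
#'
#' @param displacements k x 2 matrix of (dx, dy), nm.
#' @param valid logical vector of length k.
#' @return c(dx, dy) mean over valid markers, nm.
#' @export
average_displacement <- function(displacements, valid = NULL) {
  displacements <- matrix(as.numeric(displacements), ncol = 2L)
  k <- nrow(displacements)
  if (is.null(valid)) valid <- rep(TRUE, k)
  stopifnot(length(valid) == k)
  valid <- valid & is.finite(displacements[, 1]) & is.finite(displacements[, 2])
  if (!any(valid)) {
    stop("no valid fiducial markers: lateral lock lost")
  }
  colMeans(displacements[valid, , drop = FALSE])
}

# one-frame update of the detachment state machine; state carries
# valid / dev_count / fail_count per fiducial. Invalidation is sticky.
detach_update <- function(state, dx, dy, converged,
                          threshold_nm = 50, consecutive = 3L) {
  k <- length(state$valid)
  if (sum(state$valid) < 2L) return(state)  # need >= 2 for relative check
  for (i in which(state$valid)) {
    if (!isTRUE(converged[i])) {
      state$fail_count[i] <- state$fail_count[i] + 1L
      state$dev_count[i] <- 0L
      next
    }
    state$fail_count[i] <- 0L
    others <- setdiff(which(state$valid & converged), i)
    if (!length(others)) next
    mdx <- stats::median(dx[others])
    mdy <- stats::median(dy[others])
    dev <- sqrt((dx[i] - mdx)^2 + (dy[i] - mdy)^2)
    state$dev_count[i] <-
      if (is.finite(dev) && dev > threshold_nm) state$dev_count[i] + 1L else 0L
  }
  drop <- state$valid &
    (state$dev_count >= consecutive | state$fail_count >= consecutive)
  state$valid[drop] <- FALSE
  state
}

#' Flag detached fiducial markers in a displacement track
#'
#' A marker is invalidated (sticky, until manual reset) when its lateral
#' displacement deviates from the median of the other tracked markers by more
#' than `threshold_nm` for `consecutive` frames, or when its fit fails for
#' `consecutive` frames. With fewer than two tracked markers the relative
#' comparison is impossible and flagging is disabled.
#'
#' @param dx,dy frames x k matrices of per-fiducial displacements, nm (NA
#'   where the fit failed).
#' @param converged optional frames x k logical matrix; default: finite dx.
#' @param threshold_nm deviation threshold, nm.
#' @param consecutive number of consecutive offending frames.
#' @return logical vector of length k: TRUE for still-valid markers.
#' @export
detect_detachment <- function(dx, dy, converged = NULL,
                              threshold_nm = 50, consecutive = 3L) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  stopifnot(all(dim(dx) == dim(dy)))
  k <- ncol(dx)
  if (is.null(converged)) converged <- is.finite(dx)
  state <- list(valid = rep(TRUE, k), dev_count = integer(k),
                fail_count = integer(k))
  for (f in seq_len(nrow(dx))) {
    state <- detach_update(state, dx[f, ], dy[f, ], converged[f, ],
                           threshold_nm = threshold_nm,
                           consecutive = consecutive)
  }
  state$valid
}
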