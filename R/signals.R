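#' Construct a measurement epoch from wrist-sensor time series
#'
#' A measurement epoch is the finite observation period `[0, T]` over which a
#' wrist-worn sensor records movement from one upper limb. Channels share one
#' strictly increasing, uniform time grid starting at `t = 0`, sampled at
#' `fs` Hz. Accelerometer data may be supplied in g or m/s^2 (the unit is
#' recorded and converted on demand); gyroscope data are in deg/s.
#'
#' @param limb `"left"` or `"right"`.
#' @param t Numeric vector of per-sample times in seconds. Must start at 0,
#'   be strictly increasing and uniform (relative jitter below `1e-6`).
#' @param accel Numeric matrix with 3 columns (x, y, z). The x axis is the
#'   forearm long axis pointing distally; z points out of the dorsal wrist
#'   when the arm hangs pronated.
#' @param gyro Optional numeric matrix with 3 columns, deg/s, same grid.
#' @param accel_unit `"m/s^2"` (default) or `"g"`.
#' @param valid Optional logical vector marking samples where the sensor was
#'   worn and recording; `FALSE` samples propagate as missing through
#'   windowed averages.
#'
#' @return An object of class `"measurement_epoch"`: a list with elements
#'   `limb`, `t`, `fs`, `T`, `accel`, `gyro`, `accel_unit`, `valid`.
#' @examples
#' t <- seq(0, 10, by = 1 / 50)
#' acc <- cbind(0, 0, rep(9.81, length(t)))
#' ep <- measurement_epoch("left", t, acc)
#' ep$fs
#' @export
measurement_epoch <- function(limb, t, accel, gyro = NULL,
                              accel_unit = c("m/s^2", "g"), valid = NULL) {
  limb <- match.arg(limb, c("left", "right"))
  accel_unit <- match.arg(accel_unit)
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("epoch needs at least two samples")
  if (abs(t[1L]) > 1e-9) stop("time grid must start at t = 0")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L]) {
    stop("non-uniform time grid; resample first (see read_epoch)")
  }
  fs <- 1 / dt[1L]
  accel <- as_channel3(accel, n, "accel")
  if (!is.null(gyro)) gyro <- as_channel3(gyro, n, "gyro")
  if (!is.null(valid)) {
    valid <- as.logical(valid)
    if (length(valid) != n) stop("valid mask length mismatch")
  }
  structure(
    list(limb = limb, t = t, fs = fs, T = t[n] + 1 / fs,
         accel = accel, gyro = gyro, accel_unit = accel_unit, valid = valid),
    class = "measurement_epoch"
  )
}

as_channel3 <- function(x, n, what) {
  x <- as.matrix(x)
  if (nrow(x) != n || ncol(x) != 3L) {
    stop(sprintf("%s must be an n x 3 matrix on the epoch grid", what))
  }
  if (anyNA(x)) stop(sprintf("%s contains NA; use the valid mask instead", what))
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' Accelerometer channel in a requested unit
#' @param epoch A [measurement_epoch()].
#' @param unit `"m/s^2"` or `"g"`.
#' @return n x 3 matrix.
#' @keywords internal
accel_in <- function(epoch, unit = c("m/s^2", "g")) {
  unit <- match.arg(unit)
  a <- epoch$accel
  if (identical(unit, epoch$accel_unit)) return(a)
  if (unit == "g") a / STANDARD_GRAVITY else a * STANDARD_GRAVITY
}

STANDARD_GRAVITY <- 9.80665

#' @export
print.measurement_epoch <- function(x, ...) {
  cat(sprintf("<measurement_epoch> %s limb, %.5g s at %.4g Hz (%d samples)\n",
              x$limb, x$T, x$fs, length(x$t)))
  cat(sprintf("  channels: accel [%s]%s\n", x$accel_unit,
              if (is.null(x$gyro)) "" else ", gyro [deg/s]"))
  if (!is.null(x$valid)) {
    cat(sprintf("  valid: %.1f%% of samples\n", 100 * mean(x$valid)))
  }
  invisible(x)
}

#' Construct a binary upper-limb use signal
#'
#' Upper-limb use is the binary construct marking the presence of a voluntary,
#' meaningful movement or posture: `u(t) = 1` while the limb is in use, else 0.
#'
#' @param limb `"left"` or `"right"`.
#' @param t Time grid in seconds (uniform, from 0).
#' @param u 0/1 (or logical) vector on that grid.
#' @param valid Optional logical wear mask.
#' @return Object of class `"use_signal"` with fields `limb`, `t`, `fs`, `u`,
#'   `valid`.
#' @export
use_signal <- function(limb, t, u, valid = NULL) {
  limb <- match.arg(limb, c("left", "right"))
  grid <- check_grid(t)
  u <- as.numeric(u)
  if (length(u) != length(t)) stop("u and t length mismatch")
  if (anyNA(u) || !all(u %in% c(0, 1))) stop("u must be binary (0/1)")
  if (!is.null(valid) && length(valid) != length(t)) {
    stop("valid mask length mismatch")
  }
  structure(list(limb = limb, t = as.numeric(t), fs = grid$fs, u = u,
                 valid = valid),
            class = "use_signal")
}

#' Construct a non-negative instantaneous intensity signal
#'
#' Instantaneous intensity of use reflects how strenuous a movement or posture
#' is at each instant. By construction it is zero whenever the limb is not in
#' use; [gate_intensity()] enforces that gating against a use signal.
#'
#' @inheritParams use_signal
#' @param mu Non-negative vector on the grid.
#' @param units Free-text label for the intensity measure (e.g. `"counts/s"`).
#' @return Object of class `"intensity_signal"`.
#' @export
intensity_signal <- function(limb, t, mu, units = "a.u.", valid = NULL) {
  limb <- match.arg(limb, c("left", "right"))
  grid <- check_grid(t)
  mu <- as.numeric(mu)
  if (length(mu) != length(t)) stop("mu and t length mismatch")
  if (anyNA(mu) || any(mu < 0)) stop("mu must be non-negative")
  if (!is.null(valid) && length(valid) != length(t)) {
    stop("valid mask length mismatch")
  }
  structure(list(limb = limb, t = as.numeric(t), fs = grid$fs, mu = mu,
                 units = units, valid = valid),
            class = "intensity_signal")
}

#' Construct a task label signal
#'
#' Task labels mark which of `p` predefined tasks the limb performs at each
#' sample; 0 means none of them. A non-zero label requires the limb to be in
#' use at that sample, which is validated against `u` when supplied. No task
#' recogniser is provided here; the type exists so labelled data can be
#' carried alongside use/intensity signals.
#'
#' @inheritParams use_signal
#' @param tau Integer vector in `0..p`.
#' @param p Number of distinct tasks.
#' @param u Optional binary use vector to validate the use constraint against.
#' @return Object of class `"task_label_signal"`.
#' @export
task_label_signal <- function(limb, t, tau, p, u = NULL) {
  limb <- match.arg(limb, c("left", "right"))
  grid <- check_grid(t)
  tau <- as.integer(tau)
  if (length(tau) != length(t)) stop("tau and t length mismatch")
  p <- as.integer(p)
  if (p < 1L || anyNA(tau) || any(tau < 0L) || any(tau > p)) {
    stop("tau must lie in 0..p")
  }
  if (!is.null(u) && any(tau > 0L & u == 0)) {
    stop("non-zero task labels require the limb to be in use")
  }
  structure(list(limb = limb, t = as.numeric(t), fs = grid$fs,
                 tau = tau, p = p),
            class = "task_label_signal")
}

check_grid <- function(t) {
  if (length(t) < 1L) stop("empty signal")
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L]) stop("non-uniform time grid")
    list(fs = 1 / dt[1L])
  } else {
    list(fs = NA_real_)
  }
}

same_grid <- function(a, b) {
  length(a$t) == length(b$t) && max(abs(a$t - b$t)) <= 1e-9
}

#' Classify each sample as unimanual, bimanual, or no use
#'
#' From the two limbs' binary use signals, each instant is exactly one of:
#' no use, unimanual left (`u_l (1 - u_r)`), unimanual right
#' (`u_r (1 - u_l)`), or bimanual (`u_r u_l`).
#'
#' @param u_left,u_right [use_signal()] objects on a shared grid.
#' @return Factor of length `n` with levels `none`, `unimanual_left`,
#'   `unimanual_right`, `bimanual`.
#' @examples
#' t <- seq(0, 0.3, by = 0.1)
#' ul <- use_signal("left", t, c(0, 1, 1, 0))
#' ur <- use_signal("right", t, c(0, 0, 1, 1))
#' limb_use_modes(ul, ur)
#' @export
limb_use_modes <- function(u_left, u_right) {
  stopifnot(inherits(u_left, "use_signal"), inherits(u_right, "use_signal"))
  if (!same_grid(u_left, u_right)) stop("use signals are on different grids")
  code <- 2 * u_right$u + u_left$u  # 0 none, 1 left, 2 right, 3 both
  factor(c("none", "unimanual_left", "unimanual_right", "bimanual")[code + 1L],
         levels = c("none", "unimanual_left", "unimanual_right", "bimanual"))
}
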