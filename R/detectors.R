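#' Activity-count parameters
#'
#' Constants for the accelerometer activity-count chain implemented by
#' [activity_counts()]: band-pass cutoffs, the dead-band below which filtered
#' acceleration is ignored, the saturation ceiling, the quantisation step
#' (8-bit actigraph convention), and the aggregation epoch. All acceleration
#' thresholds are in g.
#'
#' @param epoch_len Aggregation epoch in seconds (counts are summed per epoch).
#' @param band Band-pass cutoffs in Hz, `c(low, high)` with
#'   `0 < low < high < fs/2`.
#' @param deadband Dead-band threshold in g.
#' @param saturation Saturation ceiling in g.
#' @param quant_step Quantisation step in g per count.
#' @return A list of class `"ac_params"`.
#' @export
ac_params <- function(epoch_len = 1, band = c(0.25, 2.5),
                      deadband = 0.068, saturation = 2.13,
                      quant_step = 0.0164) {
  stopifnot(epoch_len > 0, length(band) == 2L, band[1L] > 0,
            band[2L] > band[1L], deadband >= 0, saturation > deadband,
            quant_step > 0)
  structure(list(epoch_len = epoch_len, band = band, deadband = deadband,
                 saturation = saturation, quant_step = quant_step),
            class = "ac_params")
}

#' Gross-movement (GM) score parameters
#'
#' Constants for [gm_use()]: the functional forearm pitch window, the gyro
#' magnitude threshold separating movement from stillness, the smoothing
#' window applied to the gyro magnitude, and the complementary-filter
#' coefficient used for pitch estimation. The defaults (pitch within +/-30
#' degrees of horizontal, 10 deg/s threshold, 1 s smoothing) follow the common
#' gross-movement convention; they are conventions, not fixed truths, and
#' should be tuned per application.
#'
#' @param pitch_range Functional pitch window in degrees, `c(lo, hi)`.
#' @param movement_threshold Smoothed gyro magnitude threshold, deg/s.
#' @param smooth Gyro smoothing window in seconds.
#' @param alpha Complementary filter coefficient in (0, 1); the gyro
#'   integration weight (accelerometer inclination gets `1 - alpha`).
#' @return A list of class `"gm_params"`.
#' @export
gm_params <- function(pitch_range = c(-30, 30), movement_threshold = 10,
                      smooth = 1, alpha = 0.98) {
  stopifnot(length(pitch_range) == 2L, pitch_range[1L] < pitch_range[2L],
            movement_threshold > 0, smooth > 0, alpha > 0, alpha < 1)
  structure(list(pitch_range = pitch_range,
                 movement_threshold = movement_threshold,
                 smooth = smooth, alpha = alpha),
            class = "gm_params")
}

#' Accelerometer activity counts
#'
#' An intensity-of-use measure computed from the tri-axial accelerometer with
#' a simplified actigraph-style chain: band-pass filter each axis (removing
#' the DC gravity component), take the vector magnitude, apply a dead-band,
#' saturate, quantise to integer steps, and sum the steps over consecutive
#' epochs. A stationary sensor therefore yields exactly zero counts, and the
#' output is invariant to any constant acceleration offset. The returned
#' signal is *ungated*: pass it through [gate_intensity()] with a use signal
#' before computing windowed averages.
#'
#' @param epoch A [measurement_epoch()] with an accelerometer channel.
#' @param params An [ac_params()] object.
#' @return An [intensity_signal()] on the epoch-length grid (one sample per
#'   `epoch_len`, timestamped at the epoch start), units
#'   `"counts/<epoch_len>s"`.
#' @export
activity_counts <- function(epoch, params = ac_params()) {
  stopifnot(inherits(epoch, "measurement_epoch"),
            inherits(params, "ac_params"))
  if (is.null(epoch$accel)) stop("accelerometer channel required")
  if (epoch$fs < 2 * params$band[2L]) {
    stop("sampling rate too low for the requested band-pass")
  }
  acc_g <- accel_in(epoch, "g")
  bp <- signal::butter(2, params$band / (epoch$fs / 2), type = "pass")
  # demean per axis first: the zero-phase filter otherwise leaks the DC
  # (gravity) level into edge transients
  filt <- apply(acc_g, 2L, function(col) {
    signal::filtfilt(bp, col - mean(col))
  })
  mag <- sqrt(rowSums(filt^2))
  mag[mag < params$deadband] <- 0
  mag <- pmin(mag, params$saturation)
  steps <- floor(mag / params$quant_step)
  per_epoch <- max(1L, as.integer(round(params$epoch_len * epoch$fs)))
  n_ep <- length(steps) %/% per_epoch
  if (n_ep < 1L) stop("epoch shorter than one aggregation epoch")
  counts <- colSums(matrix(steps[seq_len(n_ep * per_epoch)],
                           nrow = per_epoch))
  t_ep <- (seq_len(n_ep) - 1L) * params$epoch_len
  valid <- NULL
  if (!is.null(epoch$valid)) {
    vmat <- matrix(epoch$valid[seq_len(n_ep * per_epoch)], nrow = per_epoch)
    valid <- colSums(vmat) == per_epoch
  }
  intensity_signal(epoch$limb, t_ep, counts,
                   units = sprintf("counts/%gs", params$epoch_len),
                   valid = valid)
}

#' Thresholded activity-count use detection
#'
#' The simplest use measure: the limb is declared in use whenever the
#' activity counts exceed a threshold (strictly). High sensitivity, poor
#' specificity: any movement above threshold counts as use, including passive
#' transport of the arm.
#'
#' @param counts An [intensity_signal()] of activity counts.
#' @param threshold Non-negative count threshold; `u = 1` iff
#'   `counts > threshold`.
#' @return A [use_signal()] on the counts grid.
#' @examples
#' cts <- intensity_signal("right", c(0, 1, 2), c(0, 5, 2), units = "counts/1s")
#' threshold_use(cts, 2)$u  # 0 1 0
#' @export
threshold_use <- function(counts, threshold = 2) {
  stopifnot(inherits(counts, "intensity_signal"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a non-negative scalar")
  }
  use_signal(counts$limb, counts$t, as.numeric(counts$mu > threshold),
             valid = counts$valid)
}

#' Gross-movement (GM) score use detection
#'
#' Flags use whenever there is arm movement (smoothed gyro magnitude above
#' `movement_threshold`) *and* the forearm is within a functional range of
#' orientations (`pitch_range`). Pitch — the elevation of the forearm long
#' axis above the horizontal — is estimated by a first-order complementary
#' filter fusing accelerometer inclination with integrated gyro pitch rate.
#' Highly specific (movements outside functional orientations are rejected)
#' but insensitive to postures and to in-range passive motion. Requires a
#' gyroscope; the detector is unavailable for accelerometer-only recordings.
#'
#' @param epoch A [measurement_epoch()] with accel and gyro channels.
#' @param params A [gm_params()] object.
#' @return A [use_signal()] on the raw sample grid, with the estimated pitch
#'   trace (degrees) attached as attribute `"pitch"`.
#' @export
gm_use <- function(epoch, params = gm_params()) {
  stopifnot(inherits(epoch, "measurement_epoch"),
            inherits(params, "gm_params"))
  if (is.null(epoch$gyro)) {
    stop("GM score requires a gyroscope channel (IMU data)")
  }
  pitch <- estimate_pitch(epoch, params$alpha)
  gmag <- sqrt(rowSums(epoch$gyro^2))
  k <- max(1L, as.integer(round(params$smooth * epoch$fs)))
  smoothed <- as.numeric(stats::filter(gmag, rep(1 / k, k), sides = 2))
  # moving average is NA at the edges; fall back to the raw magnitude there
  smoothed[is.na(smoothed)] <- gmag[is.na(smoothed)]
  moving <- smoothed > params$movement_threshold
  in_range <- pitch >= params$pitch_range[1L] & pitch <= params$pitch_range[2L]
  u <- use_signal(epoch$limb, epoch$t, as.numeric(moving & in_range),
                  valid = epoch$valid)
  attr(u, "pitch") <- pitch
  u
}

# Forearm pitch (deg) from a complementary filter: accelerometer inclination
# corrects the integrated gyro pitch rate (gyro y axis). Initialised from the
# first accelerometer sample.
estimate_pitch <- function(epoch, alpha = 0.98) {
  acc <- accel_in(epoch, "m/s^2")
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm < 1e-9] <- 1e-9
  ratio <- pmin(1, pmax(-1, acc[, 1L] / nrm))
  pitch_acc <- asin(ratio) * 180 / pi
  rate <- epoch$gyro[, 2L]  # deg/s about the y (mediolateral) axis
  dt <- 1 / epoch$fs
  n <- length(rate)
  pitch <- numeric(n)
  pitch[1L] <- pitch_acc[1L]
  for (k in seq.int(2L, n)) {
    pitch[k] <- alpha * (pitch[k - 1L] + rate[k] * dt) +
      (1 - alpha) * pitch_acc[k]
  }
  pitch
}

#' Gate an intensity signal by a use signal
#'
#' Enforces the defining constraint of instantaneous intensity: `mu` is the
#' raw intensity measure multiplied pointwise by the binary use signal, so
#' intensity is zero whenever the limb is not in use. When the two signals
#' live on different grids (e.g. per-second counts vs per-sample use), the
#' use signal is resampled onto the intensity grid by nearest-neighbour
#' lookup before gating.
#'
#' @param u A [use_signal()].
#' @param raw An [intensity_signal()] (ungated).
#' @return An [intensity_signal()] on the grid of `raw` with
#'   `mu = u * raw$mu`.
#' @examples
#' t <- c(0, 1, 2)
#' u <- use_signal("left", t, c(1, 0, 1))
#' raw <- intensity_signal("left", t, c(3, 4, 5))
#' gate_intensity(u, raw)$mu  # 3 0 5
#' @export
gate_intensity <- function(u, raw) {
  stopifnot(inherits(u, "use_signal"), inherits(raw, "intensity_signal"))
  if (same_grid(u, raw)) {
    uu <- u$u
  } else {
    idx <- findInterval(raw$t + 1e-9, u$t)
    if (any(idx < 1L)) stop("intensity grid starts before the use grid")
    uu <- u$u[idx]
  }
  intensity_signal(raw$limb, raw$t, uu * raw$mu, units = raw$units,
                   valid = raw$valid)
}
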