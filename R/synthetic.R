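#' Sample a uniform rectangular region of the use-intensity plane
#'
#' Draws independent points with intensity `I ~ Unif(a1, a2)` and use
#' fraction `U ~ Unif(b1, b2)` — the generative model behind the simulated
#' activity scenarios used to characterise the [hq()] measure. Two canonical
#' scenarios are shipped:
#' \describe{
#'   \item{`scenario_region(1)`}{short, low-intensity use:
#'     `I` in `[0, 10]`, `U` in `[0, 0.2]` (activity `A = U I` in `[0, 2]`).}
#'   \item{`scenario_region(5)`}{long, high-intensity use:
#'     `I` in `[40, 50]`, `U` in `[0.8, 1]` (`A` in `[32, 50]`).}
#' }
#' The intermediate scenarios of that family have non-rectangular supports
#' that are not reproducible from a rectangle; approximate them by composing
#' several regions.
#'
#' @param intensity_range `c(a1, a2)`, `a1 <= a2`, non-negative.
#' @param use_range `c(b1, b2)` inside `[0, 1]`.
#' @param n Number of points.
#' @param seed Integer seed (one explicit seed per call; no global state is
#'   left behind).
#' @return data.frame with columns `I`, `U`, `A` (`A = U * I`).
#' @examples
#' pts <- sample_uniform_region(c(0, 10), c(0, 0.2), n = 1000, seed = 7)
#' hq(pts$A)
#' @export
sample_uniform_region <- function(intensity_range, use_range, n, seed) {
  stopifnot(length(intensity_range) == 2L, length(use_range) == 2L,
            intensity_range[1L] <= intensity_range[2L],
            intensity_range[1L] >= 0,
            use_range[1L] >= 0, use_range[1L] <= use_range[2L],
            use_range[2L] <= 1, n >= 1L)
  with_seed(seed, {
    I <- stats::runif(n, intensity_range[1L], intensity_range[2L])
    U <- stats::runif(n, use_range[1L], use_range[2L])
    data.frame(I = I, U = U, A = U * I)
  })
}

#' @rdname sample_uniform_region
#' @param which Scenario number, 1 or 5.
#' @return `scenario_region()` returns a list with `intensity_range` and
#'   `use_range` for the requested canonical scenario.
#' @export
scenario_region <- function(which) {
  switch(as.character(which),
    "1" = list(intensity_range = c(0, 10), use_range = c(0, 0.2)),
    "5" = list(intensity_range = c(40, 50), use_range = c(0.8, 1)),
    stop("only scenarios 1 and 5 have text-specified rectangular regions"))
}

#' Generate paired intensity series realising a named laterality pattern
#'
#' Produces `(I_r, I_l)` pairs that realise archetypal relative-use
#' behaviours exactly, for validating [rq()] and the laterality views:
#' \describe{
#'   \item{`unimanual_right` / `unimanual_left`}{the active limb draws from
#'     `Unif(range)`, the other is identically zero (`I_r * I_l = 0`).}
#'   \item{`symmetric_bimanual`}{`I_r = I_l > 0`.}
#'   \item{`scaled`}{`I_l = m * I_r` with `I_r > 0` and `m` in `[0, 1]`.}
#'   \item{`banded`}{independent uniform draws in a rectangle,
#'     `I_r ~ Unif(range)`, `I_l ~ Unif(m * range)` — a diffuse bimanual
#'     cloud rather than an exact line.}
#' }
#'
#' @param kind Pattern name.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param m Scaling factor in `[0, 1]` (scaled / banded kinds).
#' @param range Intensity range for the driving limb, default `c(1, 10)`.
#' @return data.frame with columns `I_r`, `I_l`.
#' @examples
#' p <- laterality_pattern("scaled", n = 500, seed = 3, m = 0.3)
#' rq(p$I_r, p$I_l)$rq  # exactly 0.3
#' @export
laterality_pattern <- function(kind = c("unimanual_right", "unimanual_left",
                                        "symmetric_bimanual", "scaled",
                                        "banded"),
                               n, seed, m = 0.5, range = c(1, 10)) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, range[1L] > 0, range[2L] >= range[1L])
  if (kind %in% c("scaled", "banded") && (m < 0 || m > 1)) {
    stop("m must lie in [0, 1]")
  }
  with_seed(seed, {
    base <- stats::runif(n, range[1L], range[2L])
    switch(kind,
      unimanual_right = data.frame(I_r = base, I_l = 0),
      unimanual_left = data.frame(I_r = 0, I_l = base),
      symmetric_bimanual = data.frame(I_r = base, I_l = base),
      scaled = data.frame(I_r = base, I_l = m * base),
      banded = data.frame(I_r = base,
                          I_l = stats::runif(n, m * range[1L],
                                             m * range[2L])))
  })
}

#' Build an activity schedule for the IMU simulator
#'
#' A schedule lists non-overlapping bouts per limb, each with a kind:
#' \describe{
#'   \item{`functional_move`}{voluntary movement: oscillatory accel + gyro
#'     activity at the bout's pitch; ground-truth use = 1.}
#'   \item{`functional_posture`}{a held meaningful posture: no movement, use
#'     = 1 (invisible to both shipped detectors, by design).}
#'   \item{`passive`}{the arm is moved externally (e.g. transport): same
#'     motion signature as a functional movement but ground-truth use = 0.}
#'   \item{`rest`}{nothing happens (equivalent to unscheduled time).}
#' }
#'
#' @param limb,start,duration,kind,intensity,pitch Vectors (recycled to a
#'   common length): limb, bout start (s), duration (s), kind, oscillation
#'   amplitude in m/s^2, and forearm pitch in degrees.
#' @param fs Sampling rate, Hz.
#' @param T Total epoch duration, seconds.
#' @return data.frame of class `"activity_schedule"` with attributes `fs`,
#'   `T`.
#' @export
activity_schedule <- function(limb, start, duration, kind,
                              intensity = 2, pitch = 0, fs = 50, T = 60) {
  kinds <- c("functional_move", "functional_posture", "passive", "rest")
  df <- data.frame(limb = limb, start = start, duration = duration,
                   kind = kind, intensity = intensity, pitch = pitch)
  stopifnot(all(df$limb %in% c("left", "right")),
            all(df$kind %in% kinds),
            all(df$start >= 0), all(df$duration > 0),
            all(df$start + df$duration <= T + 1e-9),
            fs > 0, T > 0)
  for (lb in unique(df$limb)) {
    b <- df[df$limb == lb, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L &&
        any(b$start[-1L] < (b$start + b$duration)[-nrow(b)] - 1e-9)) {
      stop("overlapping bouts for the ", lb, " limb")
    }
  }
  structure(df, fs = fs, T = T,
            class = c("activity_schedule", "data.frame"))
}

#' Simulate a two-limb IMU epoch with ground-truth use labels
#'
#' Synthesises wrist accelerometer and gyroscope signals for both limbs from
#' an [activity_schedule()]. Each limb at rest reads gravity at its current
#' pitch plus white noise. During `functional_move` and `passive` bouts an
#' oscillation (1.5 Hz) of the scheduled amplitude is added to the
#' accelerometer (transverse axis) and a proportional roll-rate oscillation
#' to the gyroscope; `functional_posture` bouts change only the orientation.
#' Orientation changes between bouts are written into the gyro pitch-rate
#' channel as a one-sample impulse, so an orientation filter can track the
#' true pitch exactly. Ground truth: `u = 1` exactly during
#' `functional_move` and `functional_posture` bouts.
#'
#' @param schedule An [activity_schedule()].
#' @param seed Integer seed.
#' @param noise_accel,noise_gyro White-noise standard deviations
#'   (m/s^2, deg/s).
#' @return A list with elements `left` and `right`, each a list of `epoch`
#'   (a [measurement_epoch()]), `truth` (a [use_signal()] of ground-truth
#'   use), and `pitch` (the true pitch trace, degrees).
#' @examples
#' sch <- activity_schedule("right", start = 10, duration = 10,
#'                          kind = "functional_move", fs = 50, T = 60)
#' sim <- simulate_imu_epoch(sch, seed = 1)
#' mean(sim$right$truth$u)  # about 1/6
#' @export
simulate_imu_epoch <- function(schedule, seed, noise_accel = 0.05,
                               noise_gyro = 0.5) {
  stopifnot(inherits(schedule, "activity_schedule"))
  fs <- attr(schedule, "fs")
  T <- attr(schedule, "T")
  with_seed(seed, {
    out <- lapply(c(left = "left", right = "right"), function(lb) {
      simulate_limb(schedule[schedule$limb == lb, , drop = FALSE],
                    lb, fs, T, noise_accel, noise_gyro)
    })
    out
  })
}

simulate_limb <- function(bouts, limb, fs, T, noise_accel, noise_gyro) {
  # include the endpoint sample so a full-epoch window (D = T) exists
  n <- as.integer(round(T * fs)) + 1L
  t <- (seq_len(n) - 1L) / fs
  dt <- 1 / fs
  g <- STANDARD_GRAVITY
  pitch <- numeric(n)             # true pitch trace, deg
  osc_acc <- numeric(n)           # transverse accel oscillation, m/s^2
  osc_gyro <- numeric(n)          # roll-rate oscillation, deg/s
  truth <- numeric(n)
  if (nrow(bouts) > 0L) {
    for (b in seq_len(nrow(bouts))) {
      idx <- which(t >= bouts$start[b] &
                   t < bouts$start[b] + bouts$duration[b])
      if (length(idx) == 0L) next
      pitch[idx] <- bouts$pitch[b]
      kind <- bouts$kind[b]
      if (kind %in% c("functional_move", "passive")) {
        amp <- bouts$intensity[b]
        phase <- 2 * pi * 1.5 * t[idx]
        osc_acc[idx] <- amp * sin(phase)
        # roll oscillation large enough to clear the GM movement threshold
        osc_gyro[idx] <- max(40, 25 * amp) * cos(phase)
      }
      if (kind %in% c("functional_move", "functional_posture")) {
        truth[idx] <- 1
      }
    }
  }
  prad <- pitch * pi / 180
  accel <- cbind(g * sin(prad),
                 osc_acc,
                 g * cos(prad)) +
    matrix(stats::rnorm(3L * n, sd = noise_accel), ncol = 3L)
  # gyro y carries the pitch rate; orientation steps become 1-sample impulses
  pitch_rate <- c(0, diff(pitch)) / dt
  gyro <- cbind(osc_gyro,
                pitch_rate,
                0) +
    matrix(stats::rnorm(3L * n, sd = noise_gyro), ncol = 3L)
  ep <- measurement_epoch(limb, t, accel, gyro, accel_unit = "m/s^2")
  list(epoch = ep,
       truth = use_signal(limb, t, truth),
       pitch = pitch)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
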