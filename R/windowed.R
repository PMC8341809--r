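#' Windowed average use, intensity, and activity
#'
#' The three windowed constructs summarise a limb's behaviour over the causal
#' window `(t - D, t]`:
#' \describe{
#'   \item{average use `U(t; D)`}{fraction of the window during which the limb
#'     was in use; a smoothed version of `u` taking values in `[0, 1]`.}
#'   \item{average intensity `I(t; D)`}{mean instantaneous intensity over the
#'     in-use portion of the window, i.e. the ratio of the window integrals of
#'     `mu` and `u`; defined as exactly 0 when the limb was never in use in
#'     the window (the 0/0 rule).}
#'   \item{average activity `A(t; D)`}{the product `U * I`, identically the
#'     plain window mean of `mu`; it jointly captures duration and
#'     strenuousness and is bounded above by `I`.}
#' }
#' Integrals are discretised with the rectangular rule on the uniform grid:
#' the window is the trailing `round(D * fs)` samples, covering the half-open
#' interval `(t - D, t]`. Outputs exist only for `t >= D` (the first window
#' ends exactly at `t = D`); earlier times are dropped, not padded.
#'
#' If either input carries a validity (wear) mask, any window containing an
#' invalid sample reports `NA` for all three quantities.
#'
#' @param u A [use_signal()].
#' @param mu An [intensity_signal()] on the same grid, gated by `u`
#'   (`mu = 0` wherever `u = 0`; see [gate_intensity()]).
#' @param D Window length in seconds; `0 < D <=` signal duration.
#' @return `windowed_activity()` returns a `"windowed_series"` object: a
#'   data.frame with columns `t`, `U`, `I`, `A` and attributes `D`, `limb`,
#'   `units`. `windowed_use()` and `windowed_intensity()` return the
#'   corresponding single-component data.frames (`t`, `U`) and (`t`, `I`).
#' @examples
#' t <- seq(0, 60, by = 1 / 50)
#' u <- use_signal("right", t, as.numeric(t <= 30))
#' mu <- intensity_signal("right", t, 10 * (t <= 30))
#' w <- windowed_activity(u, mu, D = 60)
#' w[w$t == 60, ]  # U = 0.5, I = 10, A = 5
#' @export
windowed_activity <- function(u, mu, D) {
  stopifnot(inherits(u, "use_signal"), inherits(mu, "intensity_signal"))
  if (!same_grid(u, mu)) stop("u and mu are on different grids")
  check_gating(u, mu)
  rs <- roll_sums(u, list(u$u, mu$mu), D)
  U <- rs$sums[[1L]] / rs$w
  Smu <- rs$sums[[2L]]
  I <- ifelse(rs$sums[[1L]] > 0, Smu / rs$sums[[1L]], 0)
  A <- Smu / rs$w
  if (!is.null(rs$bad)) U[rs$bad] <- I[rs$bad] <- A[rs$bad] <- NA_real_
  out <- data.frame(t = rs$t, U = U, I = I, A = A)
  structure(out, D = D, limb = u$limb, units = mu$units,
            class = c("windowed_series", "data.frame"))
}

#' @rdname windowed_activity
#' @export
windowed_use <- function(u, D) {
  stopifnot(inherits(u, "use_signal"))
  rs <- roll_sums(u, list(u$u), D)
  U <- rs$sums[[1L]] / rs$w
  if (!is.null(rs$bad)) U[rs$bad] <- NA_real_
  data.frame(t = rs$t, U = U)
}

#' @rdname windowed_activity
#' @export
windowed_intensity <- function(u, mu, D) {
  stopifnot(inherits(u, "use_signal"), inherits(mu, "intensity_signal"))
  if (!same_grid(u, mu)) stop("u and mu are on different grids")
  check_gating(u, mu)
  rs <- roll_sums(u, list(u$u, mu$mu), D)
  I <- ifelse(rs$sums[[1L]] > 0, rs$sums[[2L]] / rs$sums[[1L]], 0)
  if (!is.null(rs$bad)) I[rs$bad] <- NA_real_
  data.frame(t = rs$t, I = I)
}

check_gating <- function(u, mu) {
  if (any(mu$mu[u$u == 0] > 0)) {
    stop("mu is non-zero where u = 0; gate it first with gate_intensity()")
  }
}

# Trailing-window sums over the last w = round(D*fs) samples, reported at
# grid times t >= D. Returns the shared window size, output times, one
# rolling-sum vector per input series, and indices of windows touched by
# invalid samples.
roll_sums <- function(sig, series, D) {
  n <- length(sig$t)
  if (n < 2L) stop("signal too short for windowing")
  fs <- sig$fs
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    stop("window length D must be a positive scalar")
  }
  w <- as.integer(round(D * fs))
  if (w < 1L) stop("window length D is shorter than one sample")
  if (w + 1L > n) stop("window length D exceeds the signal duration")
  idx <- seq.int(w + 1L, n)
  sums <- lapply(series, function(x) {
    cs <- c(0, cumsum(x))
    cs[idx + 1L] - cs[idx - w + 1L]
  })
  bad <- NULL
  valid <- sig$valid
  if (!is.null(valid)) {
    cs <- c(0, cumsum(!valid))
    nbad <- cs[idx + 1L] - cs[idx - w + 1L]
    if (any(nbad > 0)) bad <- which(nbad > 0)
  }
  list(w = w, t = sig$t[idx], sums = sums, bad = bad)
}

#' @export
print.windowed_series <- function(x, ...) {
  cat(sprintf("<windowed_series> %s limb, D = %g s, %d windows, units: %s\n",
              attr(x, "limb"), attr(x, "D"), nrow(x), attr(x, "units")))
  ok <- stats::complete.cases(x)
  if (any(ok)) {
    cat(sprintf("  U in [%.3g, %.3g], I in [%.3g, %.3g], A in [%.3g, %.3g]\n",
                min(x$U[ok]), max(x$U[ok]), min(x$I[ok]), max(x$I[ok]),
                min(x$A[ok]), max(x$A[ok])))
  }
  if (!all(ok)) cat(sprintf("  %d windows missing (sensor not worn)\n", sum(!ok)))
  invisible(x)
}
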