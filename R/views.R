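#' Use vs Intensity (UI) scatter geometry
#'
#' Builds the point set of the UI plot: average use `U(t)` against average
#' intensity `I(t)`, for all windows with `U != 0` (the x axis is by
#' definition not part of the plot). When both limbs are supplied the right
#' limb occupies the first quadrant and the left limb is mirrored into the
#' second quadrant by negating its intensity. Constant-activity iso-lines
#' `U * I = c` can be generated for a grid of `c` values.
#'
#' @param right,left `"windowed_series"` objects from [windowed_activity()]
#'   (either may be `NULL`).
#' @param iso_c Numeric vector of activity levels for iso-lines (optional).
#' @param n_iso Points per iso-line polyline.
#' @return A list of class `"plane_points"` with `view = "UI"`, a data.frame
#'   `points` (`x`, `y`, `limb`), and (if requested) a data.frame `curves`
#'   (`c`, `x`, `y`) tracing each iso-line in the first quadrant.
#' @export
ui_points <- function(right = NULL, left = NULL, iso_c = NULL, n_iso = 200L) {
  pts <- list()
  if (!is.null(right)) {
    stopifnot(inherits(right, "windowed_series"))
    ok <- !is.na(right$U) & right$U > 0
    pts$right <- data.frame(x = right$I[ok], y = right$U[ok],
                            limb = rep("right", sum(ok)))
  }
  if (!is.null(left)) {
    stopifnot(inherits(left, "windowed_series"))
    ok <- !is.na(left$U) & left$U > 0
    pts$left <- data.frame(x = -left$I[ok], y = left$U[ok],
                           limb = rep("left", sum(ok)))
  }
  if (length(pts) == 0L) stop("supply at least one windowed series")
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  if (nrow(points) == 0L) {
    warning("all windows have U = 0; empty UI view")
  }
  curves <- NULL
  if (!is.null(iso_c)) {
    stopifnot(all(iso_c > 0))
    xmax <- max(abs(points$x), iso_c, 1)
    curves <- do.call(rbind, lapply(iso_c, function(cc) {
      x <- exp(seq(log(cc), log(xmax * 1.05), length.out = n_iso))
      data.frame(c = cc, x = x, y = pmin(1, cc / x))
    }))
  }
  structure(list(view = "UI", points = points, curves = curves),
            class = "plane_points")
}

#' Bilateral-Magnitude vs Magnitude-Ratio (BMMR) geometry
#'
#' The classic laterality heat-map geometry: each retained sample maps to
#' `x = log(I_r / I_l)` (magnitude ratio, natural log by default) and
#' `y = I_l + I_r` (bilateral magnitude). Pure unilateral samples have an
#' infinite log-ratio; with clamping on (the plotting convention) they map to
#' exactly `x = +/- bound`.
#'
#' @param I_r,I_l Paired non-negative intensities; both-zero pairs are
#'   removed by [laterality_mask()].
#' @param clamp Clamp the magnitude ratio into `[-bound, bound]`? Default
#'   `TRUE` (the plotting convention); `FALSE` keeps infinities.
#' @param bound Clamp bound, default 7.
#' @param base Logarithm base; default `exp(1)`.
#' @return `"plane_points"` with `view = "BMMR"`; `points` has columns `x`,
#'   `y`, `clamped` (logical).
#' @examples
#' bmmr_points(c(5, 3, 0), c(5, 0, 3))$points
#' @export
bmmr_points <- function(I_r, I_l, clamp = TRUE, bound = 7, base = exp(1)) {
  stopifnot(bound > 0)
  m <- laterality_mask(I_r, I_l)
  x <- log(m$I_r / m$I_l, base = base)  # +/-Inf for pure unilateral samples
  clamped <- rep(FALSE, length(x))
  if (clamp) {
    clamped <- is.infinite(x) | abs(x) > bound
    x <- pmin(bound, pmax(-bound, x))
  }
  structure(list(view = "BMMR",
                 points = data.frame(x = x, y = m$I_r + m$I_l,
                                     clamped = clamped),
                 clamp = clamp, bound = bound, base = base,
                 mask_fraction = m$retained_fraction),
            class = "plane_points")
}

#' Left-Intensity vs Right-Intensity (LIRI) geometry
#'
#' The identity embedding of the paired intensities: `x = I_r`, `y = I_l`.
#' The diagonal `y = x` marks symmetric use; pure right and left unilateral
#' use fall on the x and y axes respectively.
#'
#' @inheritParams bmmr_points
#' @return `"plane_points"` with `view = "LIRI"`.
#' @export
liri_points <- function(I_r, I_l) {
  m <- laterality_mask(I_r, I_l)
  structure(list(view = "LIRI",
                 points = data.frame(x = m$I_r, y = m$I_l),
                 mask_fraction = m$retained_fraction),
            class = "plane_points")
}

#' Intensity-Sum vs Intensity-Difference (ISID) geometry
#'
#' The LIRI plane rotated 45 degrees counter-clockwise (and scaled by
#' sqrt(2)): `x = I_r - I_l`, `y = I_r + I_l`. Since intensities are
#' non-negative, every point satisfies `y >= |x|`; symmetric use lies on
#' `x = 0`, pure right/left unilateral use on the `y = x` / `y = -x` lines.
#'
#' @inheritParams bmmr_points
#' @return `"plane_points"` with `view = "ISID"`.
#' @export
isid_points <- function(I_r, I_l) {
  m <- laterality_mask(I_r, I_l)
  structure(list(view = "ISID",
                 points = data.frame(x = m$I_r - m$I_l, y = m$I_r + m$I_l),
                 mask_fraction = m$retained_fraction),
            class = "plane_points")
}

#' @export
print.plane_points <- function(x, ...) {
  cat(sprintf("<plane_points> view %s, %d points\n", x$view, nrow(x$points)))
  invisible(x)
}

#' Reference curve families L1-L4 for the laterality views
#'
#' Four families of curves in the `(I_r, I_l)` plane organise the geometry of
#' every laterality view:
#' \describe{
#'   \item{L1}{constant left intensity, `I_l = c`}
#'   \item{L2}{constant right intensity, `I_r = c`}
#'   \item{L3}{constant intensity ratio, `I_l = c I_r`}
#'   \item{L4}{constant intensity product, `I_l I_r = c`}
#' }
#' Each curve is sampled as a polyline in `(I_r, I_l)` space and pushed
#' through the requested view transform (LIRI, ISID, or BMMR).
#'
#' @param family `"L1"`, `"L2"`, `"L3"` or `"L4"`.
#' @param c_values Non-negative constants, one curve per value.
#' @param view Target view: `"LIRI"`, `"ISID"` or `"BMMR"`.
#' @param range Range of the free coordinate (`I_r` for L1/L3/L4, `I_l` for
#'   L2), default `c(0, 50)`; for L4 and BMMR the lower end is bumped off
#'   zero.
#' @param n Points per polyline.
#' @param ... Passed to [bmmr_points()] (`clamp`, `bound`, `base`).
#' @return A list of class `"curve_family"`: data.frame `curves` with columns
#'   `family`, `c`, `x`, `y`, `I_r`, `I_l`.
#' @examples
#' reference_curves("L3", 1, "LIRI")$curves[1:3, ]  # the y = x diagonal
#' @export
reference_curves <- function(family = c("L1", "L2", "L3", "L4"),
                             c_values, view = c("LIRI", "ISID", "BMMR"),
                             range = c(0, 50), n = 100L, ...) {
  family <- match.arg(family)
  view <- match.arg(view)
  stopifnot(all(c_values >= 0), range[2L] > range[1L], range[1L] >= 0)
  lo <- range[1L]
  if (family == "L4" || view == "BMMR") lo <- max(lo, 1e-3 * range[2L])
  curves <- do.call(rbind, lapply(c_values, function(cc) {
    s <- seq(lo, range[2L], length.out = n)
    irl <- switch(family,
      L1 = data.frame(I_r = s, I_l = cc),
      L2 = data.frame(I_r = cc, I_l = s),
      L3 = data.frame(I_r = s, I_l = cc * s),
      L4 = {
        if (cc == 0) stop("L4 with c = 0 degenerates to the axes")
        s <- exp(seq(log(lo), log(range[2L]), length.out = n))
        data.frame(I_r = s, I_l = cc / s)
      })
    xy <- view_transform(irl$I_r, irl$I_l, view, ...)
    data.frame(family = family, c = cc, x = xy$x, y = xy$y,
               I_r = irl$I_r, I_l = irl$I_l)
  }))
  structure(list(family = family, view = view, curves = curves),
            class = "curve_family")
}

# Push (I_r, I_l) coordinates through a laterality view transform.
view_transform <- function(I_r, I_l, view, clamp = TRUE, bound = 7,
                           base = exp(1)) {
  switch(view,
    LIRI = list(x = I_r, y = I_l),
    ISID = list(x = I_r - I_l, y = I_r + I_l),
    BMMR = {
      x <- log(I_r / I_l, base = base)
      if (clamp) x <- pmin(bound, pmax(-bound, x))
      list(x = x, y = I_r + I_l)
    },
    stop("unsupported view: ", view))
}

#' Low/medium/high intensity fractions per window
#'
#' For each causal window `(t - D, t]`, the fractions of *in-use* samples
#' whose instantaneous intensity falls in the low (`mu <= low_hi`), medium
#' (`low_hi < mu <= med_hi`) and high (`mu > med_hi`) bands. Fractions sum to
#' 1 whenever the window contains any use, and are all zero otherwise. This
#' is the stacked-band temporal profile companion to average intensity.
#'
#' @inheritParams windowed_activity
#' @param thresholds Increasing pair `c(low_hi, med_hi)` in the units of `mu`.
#' @return data.frame with columns `t`, `low`, `medium`, `high`.
#' @export
intensity_band_fractions <- function(u, mu, D, thresholds) {
  stopifnot(inherits(u, "use_signal"), inherits(mu, "intensity_signal"))
  if (!same_grid(u, mu)) stop("u and mu are on different grids")
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    stop("thresholds must be an increasing pair")
  }
  in_use <- u$u == 1
  lo <- as.numeric(in_use & mu$mu <= thresholds[1L])
  mid <- as.numeric(in_use & mu$mu > thresholds[1L] & mu$mu <= thresholds[2L])
  hi <- as.numeric(in_use & mu$mu > thresholds[2L])
  rs <- roll_sums(u, list(u$u, lo, mid, hi), D)
  n_use <- rs$sums[[1L]]
  denom <- ifelse(n_use > 0, n_use, 1)
  out <- data.frame(t = rs$t,
                    low = rs$sums[[2L]] / denom,
                    medium = rs$sums[[3L]] / denom,
                    high = rs$sums[[4L]] / denom)
  if (!is.null(rs$bad)) out[rs$bad, c("low", "medium", "high")] <- NA_real_
  out
}

#' Functional workspace density
#'
#' A histogram estimate of the probability density over the space traversed
#' by the limb during functional use: positions are gated by the use signal
#' (or its complement for the non-functional workspace), binned on a regular
#' grid, and normalised so the density integrates to one over the grid. The
#' occupied-volume summary is the fraction of cells whose density exceeds a
#' quantile of the positive cell densities.
#'
#' @param positions n x d numeric matrix of positions (d = 2 or 3), one row
#'   per sample of `u`.
#' @param u A [use_signal()] on the same sample grid.
#' @param nbins Bins per dimension (scalar or length-d).
#' @param functional `TRUE` (default) gates by `u`; `FALSE` gates by `1 - u`
#'   (non-functional workspace).
#' @param t_end,D Optional: restrict to the causal window `(t_end - D, t_end]`
#'   before gating.
#' @param volume_quantile Quantile of positive cell densities defining the
#'   occupied-volume summary (default 0.5).
#' @return A list of class `"workspace_density"`: `density` (d-dimensional
#'   array, integrates to 1), `breaks` (list of bin edges), `cell_volume`,
#'   `n_points`, `volume_fraction`.
#' @export
workspace_density <- function(positions, u, nbins = 20L, functional = TRUE,
                              t_end = NULL, D = NULL,
                              volume_quantile = 0.5) {
  stopifnot(inherits(u, "use_signal"))
  positions <- as.matrix(positions)
  d <- ncol(positions)
  if (!d %in% c(2L, 3L)) stop("positions must be 2- or 3-dimensional")
  if (nrow(positions) != length(u$t)) stop("positions and u grid mismatch")
  keep <- if (functional) u$u == 1 else u$u == 0
  if (!is.null(t_end)) {
    if (is.null(D)) stop("D required with t_end")
    keep <- keep & u$t > t_end - D & u$t <= t_end
  }
  pts <- positions[keep, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no gated samples: empty workspace")
  nbins <- rep_len(as.integer(nbins), d)
  breaks <- lapply(seq_len(d), function(j) {
    rng <- range(pts[, j])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1L], rng[2L], length.out = nbins[j] + 1L)
  })
  idx <- vapply(seq_len(d), function(j) {
    pmin(nbins[j], pmax(1L, findInterval(pts[, j], breaks[[j]],
                                         rightmost.closed = TRUE)))
  }, integer(nrow(pts)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  counts <- array(0, dim = nbins)
  flat <- as.integer(idx[, 1L])
  mult <- 1L
  for (j in seq_len(d - 1L)) {
    mult <- mult * nbins[j]
    flat <- flat + (as.integer(idx[, j + 1L]) - 1L) * mult
  }
  tab <- tabulate(flat, nbins = prod(nbins))
  counts[] <- tab
  cell_volume <- prod(vapply(breaks, function(b) b[2L] - b[1L], numeric(1)))
  dens <- counts / (nrow(pts) * cell_volume)
  pos <- dens[dens > 0]
  thr <- stats::quantile(pos, volume_quantile)
  structure(list(density = dens, breaks = breaks, cell_volume = cell_volume,
                 n_points = nrow(pts),
                 volume_fraction = mean(dens > thr)),
            class = "workspace_density")
}
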