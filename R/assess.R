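#' Assess two-limb upper-limb functioning from wrist IMU epochs
#'
#' The central analysis: from a pair of wrist-sensor measurement epochs it
#' (1) computes activity counts as the instantaneous intensity measure,
#' (2) detects upper-limb use with the chosen detector (gross-movement score
#' by default, or thresholded activity counts), (3) gates the intensity by
#' use, (4) computes the causal windowed averages U, I, A for each limb, and
#' (5) summarises the epoch with Hq per limb and the bilateral Rq with
#' preferred-limb sign.
#'
#' @param left,right [measurement_epoch()] objects for the two limbs.
#' @param detector `"gm"` (gross movement; requires gyro) or `"ac"`
#'   (thresholded activity counts).
#' @param ac [ac_params()] for the intensity measure.
#' @param gm [gm_params()] for the GM detector.
#' @param use_threshold Count threshold for the `"ac"` detector.
#' @param D Averaging window in seconds (default 60).
#' @param q Percentile order for Hq and Rq (default 90).
#' @return An object of class `"ul_assessment"`: list with `limbs` (per limb:
#'   `counts`, `use`, `mu`, `windowed`), `summary` (`q`, `Hq_left`,
#'   `Hq_right`, `rq` — an [rq()] result), `modes` (per-sample
#'   [limb_use_modes()] factor, when the raw grids match), and `params`.
#'   Methods: `print`, `summary`, `coef`, `plot`.
#' @seealso [run_pipeline()] for the file/config-driven interface.
#' @export
ul_assess <- function(left, right, detector = c("gm", "ac"),
                      ac = ac_params(), gm = gm_params(),
                      use_threshold = 2, D = 60, q = 90) {
  stopifnot(inherits(left, "measurement_epoch"),
            inherits(right, "measurement_epoch"))
  if (left$limb != "left" || right$limb != "right") {
    stop("epochs must be labelled left and right")
  }
  detector <- match.arg(detector)
  limbs <- lapply(list(left = left, right = right), function(ep) {
    counts <- activity_counts(ep, ac)
    u_raw <- switch(detector,
      gm = gm_use(ep, gm),
      ac = threshold_use(counts, use_threshold))
    u <- use_on_grid(u_raw, counts)
    mu <- gate_intensity(u, counts)
    W <- windowed_activity(u, mu, D)
    list(counts = counts, use = u_raw, mu = mu, windowed = W)
  })
  Wl <- limbs$left$windowed
  Wr <- limbs$right$windowed
  tt <- intersect(Wl$t, Wr$t)
  Il <- Wl$I[match(tt, Wl$t)]
  Ir <- Wr$I[match(tt, Wr$t)]
  rq_res <- rq(Ir, Il, q = q)
  modes <- NULL
  if (same_grid(limbs$left$use, limbs$right$use)) {
    modes <- limb_use_modes(limbs$left$use, limbs$right$use)
  }
  structure(
    list(limbs = limbs,
         summary = list(q = q,
                        Hq_left = hq(Wl$A, q),
                        Hq_right = hq(Wr$A, q),
                        rq = rq_res),
         modes = modes,
         params = list(detector = detector, ac = ac, gm = gm,
                       use_threshold = use_threshold, D = D, q = q),
         call = match.call()),
    class = "ul_assessment")
}

# Resample a use signal onto the (coarser) grid of an intensity signal: an
# aggregation epoch counts as in use when at least half its samples are.
use_on_grid <- function(u, counts) {
  if (same_grid(u, counts)) return(u)
  dt <- if (length(counts$t) > 1L) diff(counts$t)[1L] else 1 / counts$fs
  bins <- findInterval(u$t + 1e-9, counts$t)
  ok <- bins >= 1L & u$t < counts$t[length(counts$t)] + dt
  frac <- tapply(u$u[ok], bins[ok], mean)
  uu <- numeric(length(counts$t))
  uu[as.integer(names(frac))] <- as.numeric(frac >= 0.5)
  use_signal(u$limb, counts$t, uu, valid = counts$valid)
}

#' @export
print.ul_assessment <- function(x, ...) {
  s <- x$summary
  cat("Upper-limb assessment\n")
  cat(sprintf("  detector: %s, D = %g s, q = %g\n",
              x$params$detector, x$params$D, s$q))
  cat(sprintf("  Hq: left %.3f, right %.3f [%s]\n",
              s$Hq_left, s$Hq_right, attr(x$limbs$left$windowed, "units")))
  side <- c("left", "none", "right")[s$rq$preferred + 2L]
  cat(sprintf("  Rq: %.3f (preferred limb: %s)\n", s$rq$rq, side))
  invisible(x)
}

#' @export
summary.ul_assessment <- function(object, ...) {
  s <- object$summary
  out <- list(coefficients = coef.ul_assessment(object),
              rq = s$rq, params = object$params)
  if (!is.null(object$modes)) {
    out$mode_fractions <- prop.table(table(object$modes))
  }
  class(out) <- "summary.ul_assessment"
  out
}

#' @export
print.summary.ul_assessment <- function(x, ...) {
  cat("Upper-limb assessment summary\n\nMeasures:\n")
  print(round(x$coefficients, 4))
  cat("\n")
  print(x$rq)
  if (!is.null(x$mode_fractions)) {
    cat("\nUse-mode fractions:\n")
    print(round(x$mode_fractions, 4))
  }
  invisible(x)
}

#' @export
coef.ul_assessment <- function(object, ...) {
  s <- object$summary
  c(Hq_left = s$Hq_left, Hq_right = s$Hq_right,
    Rq = s$rq$rq, preferred = s$rq$preferred)
}

#' Plot an upper-limb assessment
#'
#' @param x An [ul_assess()] result.
#' @param type `"ui"` (use vs intensity with activity iso-lines), `"liri"`,
#'   `"isid"`, `"bmmr"` (laterality scatters), or `"profile"` (windowed U and
#'   I over time).
#' @param iso_c Activity iso-line levels for the UI plot.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ul_assessment <- function(x, type = c("ui", "liri", "isid", "bmmr",
                                           "profile"),
                               iso_c = c(2, 20), ...) {
  type <- match.arg(type)
  Wl <- x$limbs$left$windowed
  Wr <- x$limbs$right$windowed
  tt <- intersect(Wl$t, Wr$t)
  Il <- Wl$I[match(tt, Wl$t)]
  Ir <- Wr$I[match(tt, Wr$t)]
  if (type == "ui") {
    v <- ui_points(right = Wr, left = Wl, iso_c = iso_c)
    plot(v$points$x, v$points$y, xlab = "average intensity I (left | right)",
         ylab = "average use U", ylim = c(0, 1),
         col = ifelse(v$points$limb == "right", "steelblue", "firebrick"),
         pch = 16, cex = 0.5, ...)
    if (!is.null(v$curves)) {
      for (cc in unique(v$curves$c)) {
        cv <- v$curves[v$curves$c == cc, ]
        graphics::lines(cv$x, cv$y, col = "rosybrown1")
        graphics::lines(-cv$x, cv$y, col = "rosybrown1")
      }
    }
    graphics::abline(v = 0, col = "grey")
  } else if (type == "profile") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    plot(Wl$t, Wl$U, type = "l", col = "firebrick", ylim = c(0, 1),
         xlab = "t [s]", ylab = "U", ...)
    graphics::lines(Wr$t, Wr$U, col = "steelblue")
    plot(Wl$t, Wl$I, type = "l", col = "firebrick",
         xlab = "t [s]", ylab = "I", ...)
    graphics::lines(Wr$t, Wr$I, col = "steelblue")
  } else {
    v <- switch(type,
      liri = liri_points(Ir, Il),
      isid = isid_points(Ir, Il),
      bmmr = bmmr_points(Ir, Il))
    plot(v$points$x, v$points$y, pch = 16, cex = 0.5,
         xlab = switch(type, liri = "I_r", isid = "I_r - I_l",
                       bmmr = "log(I_r / I_l)"),
         ylab = switch(type, liri = "I_l", isid = "I_r + I_l",
                       bmmr = "I_l + I_r"), ...)
    if (type == "liri") graphics::abline(0, 1, col = "red")
    if (type != "liri") graphics::abline(v = 0, col = "grey")
  }
  invisible(x)
}
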