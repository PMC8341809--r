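test_that("the UI view drops U = 0 windows and mirrors the left limb", {
  u <- make_use(c(rep(0, 100), rep(1, 200), rep(0, 201)))
  mu <- make_mu(u$u * 10)
  Wr <- windowed_activity(u, mu, D = 1)
  ul <- make_use(rep(1, 501), limb = "left")
  Wl <- windowed_activity(ul, make_mu(rep(4, 501), limb = "left"), D = 1)
  v <- ui_points(right = Wr, left = Wl, iso_c = c(2, 5))
  expect_true(all(v$points$y > 0))
  expect_true(all(v$points$x[v$points$limb == "left"] < 0))
  expect_true(all(v$points$x[v$points$limb == "right"] >= 0))
  # iso-lines trace U * I = c (until the U = 1 cap)
  for (cc in unique(v$curves$c)) {
    cv <- v$curves[v$curves$c == cc & v$curves$y < 1, ]
    expect_lt(max(abs(cv$x * cv$y - cc)), 1e-9)
  }
  # the point (I = 10, U = 0.5) lies on the c = 5 iso-line
  expect_equal(10 * 0.5, 5)
  expect_warning(ui_points(right = windowed_activity(
    make_use(rep(0, 200)), make_mu(rep(0, 200)), D = 1)), "empty UI view")
})

test_that("BMMR maps ratios to log space and clamps pure unilateral use", {
  v <- bmmr_points(c(5, 3, 0), c(5, 0, 3))
  expect_equal(v$points$x, c(0, 7, -7))
  expect_equal(v$points$y, c(10, 3, 3))
  expect_equal(v$points$clamped, c(FALSE, TRUE, TRUE))
  raw <- bmmr_points(c(3, 0), c(0, 3), clamp = FALSE)
  expect_equal(raw$points$x, c(Inf, -Inf))
  # exchangeable limbs give a ratio distribution centred on 0
  set.seed(10)
  x <- rexp(4000) + 0.1; y <- rexp(4000) + 0.1
  mr <- bmmr_points(x, y)$points$x
  expect_lt(abs(mean(mr)), 4 * sd(mr) / sqrt(length(mr)))
})

test_that("a rectangle boundary stays a simple closed curve in BMMR space", {
  seg_intersects <- function(p1, p2, p3, p4) {
    o <- function(a, b, c) {
      sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    }
    o(p1, p2, p3) != o(p1, p2, p4) && o(p3, p4, p1) != o(p3, p4, p2)
  }
  m <- 30
  s <- seq(5, 500, length.out = m)
  keep <- seq_len(m - 1)  # drop each side's last point: corners appear once
  bnd <- rbind(cbind(s[keep], 5), cbind(500, s[keep]),
               cbind(rev(s)[keep], 500), cbind(5, rev(s)[keep]))
  v <- bmmr_points(bnd[, 1], bnd[, 2], clamp = FALSE)
  xy <- cbind(v$points$x, v$points$y)
  expect_true(all(is.finite(xy)))
  n <- nrow(xy)
  closed <- rbind(xy, xy[1, ])
  crossings <- 0L
  for (i in 1:n) {
    for (j in 1:n) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (seg_intersects(closed[i, ], closed[i + 1, ],
                         closed[j, ], closed[j + 1, ])) {
        crossings <- crossings + 1L
      }
    }
  }
  expect_equal(crossings, 0L)
})

test_that("LIRI is the identity embedding and ISID its scaled 45-degree rotation", {
  li <- liri_points(c(2, 3, 0), c(2, 0, 4))
  expect_equal(li$points$x, c(2, 3, 0))
  expect_equal(li$points$y, c(2, 0, 4))
  is1 <- isid_points(3, 3)
  expect_equal(c(is1$points$x, is1$points$y), c(0, 6))
  is2 <- isid_points(3, 0)
  expect_equal(c(is2$points$x, is2$points$y), c(3, 3))  # on the y = x edge
  set.seed(12)
  Ir <- rexp(300); Il <- rexp(300)
  keep <- Ir + Il > 0
  is_all <- isid_points(Ir, Il)$points
  # rotation-matrix oracle: rotate (I_r, I_l) by 45 deg CCW, scale by sqrt(2)
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- sqrt(2) * t(R %*% rbind(Ir[keep], Il[keep]))
  expect_equal(is_all$x, rot[, 1], tolerance = 1e-12)
  expect_equal(is_all$y, rot[, 2], tolerance = 1e-12)
  expect_true(all(is_all$y >= abs(is_all$x) - 1e-12))
})

test_that("reference curves satisfy their defining equations in every view", {
  d <- reference_curves("L3", 1, "LIRI")$curves
  expect_equal(d$x, d$y)  # the diagonal
  h <- reference_curves("L1", 3, "LIRI")$curves
  expect_true(all(h$y == 3))  # horizontal line
  for (fam in c("L1", "L2", "L3", "L4")) {
    for (view in c("LIRI", "ISID", "BMMR")) {
      cv <- reference_curves(fam, c(0.5, 4), view, range = c(0, 50))$curves
      resid <- switch(fam,
        L1 = cv$I_l - cv$c, L2 = cv$I_r - cv$c,
        L3 = cv$I_l - cv$c * cv$I_r, L4 = cv$I_l * cv$I_r - cv$c)
      expect_lt(max(abs(resid)), 1e-9)
    }
  }
  l4 <- reference_curves("L4", 4, "LIRI")$curves
  expect_lt(min(abs(l4$I_r - 2) + abs(l4$I_l - 2)), 0.3)  # passes near (2, 2)
  expect_error(reference_curves("L4", 0, "LIRI"), "degenerates")
})

test_that("intensity band fractions count in-use samples per band", {
  u <- make_use(rep(1, 301))
  mu_low <- make_mu(rep(0.5, 301))
  b <- intensity_band_fractions(u, mu_low, D = 1, thresholds = c(1, 2))
  expect_true(all(b$low == 1 & b$medium == 0 & b$high == 0))
  u0 <- make_use(rep(0, 301))
  b0 <- intensity_band_fractions(u0, make_mu(rep(0, 301)), D = 1, c(1, 2))
  expect_true(all(b0$low == 0 & b0$medium == 0 & b0$high == 0))
  # uniform intensity across bands: about a third each, summing to one
  set.seed(13)
  u <- make_use(rep(1, 5001))
  mu <- make_mu(runif(5001, 0, 3))
  b <- intensity_band_fractions(u, mu, D = 10, thresholds = c(1, 2))
  expect_true(all(abs(b$low + b$medium + b$high - 1) < 1e-9))
  expect_lt(max(abs(colMeans(b[, c("low", "medium", "high")]) - 1 / 3)), 0.05)
  # counting oracle on one window
  k <- 1000
  w <- 500
  idx <- (k - w + 1):k
  expect_equal(b$low[b$t == u$t[k]],
               mean(mu$mu[idx] <= 1))
  expect_error(intensity_band_fractions(u, mu, 1, c(2, 1)), "increasing")
})

test_that("workspace density is a normalised histogram of gated positions", {
  n <- 400
  u <- make_use(rep(1, n))
  one_pt <- matrix(rep(c(0.3, 0.7), each = n), ncol = 2)
  wd <- workspace_density(one_pt, u, nbins = 10)
  expect_equal(sum(wd$density > 0), 1L)  # unit mass in a single cell
  expect_equal(sum(wd$density) * wd$cell_volume, 1)
  set.seed(14)
  pos <- cbind(runif(n), runif(n), runif(n))
  uu <- make_use(rbinom(n, 1, 0.7))
  wd3 <- workspace_density(pos, uu, nbins = 4)
  expect_equal(sum(wd3$density) * wd3$cell_volume, 1, tolerance = 1e-12)
  expect_equal(wd3$n_points, sum(uu$u))
  # non-functional variant gates on the complement
  wd_nf <- workspace_density(pos, uu, nbins = 4, functional = FALSE)
  expect_equal(wd_nf$n_points, sum(uu$u == 0))
  expect_error(workspace_density(pos, make_use(rep(0, n)), nbins = 4),
               "empty workspace")
})
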