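# Independent analytic oracle: p-th quantile of X*Y for independent
# X ~ Unif(a1, a2), Y ~ Unif(b1, b2), by numerically inverting the exact CDF
# F(z) = E_Y[ P(X <= z / Y) ].
product_uniform_quantile <- function(a, b, p) {
  cdf <- function(z) {
    stats::integrate(function(y) {
      pmin(1, pmax(0, (z / y - a[1]) / (a[2] - a[1])))
    }, b[1], b[2], rel.tol = 1e-10)$value / (b[2] - b[1])
  }
  stats::uniroot(function(z) cdf(z) - p,
                 interval = c(a[1] * b[1], a[2] * b[2]),
                 tol = 1e-10)$root
}

test_that("nearest-rank percentile matches a brute-force sort oracle", {
  expect_equal(empirical_percentile(5, 90), 5)
  expect_equal(empirical_percentile(1:100, 90), 90)
  set.seed(3)
  for (n in 1:12) {
    x <- round(rnorm(n), 3)
    for (q in seq(1, 99, by = 1)) {
      expect_identical(empirical_percentile(x, q),
                       sort(x)[ceiling(q / 100 * n)])
    }
  }
  expect_error(empirical_percentile(numeric(0), 90), "non-empty")
  expect_error(empirical_percentile(1:5, 0), "between 0 and 100")
  expect_error(empirical_percentile(1:5, 100), "between 0 and 100")
})

test_that("the inverse-CDF estimator commutes with monotone transforms", {
  set.seed(4)
  for (i in 1:20) {
    x <- rexp(sample(5:200, 1))
    q <- sample(5:95, 1)
    expect_identical(empirical_percentile(x^2, q),
                     empirical_percentile(x, q)^2)
    expect_identical(empirical_percentile(3 * x + 1, q),
                     3 * empirical_percentile(x, q) + 1)
  }
  # the interpolating estimator matches the standard type-7 quantile
  x <- rexp(50)
  expect_equal(empirical_percentile(x, 37, method = "linear"),
               unname(quantile(x, 0.37, type = 7)))
})

test_that("Hq is homogeneous, permutation invariant, and exact on constants", {
  expect_equal(hq(rep(4.2, 100)), 4.2)
  set.seed(5)
  A <- rexp(500)
  expect_identical(hq(3 * A), 3 * hq(A))
  expect_identical(hq(sample(A)), hq(A))
  expect_equal(hq(c(A, NA)), hq(A))  # missing windows are dropped
  expect_error(hq(numeric(0)), "no activity")
  expect_error(hq(c(-1, 2)), "non-negative")
})

test_that("Monte-Carlo Hq agrees with the analytic product-of-uniforms CDF", {
  cases <- list(list(a = c(0, 10), b = c(0, 0.2)),
                list(a = c(40, 50), b = c(0.8, 1)))
  for (cs in cases) {
    n <- 2e5
    pts <- sample_uniform_region(cs$a, cs$b, n = n, seed = 20)
    h <- hq(pts$A, q = 90)
    truth <- product_uniform_quantile(cs$a, cs$b, 0.9)
    # 3 standard errors of the sample quantile, density via finite difference
    eps <- 1e-3 * truth
    dens <- (product_uniform_quantile(cs$a, cs$b, 0.9 + 1e-4) -
             product_uniform_quantile(cs$a, cs$b, 0.9 - 1e-4))
    dens <- 2e-4 / dens
    se <- sqrt(0.9 * 0.1 / n) / dens
    expect_lt(abs(h - truth), 3 * se + eps)
  }
})

test_that("Rq maps unimanual, symmetric, and scaled patterns exactly", {
  set.seed(6)
  Ir <- runif(1000, 1, 10)
  expect_identical(rq(Ir, Ir)$rq, 1)
  expect_identical(rq(Ir, 0 * Ir)$rq, 0)
  for (m in seq(0.1, 1, by = 0.1)) {
    expect_equal(rq(Ir, m * Ir)$rq, m, tolerance = 1e-12)
    expect_equal(rq(Ir, Ir / m)$rq, m, tolerance = 1e-12)  # mirror identity
  }
})

test_that("Rq is symmetric, scale invariant, clipped, and signs the preferred limb", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    Ir <- rexp(n); Il <- rexp(n) * runif(1, 0.2, 1)
    a <- rq(Ir, Il); b <- rq(Il, Ir)
    expect_identical(a$rq, b$rq)                 # limb symmetry
    expect_identical(a$preferred, -b$preferred)  # sign flips
    cc <- runif(1, 0.1, 100)
    expect_equal(rq(cc * Ir, cc * Il)$rq, a$rq, tolerance = 1e-12)
    expect_true(a$rq >= 0 && a$rq <= 1)
    expect_lte(a$clipped, 0.05)                  # estimator stays well-behaved
  }
  expect_identical(rq(runif(100, 1, 2), runif(100, 3, 4))$preferred, -1L)
  # both marginal percentiles zero at a low q on sparse alternating data
  Ir <- rep(c(1, 0), 5); Il <- rep(c(0, 1), 5)
  expect_error(rq(Ir, Il, q = 40), "raise q")
})

test_that("the laterality mask keeps exactly the samples with any use", {
  m <- laterality_mask(c(0, 1, 2), c(0, 0, 3))
  expect_equal(m$I_r, c(1, 2))
  expect_equal(m$I_l, c(0, 3))
  expect_equal(m$retained_fraction, 2 / 3)
  expect_error(laterality_mask(c(0, 0), c(0, 0)), "zero intensity")
  set.seed(9)
  Ir <- rbinom(200, 1, 0.5) * rexp(200)
  Il <- rbinom(200, 1, 0.5) * rexp(200)
  keep <- (Ir + Il) > 0
  m <- laterality_mask(Ir, Il)
  expect_identical(m$I_r, Ir[keep])
  expect_identical(m$I_l, Il[keep])
})
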