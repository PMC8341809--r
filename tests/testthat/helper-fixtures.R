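# Shared builders for signal fixtures (all generated in code).

make_grid <- function(T = 60, fs = 50) seq(0, T, by = 1 / fs)

make_use <- function(u, fs = 50, limb = "right", valid = NULL) {
  t <- (seq_along(u) - 1) / fs
  use_signal(limb, t, u, valid = valid)
}

make_mu <- function(mu, fs = 50, limb = "right", valid = NULL) {
  t <- (seq_along(mu) - 1) / fs
  intensity_signal(limb, t, mu, valid = valid)
}

# Random gated (u, mu) pair of length n.
random_pair <- function(n, fs = 50, p_use = 0.5, limb = "right") {
  u <- rbinom(n, 1, p_use)
  mu <- u * rexp(n, rate = 0.2)
  list(u = make_use(u, fs, limb), mu = make_mu(mu, fs, limb))
}

# Stationary epoch: gravity only (given pitch), optional gyro.
still_epoch <- function(T = 10, fs = 50, pitch = 0, limb = "right",
                        gyro = TRUE) {
  t <- seq(0, T - 1 / fs, by = 1 / fs)
  g <- 9.80665
  p <- pitch * pi / 180
  acc <- cbind(rep(g * sin(p), length(t)), 0, rep(g * cos(p), length(t)))
  gy <- if (gyro) matrix(0, length(t), 3) else NULL
  measurement_epoch(limb, t, acc, gy)
}
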