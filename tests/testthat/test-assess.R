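make_two_limb_sim <- function(seed = 4) {
  sch <- activity_schedule(
    limb = c("right", "right", "left", "right", "left"),
    start = c(10, 60, 60, 150, 150),
    duration = c(30, 60, 60, 80, 40),
    kind = "functional_move",
    intensity = c(2, 3, 3, 2, 1), pitch = 0, fs = 50, T = 300)
  simulate_imu_epoch(sch, seed = seed)
}

test_that("the end-to-end assessment produces a coherent summary object", {
  sim <- make_two_limb_sim()
  a <- ul_assess(sim$left$epoch, sim$right$epoch, D = 60, q = 90)
  expect_s3_class(a, "ul_assessment")
  co <- coef(a)
  expect_named(co, c("Hq_left", "Hq_right", "Rq", "preferred"))
  expect_true(co["Hq_left"] >= 0 && co["Hq_right"] >= 0)
  expect_true(co["Rq"] >= 0 && co["Rq"] <= 1)
  # right limb was scheduled with more functional time than the left
  expect_gt(co["Hq_right"], co["Hq_left"])
  expect_s3_class(a$limbs$left$windowed, "windowed_series")
  expect_false(anyNA(a$limbs$left$windowed$A))
  expect_s3_class(a$modes, "factor")
  expect_output(print(a), "Upper-limb assessment")
  expect_output(print(summary(a)), "Use-mode fractions")
  # both detectors run the same chain
  a2 <- ul_assess(sim$left$epoch, sim$right$epoch, detector = "ac",
                  D = 60, q = 90)
  expect_true(coef(a2)["Rq"] >= 0 && coef(a2)["Rq"] <= 1)
  expect_error(ul_assess(sim$right$epoch, sim$right$epoch),
               "left and right")
})

test_that("plot methods draw without a display", {
  sim <- make_two_limb_sim()
  a <- ul_assess(sim$left$epoch, sim$right$epoch, D = 60)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  for (type in c("ui", "liri", "isid", "bmmr", "profile")) {
    expect_invisible(plot(a, type = type))
  }
  grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("scenario and laterality pipeline configs reproduce the measures", {
  rep1 <- run_pipeline(list(input = list(kind = "scenario", which = 1,
                                         n = 200000L), seed = 11))
  expect_lt(abs(rep1$result$Hq - 1.18), 0.02)
  rep5 <- run_pipeline(list(input = list(kind = "scenario", which = 5,
                                         n = 200000L), seed = 11))
  expect_lt(abs(rep5$result$Hq - 45.64), 0.25)
  sym <- run_pipeline(list(input = list(kind = "laterality",
                                        pattern = "symmetric_bimanual",
                                        n = 500), seed = 12))
  expect_identical(sym$result$rq$rq, 1)
  expect_error(run_pipeline(list(input = list())), "kind")
  expect_error(run_pipeline(list(input = list(kind = "nope"))), "unknown")
  expect_error(run_pipeline(list(input = list(kind = "files"))), "paths")
})

test_that("pipeline outputs and manifest allow a bitwise rerun", {
  out <- withr::local_tempdir()
  cfg <- list(input = list(kind = "scenario", which = 1, n = 20000L),
              seed = 33, q = 90,
              output = list(dir = out))
  rep <- run_pipeline(cfg)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "points.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  # manifest records every tunable needed to rerun
  expect_equal(man$seed, 33)
  expect_equal(man$q, 90)
  expect_equal(man$D, 60)
  expect_true(!is.null(man$detector$ac$deadband))
  rerun <- run_pipeline(list(input = man$input, seed = man$seed,
                             D = man$D, q = man$q))
  expect_identical(rerun$result$Hq, rep$result$Hq)
})

test_that("YAML configs and the CLI wrapper drive the same pipeline", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "cfg.yaml")
  yaml::write_yaml(list(input = list(kind = "laterality",
                                     pattern = "scaled", m = 0.4, n = 400),
                        seed = 21,
                        output = list(dir = file.path(out, "res"))),
                   cfg_path)
  rep <- run_pipeline(cfg_path)
  expect_equal(rep$result$rq$rq, 0.4, tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "res", "liri_points.csv")))
  cli <- system.file("cli", "uluse.R", package = "uluse")
  expect_true(nzchar(cli) && file.exists(cli))
})

test_that("per-sample use aggregates sensibly onto the counts grid", {
  u <- make_use(c(rep(1, 80), rep(0, 70)), fs = 50)   # 3 s at 50 Hz
  cts <- intensity_signal("right", c(0, 1, 2), c(5, 5, 5), units = "counts/1s")
  ug <- uluse:::use_on_grid(u, cts)
  expect_equal(ug$u, c(1, 1, 0))  # epochs 1-2 majority in use, epoch 3 not
})
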