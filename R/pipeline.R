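#' Run the full analysis pipeline from a configuration
#'
#' Config-driven front end tying the modules together, usable from R or the
#' shell wrapper in `inst/cli/`. The configuration (a YAML file or an
#' equivalent nested list) names the input, the detector, and the analysis
#' parameters; a manifest recording every tunable and seed is written next to
#' the outputs so a run can be reproduced exactly.
#'
#' Supported `input$kind`:
#' \describe{
#'   \item{`scenario`}{a canonical use-intensity rectangle
#'     ([scenario_region()]; fields `which`, `n`) — reports Hq.}
#'   \item{`region`}{an explicit rectangle (fields `intensity_range`,
#'     `use_range`, `n`) — reports Hq.}
#'   \item{`laterality`}{a named laterality pattern (fields `pattern`, `n`,
#'     optionally `m`) — reports Rq and the view geometries.}
#'   \item{`files`}{per-limb epoch CSVs (fields `left`, `right`) — full
#'     [ul_assess()] analysis.}
#'   \item{`simulate`}{an inline bout schedule (field `bouts`: list of
#'     records with `limb`, `start`, `duration`, `kind`, and optionally
#'     `intensity`, `pitch`; plus `fs`, `T`) — full analysis of the
#'     simulated epochs.}
#' }
#'
#' @param config Path to a YAML file, or a nested list with the same
#'   structure. Top-level fields: `input` (required), `detector`
#'   (`f_u`: `"gm"` or `"thresholded_ac"`; optional `use_threshold`, `ac`,
#'   `gm` parameter blocks), `D`, `q`, `seed`, `output` (`dir`).
#' @return A list of class `"ul_report"`: `kind`, `result` (Hq value, an
#'   [rq()] result plus views, or an [ul_assess()] object), `manifest`, and
#'   `files` (paths written, if an output directory was configured).
#' @examples
#' rep <- run_pipeline(list(
#'   input = list(kind = "scenario", which = 1, n = 20000),
#'   seed = 1))
#' rep$result$Hq
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$input) || is.null(config$input$kind)) {
    stop("config must contain an input block with a kind")
  }
  seed <- config$seed %||% 1L
  D <- config$D %||% 60
  q <- config$q %||% 90
  det <- config$detector %||% list()
  f_u <- det$f_u %||% "gm"
  if (!f_u %in% c("gm", "thresholded_ac")) stop("unknown detector: ", f_u)
  ac <- do.call(ac_params, det$ac %||% list())
  gm <- do.call(gm_params, det$gm %||% list())
  use_threshold <- det$use_threshold %||% 2
  inp <- config$input
  kind <- inp$kind
  result <- switch(kind,
    scenario = {
      reg <- scenario_region(inp$which %||% 1)
      pts <- sample_uniform_region(reg$intensity_range, reg$use_range,
                                   n = inp$n %||% 200000L, seed = seed)
      list(Hq = hq(pts$A, q), q = q, n = nrow(pts), points = pts)
    },
    region = {
      pts <- sample_uniform_region(unlist(inp$intensity_range),
                                   unlist(inp$use_range),
                                   n = inp$n %||% 200000L, seed = seed)
      list(Hq = hq(pts$A, q), q = q, n = nrow(pts), points = pts)
    },
    laterality = {
      p <- laterality_pattern(inp$pattern, n = inp$n %||% 1000L,
                              seed = seed, m = inp$m %||% 0.5)
      list(rq = rq(p$I_r, p$I_l, q = q),
           liri = liri_points(p$I_r, p$I_l),
           isid = isid_points(p$I_r, p$I_l),
           bmmr = bmmr_points(p$I_r, p$I_l),
           pairs = p)
    },
    files = {
      if (is.null(inp$left) || is.null(inp$right)) {
        stop("files input needs left and right paths")
      }
      left <- read_epoch(inp$left, resample = inp$resample %||% "none")
      right <- read_epoch(inp$right, resample = inp$resample %||% "none")
      ul_assess(left, right, detector = if (f_u == "gm") "gm" else "ac",
                ac = ac, gm = gm, use_threshold = use_threshold,
                D = D, q = q)
    },
    simulate = {
      bouts <- do.call(rbind, lapply(inp$bouts, as.data.frame))
      sch <- activity_schedule(bouts$limb, bouts$start, bouts$duration,
                               bouts$kind,
                               intensity = bouts$intensity %||% 2,
                               pitch = bouts$pitch %||% 0,
                               fs = inp$fs %||% 50, T = inp$T %||% 60)
      sim <- simulate_imu_epoch(sch, seed = seed)
      ul_assess(sim$left$epoch, sim$right$epoch,
                detector = if (f_u == "gm") "gm" else "ac",
                ac = ac, gm = gm, use_threshold = use_threshold,
                D = D, q = q)
    },
    stop("unknown input kind: ", kind))
  manifest <- list(
    package_version = as.character(utils::packageVersion("uluse")),
    input = inp, detector = list(f_u = f_u, use_threshold = use_threshold,
                                 ac = unclass(ac), gm = unclass(gm)),
    D = D, q = q, seed = seed)
  files <- character()
  out_dir <- config$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_report_files(kind, result, manifest, out_dir)
  }
  structure(list(kind = kind, result = result, manifest = manifest,
                 files = files),
            class = "ul_report")
}

write_report_files <- function(kind, result, manifest, out_dir) {
  paths <- character()
  put <- function(name) file.path(out_dir, name)
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, put("manifest.json"))
  if (kind %in% c("scenario", "region")) {
    utils::write.csv(result$points, put("points.csv"), row.names = FALSE)
    jsonlite::write_json(list(Hq = result$Hq, q = result$q, n = result$n),
                         put("summary.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, put("points.csv"), put("summary.json"))
  } else if (kind == "laterality") {
    utils::write.csv(result$pairs, put("pairs.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(result$rq), put("summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (v in c("liri", "isid", "bmmr")) {
      utils::write.csv(result[[v]]$points, put(paste0(v, "_points.csv")),
                       row.names = FALSE)
      paths <- c(paths, put(paste0(v, "_points.csv")))
    }
    paths <- c(paths, put("pairs.csv"), put("summary.json"))
  } else {
    s <- result$summary
    jsonlite::write_json(
      list(q = s$q, Hq_left = s$Hq_left, Hq_right = s$Hq_right,
           rq = unclass(s$rq), detector = result$params$detector,
           D = result$params$D),
      put("summary.json"), auto_unbox = TRUE, digits = NA)
    for (lb in c("left", "right")) {
      utils::write.csv(as.data.frame(result$limbs[[lb]]$windowed),
                       put(paste0("windowed_", lb, ".csv")),
                       row.names = FALSE)
      paths <- c(paths, put(paste0("windowed_", lb, ".csv")))
    }
    paths <- c(paths, put("summary.json"))
  }
  paths
}

#' @export
print.ul_report <- function(x, ...) {
  cat(sprintf("<ul_report> input kind: %s\n", x$kind))
  if (x$kind %in% c("scenario", "region")) {
    cat(sprintf("  Hq = %.4f (q = %g, n = %d)\n",
                x$result$Hq, x$result$q, x$result$n))
  } else if (x$kind == "laterality") {
    print(x$result$rq)
  } else {
    print(x$result)
  }
  if (length(x$files)) {
    cat("  files written:\n")
    cat(paste0("    ", x$files, collapse = "\n"), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
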