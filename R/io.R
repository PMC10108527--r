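# Interchange formats (CSV + JSON sidecars) and the end-to-end pipeline.
#
# Timestamps are serialized as ISO-8601 UTC with microsecond fractional
# seconds; internal representation is numeric seconds since epoch, with
# local clock hour derived from a configured zone offset. Numeric columns
# are written with %.17g so a write/read round trip reproduces doubles
# exactly.

.fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  out[!is.finite(v)] <- "NA"
  out
}

.fmt_time <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS6Z")
}

.parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  looks_iso <- grepl("T", x[1], fixed = TRUE)
  if (!looks_iso) return(suppressWarnings(as.numeric(x)))
  as.numeric(as.POSIXct(strptime(sub("Z$", "", x), "%Y-%m-%dT%H:%M:%OS",
                                 tz = "UTC")))
}

.write_sidecar <- function(path, params) {
  if (is.null(params)) return(invisible(NULL))
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write and read detection CSV files
#'
#' Columns `tag_id`, `time` (ISO-8601 UTC), `x_m`, `y_m`, `accel_ms2`;
#' generator parameters can be stored in a JSON sidecar (`<path>.json`).
#' `read_detections` also accepts `lon`/`lat` (or `longitude`/`latitude`)
#' columns, which are projected to local planar metres about their
#' centroid; malformed rows are dropped with a message, unsorted input is
#' sorted with a warning, and a missing acceleration column yields missing
#' `accel` (the pipeline then runs on step/angle only).
#'
#' @param x a `"detections"` data.frame (`tag_id`, `time` s, `x`, `y`,
#'   `accel`).
#' @param path CSV file path.
#' @param params optional list written to the JSON sidecar.
#' @return `read_detections`: a `"detections"` data.frame.
#' @export
write_detections <- function(x, path, params = NULL) {
  out <- data.frame(tag_id = x$tag_id, time = .fmt_time(x$time),
                    x_m = .fmt_num(x$x), y_m = .fmt_num(x$y),
                    accel_ms2 = .fmt_num(x$accel))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  .write_sidecar(path, params)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  names(d)[names(d) == "longitude"] <- "lon"
  names(d)[names(d) == "latitude"] <- "lat"
  if (!"tag_id" %in% names(d) || !"time" %in% names(d))
    stop("detections file must have 'tag_id' and 'time' columns")
  has_xy <- all(c("x_m", "y_m") %in% names(d)) || all(c("x", "y") %in% names(d))
  has_ll <- all(c("lon", "lat") %in% names(d))
  if (!has_xy && !has_ll)
    stop("detections file must have 'x_m'/'y_m' (or 'lon'/'lat') columns")
  time <- .parse_time(d$time)
  if (has_xy) {
    x <- if ("x_m" %in% names(d)) d$x_m else d$x
    y <- if ("y_m" %in% names(d)) d$y_m else d$y
  } else {
    pr <- project_lonlat(d$lon, d$lat)
    x <- pr$x; y <- pr$y
  }
  accel <- if ("accel_ms2" %in% names(d)) d$accel_ms2
  else if ("accel" %in% names(d)) d$accel else NA_real_
  out <- data.frame(tag_id = as.character(d$tag_id), time = time,
                    x = as.numeric(x), y = as.numeric(y),
                    accel = as.numeric(accel))
  bad <- !is.finite(out$time) | !is.finite(out$x) | !is.finite(out$y)
  if (any(bad)) {
    message("dropped ", sum(bad), " malformed detection row(s)")
    out <- out[!bad, , drop = FALSE]
  }
  ord <- order(out$tag_id, out$time)
  if (any(ord != seq_along(ord)))
    warning("detections were not time-sorted; sorting")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detections", "data.frame")
  out
}

#' Write and read tide CSV files
#'
#' Columns `time` (ISO-8601 UTC) and `height_m`.
#'
#' @param x a `"tide_series"` data.frame.
#' @param path CSV file path.
#' @param params optional list written to the JSON sidecar.
#' @export
write_tide <- function(x, path, params = NULL) {
  out <- data.frame(time = .fmt_time(x$time), height_m = .fmt_num(x$height))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  .write_sidecar(path, params)
  invisible(path)
}

#' @rdname write_tide
#' @export
read_tide <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(time = .parse_time(d$time),
                    height = as.numeric(d$height_m))
  class(out) <- c("tide_series", "data.frame")
  out
}

#' Write a simulated true path to CSV
#'
#' Columns `interval`, `state`, `step`, `angle`, `accel`.
#'
#' @param x a `"true_path"` data.frame.
#' @param path CSV file path.
#' @param params optional generator parameters for the JSON sidecar.
#' @export
write_true_path <- function(x, path, params = NULL) {
  out <- data.frame(interval = x$interval, state = x$state,
                    step = .fmt_num(x$step), angle = .fmt_num(x$angle),
                    accel = .fmt_num(x$accel))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  .write_sidecar(path, params)
  invisible(path)
}

#' Pipeline configuration
#'
#' Reads a YAML file (or completes a list) of pipeline settings, applying
#' defaults and validating the analysis envelope: interpolation interval
#' in \{5, 10, 15\} min, 2-3 states, mixtures K within 1..4.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    delta_min = 15, n_states = 2, K = 1,
    formulas = c("~1"),
    n_restarts = 50, ctcrw_restarts = 50, maxit = 300,
    min_track_length = 100, seed = 1, tz_offset_hours = 10,
    error_sd = 1.07, habitat_buffer = 1.26,
    tide = NULL, habitat = NULL, temperature = NULL,
    reference_tag = NULL, stationary_ci = TRUE,
    outdir = "pipeline_output")
  cfg <- modifyList(defaults, config)
  if (!cfg$delta_min %in% c(5, 10, 15))
    stop("config: delta_min must be 5, 10 or 15")
  if (!cfg$n_states %in% 2:3) stop("config: n_states must be 2 or 3")
  if (!all(cfg$K %in% 1:4)) stop("config: K must be within 1..4")
  if (is.null(cfg$detections)) stop("config: 'detections' path is required")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full movement-analysis pipeline
#'
#' Orchestrates: read detections (and tide/habitat/temperature), audit the
#' reference tag (or use the configured error SD), split into tracks,
#' regularize each with the CTCRW, derive observation streams and
#' covariates, fit the HMM over the formula-by-K grid, select by AIC,
#' decode with Viterbi, compute pseudo-residual diagnostics and occupancy,
#' and write all artefacts (CSV/JSON) with provenance to `outdir`. The
#' run is a pure function of (inputs, config, seed): identical inputs give
#' byte-identical outputs.
#'
#' @param config a config list or YAML path, see [read_pipeline_config()].
#' @return invisibly, a list with the fitted objects and artefact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  detections <- .stage("read", read_detections(cfg$detections))
  tide <- if (!is.null(cfg$tide)) .stage("read", read_tide(cfg$tide))
  habitat <- if (!is.null(cfg$habitat))
    .stage("read", read_habitat_geojson(cfg$habitat))
  temperature <- if (!is.null(cfg$temperature))
    .stage("read", read.csv(cfg$temperature))

  error_cov <- diag(cfg$error_sd^2, 2)
  audit <- NULL
  if (!is.null(cfg$reference_tag)) {
    audit <- .stage("audit", {
      ref <- read_detections(cfg$reference_tag$path)
      audit_reference_tag(ref, c(cfg$reference_tag$x, cfg$reference_tag$y))
    })
    error_cov <- audit$error_cov
  }

  tracks <- .stage("split",
                   split_tracks(detections, cfg$delta_min,
                                cfg$min_track_length))
  if (length(tracks) == 0)
    stop("pipeline stage 'split': no track met the length criterion")

  series <- .stage("regularize", lapply(seq_along(tracks), function(i) {
    fit <- fit_ctcrw(tracks[[i]], error_cov,
                     n_restarts = cfg$ctcrw_restarts,
                     seed = cfg$seed + i)
    predict_regular(tracks[[i]], fit, cfg$delta_min)
  }))

  hmm_data <- .stage("covariates",
                     prepare_hmm_data(series, tracks, tide = tide,
                                      temperature = temperature,
                                      habitat = habitat,
                                      habitat_buffer = cfg$habitat_buffer,
                                      tz_offset_hours = cfg$tz_offset_hours))

  fits <- .stage("fit", {
    grid <- expand.grid(f = seq_along(cfg$formulas), K = cfg$K)
    lapply(seq_len(nrow(grid)), function(g) {
      fit_hmm(hmm_data, n_states = cfg$n_states,
              formula = stats::as.formula(cfg$formulas[grid$f[g]]),
              K = grid$K[g], n_restarts = cfg$n_restarts,
              seed = cfg$seed + 1000 + g, maxit = cfg$maxit)
    })
  })
  sel <- .stage("select", select_model(fits))
  best_idx <- which.min(vapply(fits, function(f) f$aic, numeric(1)))
  best <- fits[[best_idx]]

  decoded <- .stage("decode", viterbi(best))
  resid <- .stage("diagnose", pseudo_residuals(best, seed = cfg$seed))
  diagn <- .stage("diagnose",
                  residual_diagnostics(list(best = resid),
                                       delta_min = cfg$delta_min))
  occ <- occupancy(decoded)

  paths <- list(
    model_selection = file.path(cfg$outdir, "model_selection.csv"),
    decoded = file.path(cfg$outdir, "decoded_states.csv"),
    diagnostics = file.path(cfg$outdir, "residual_diagnostics.csv"),
    series = file.path(cfg$outdir, "regular_series.csv"),
    occupancy = file.path(cfg$outdir, "occupancy.json"),
    provenance = file.path(cfg$outdir, "provenance.json"))
  .stage("write", {
    write.csv(as.data.frame(sel), paths$model_selection, row.names = FALSE)
    dec_out <- decoded
    for (nm in grep("^p_state", names(dec_out), value = TRUE))
      dec_out[[nm]] <- .fmt_num(dec_out[[nm]])
    write.csv(dec_out, paths$decoded, row.names = FALSE, quote = FALSE)
    write.csv(diagn, paths$diagnostics, row.names = FALSE)
    ser_out <- do.call(rbind, lapply(series, function(s)
      data.frame(track_id = attr(s, "track_id"), time = .fmt_time(s$time),
                 x = .fmt_num(s$x), y = .fmt_num(s$y),
                 var_x = .fmt_num(s$var_x), var_y = .fmt_num(s$var_y))))
    write.csv(ser_out, paths$series, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(occ), paths$occupancy, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    prov <- list(config = unclass(cfg),
                 package_version = as.character(packageVersion("crabHMM")),
                 n_tracks = length(tracks),
                 n_intervals = nrow(hmm_data),
                 best_model = sel$model[1])
    jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  stationary <- NULL
  if ("tide" %in% all.vars(best$formula)) {
    stationary <- .stage("stationary", {
      sc <- stationary_probabilities(best, "tide", se = cfg$stationary_ci)
      out <- sc
      for (nm in c("value", "prob", "lower", "upper"))
        out[[nm]] <- .fmt_num(out[[nm]])
      p <- file.path(cfg$outdir, "stationary_tide.csv")
      write.csv(out, p, row.names = FALSE, quote = FALSE)
      paths$stationary <<- p
      sc
    })
  }

  invisible(list(config = cfg, audit = audit, tracks = tracks,
                 series = series, data = hmm_data, fits = fits,
                 selection = sel, best = best, decoded = decoded,
                 residuals = resid, diagnostics = diagn,
                 occupancy = occ, stationary = stationary,
                 paths = paths))
}
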