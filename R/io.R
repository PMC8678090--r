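#' Short content hash of a configuration
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1) of the JSON
#' serialization, returned as 8 hex digits. Embedded in every output
#' artifact (together with the seed) so a run can be matched to the
#' configuration that produced it.
#'
#' @param config any serializable object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

run_header <- function(seed = NULL, hash = NULL) {
  c(if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(hash)) paste0("# config_hash: ", hash))
}

#' Read and write pipeline tables as annotated CSV
#'
#' Tables are written as UTF-8 CSV with `.` decimal separator and leading
#' `# key: value` comment lines carrying the seed and config hash; numeric
#' values keep 15 significant digits so a write/read round trip is lossless
#' to well below 1e-12 at the scales the pipeline produces.
#'
#' @param df data frame to write.
#' @param path file path.
#' @param seed,hash optional provenance to embed in the header.
#' @return `read_run_table()` returns the data frame with attributes `seed`
#'   and `config_hash` when present; `write_run_table()` returns `path`
#'   invisibly.
#' @export
write_run_table <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- run_header(seed, hash)
  if (length(hdr)) writeLines(hdr, con)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE,
                                scientific = FALSE))
  })
  utils::write.table(out, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_run_table
#' @export
read_run_table <- function(path) {
  first <- readLines(path, n = 10)
  meta <- grep("^# ", first, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NULL
  }
  attr(df, "seed") <- get_meta("seed")
  attr(df, "config_hash") <- get_meta("config_hash")
  df
}

#' Serialize fitted nitrogen models to and from JSON
#'
#' Coefficients are written at full double precision (17 significant digits)
#' so the round trip is bit-identical; the fit summary, seed and config hash
#' travel alongside.
#'
#' @param model a `nitrogen_model_i` or `nitrogen_model_ii`.
#' @param path file path.
#' @param seed,hash optional provenance fields.
#' @return `read_model_json()` rebuilds the model object;
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path, seed = NULL, hash = NULL) {
  # authoritative decimal strings: %.17g survives the text round trip exactly
  payload <- list(class = class(model)[1],
                  coefficients = as.list(model$coefficients),
                  coefficients_str = as.list(vapply(
                    model$coefficients, function(v) sprintf("%.17g", v), "")),
                  summary = model$summary,
                  seed = seed, config_hash = hash)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- vapply(payload$coefficients_str, as.numeric, numeric(1))
  structure(list(coefficients = cf, summary = payload$summary),
            class = payload$class,
            seed = payload$seed, config_hash = payload$config_hash)
}

#' Write and read multiband rasters as 32-bit TIFF with a JSON sidecar
#'
#' The pixel grid is stored as one TIFF page per band. TIFF storage holds
#' values in `[0, 1]`, so the stack is scaled by its value range and the
#' scale, offset, band wavelengths, value kind and provenance are recorded
#' in `<path>.json`; `read_band_stack()` undoes the scaling.
#'
#' @param stack a [band_stack()].
#' @param path path of the `.tif` file to write (sidecar written alongside).
#' @param seed,hash optional provenance fields.
#' @return `read_band_stack()` returns the restored [band_stack()];
#'   `write_band_stack()` returns `path` invisibly.
#' @export
write_band_stack <- function(stack, path, seed = NULL, hash = NULL) {
  stopifnot(inherits(stack, "band_stack"))
  lo <- min(stack$values); hi <- max(stack$values)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_along(stack$band_centers), function(b) {
    (stack$values[, , b] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(
    list(band_centers = stack$band_centers, value_kind = stack$value_kind,
         offset = lo, scale = scale, seed = seed, config_hash = hash),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_band_stack
#' @export
read_band_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) {
    arr[, , b] <- pages[[b]] * meta$scale + meta$offset
  }
  band_stack(arr, meta$band_centers, meta$value_kind)
}

#' Write and read plot/panel layouts as GeoJSON
#'
#' Each rectangle becomes a Polygon feature in pixel coordinates
#' (x = column, y = row), with the half-open bounds and the `role`, `id`,
#' `variety`, `stage` and `reflectance` properties; reading restores the
#' layout data frame exactly.
#'
#' @param layout a layout data frame (see [generate_scene()]).
#' @param path file path.
#' @param seed,hash optional provenance fields (stored as foreign members).
#' @return `read_layout_geojson()` returns the layout data frame;
#'   `write_layout_geojson()` returns `path` invisibly.
#' @export
write_layout_geojson <- function(layout, path, seed = NULL, hash = NULL) {
  features <- lapply(seq_len(nrow(layout)), function(i) {
    r <- layout[i, ]
    ring <- list(c(r$col0, r$row0), c(r$col1, r$row0), c(r$col1, r$row1),
                 c(r$col0, r$row1), c(r$col0, r$row0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(role = r$role, id = r$id,
                           variety = if (is.na(r$variety)) NULL else r$variety,
                           stage = r$stage,
                           reflectance = if (is.na(r$reflectance)) NULL
                                         else r$reflectance,
                           row0 = r$row0, row1 = r$row1,
                           col0 = r$col0, col1 = r$col1))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", seed = seed, config_hash = hash,
         features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    data.frame(role = p$role, id = p$id,
               variety = p$variety %||% NA_integer_,
               stage = p$stage,
               reflectance = p$reflectance %||% NA_real_,
               row0 = p$row0, row1 = p$row1, col0 = p$col0, col1 = p$col1)
  })
  do.call(rbind, rows)
}

#' Write and read the generator configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path file path.
#' @return `read_synth_config_yaml()` rebuilds the `synth_config` through
#'   [synth_config()] validation; `write_synth_config_yaml()` returns `path`
#'   invisibly.
#' @export
write_synth_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_synth_config_yaml
#' @export
read_synth_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(synth_config, raw[intersect(names(raw), names(formals(synth_config)))])
}

#' Run the full pipeline on a synthetic field trial
#'
#' Chains the stages end to end: simulate the scenes and ground measurements,
#' fit the empirical-line calibration from each scene's panels, convert DN to
#' reflectance, aggregate plot reflectance and compute vegetation indices,
#' fit Model I (N% ~ NDRE, tillering excluded) and Model II
#' (N% x LAI ~ NDRE), assemble the stage series and classify the high-NUE
#' phenotype. When `out_dir` is given, every artifact (calibration report,
#' VI table, model JSONs, phenotype report, layouts, config) is written with
#' the seed and config hash embedded.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @param measure nitrogen measure used for the phenotype screen
#'   (default `"n_eqa"`).
#' @param rule a [phenotype_rule()].
#' @return List with `trajectories`, `ground`, `calibration` (per-stage
#'   data frame), `plot_records`, `vi`, `model_i`, `model_ii`, `series`,
#'   `screen`, `flagged` (variety ids).
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         measure = "n_eqa", rule = phenotype_rule()) {
  stopifnot(inherits(config, "synth_config"))
  hash <- config_hash(config)
  traj <- generate_trajectories(config)
  ground <- generate_ground_measurements(traj, config)

  calib_rows <- list()
  plot_rows <- list()
  layouts <- list()
  for (stage in RICE_STAGES) {
    scene <- generate_scene(config, stage, traj)
    panels <- extract_panel_dns(scene$stack, scene$layout)
    elm <- fit_empirical_line(panels)
    refl <- apply_calibration(scene$stack, elm)
    calib_rows[[stage]] <- data.frame(
      stage = stage, band = elm$band_centers, gain = elm$gain,
      offset = elm$offset, rmse = elm$rmse, n_panels = elm$n_panels,
      row.names = NULL)
    plots <- scene$layout[scene$layout$role == "plot", , drop = FALSE]
    means <- t(vapply(seq_len(nrow(plots)), function(i) {
      aggregate_plot(refl, plots[i, ])
    }, numeric(length(config$band_centers))))
    pr <- data.frame(variety = plots$variety, stage = stage)
    plot_rows[[stage]] <- cbind(pr, as.data.frame(means))
    layouts[[stage]] <- scene$layout
  }
  calibration <- do.call(rbind, c(calib_rows, make.row.names = FALSE))
  plot_records <- do.call(rbind, c(plot_rows, make.row.names = FALSE))
  vi <- vi_table(plot_records)

  ndre <- vi[vi$index == "NDRE", c("variety", "stage", "value")]
  names(ndre)[3] <- "ndre"
  merged <- merge(ground, ndre, by = c("variety", "stage"))
  merged <- merged[order(merged$variety, stage_factor(merged$stage)), ]

  post_ts <- exclude_tillering(merged)
  model_i <- fit_model_i(post_ts$ndre, post_ts$n_eqa)
  model_ii <- fit_model_ii(post_ts$ndre, post_ts$n_eqa * post_ts$lai)

  merged$n_uav <- predict(model_i, merged$ndre)
  merged$n_lai_uav <- predict(model_ii, merged$ndre)

  series <- build_stage_series(merged, measure)
  screen <- classify_high_nue(series, rule)
  flagged <- screen$variety[screen$flagged]

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed
    write_synth_config_yaml(config, file.path(out_dir, "config.yaml"))
    write_run_table(calibration, file.path(out_dir, "calibration.csv"), seed, hash)
    write_run_table(vi, file.path(out_dir, "vi_table.csv"), seed, hash)
    write_run_table(merged, file.path(out_dir, "plot_records.csv"), seed, hash)
    write_run_table(screen, file.path(out_dir, "phenotype_report.csv"), seed, hash)
    write_model_json(model_i, file.path(out_dir, "model_i.json"), seed, hash)
    write_model_json(model_ii, file.path(out_dir, "model_ii.json"), seed, hash)
    write_layout_geojson(layouts[["TS"]], file.path(out_dir, "layout.geojson"),
                         seed, hash)
  }
  list(trajectories = traj, ground = ground, calibration = calibration,
       plot_records = merged, vi = vi, model_i = model_i,
       model_ii = model_ii, series = series, screen = screen,
       flagged = flagged)
}
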