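#' Configuration for the synthetic field generator
#'
#' Builds the configuration object consumed by all `generate_*()` functions.
#' The generator emulates a multi-variety rice field trial observed by a
#' 12-band multispectral camera: per-variety nitrogen trajectories over the
#' six growth stages, canopy reflectance consistent with the NDRE nitrogen
#' models, a linear per-band sensor (DN = (rho - offset)/gain), six ground
#' calibration panels, water-background contamination at tillering, ground
#' instruments (EQA chemistry, SPAD, N-pen with its 2% saturation floor), and
#' a two-variety nitrogen dosage yield trial.
#'
#' @param n_varieties number of varieties in the collection (>= 2).
#' @param seed integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param high_nue_indices 1-based variety indices planted as high-NUE.
#' @param band_centers the 12 nominal band centers in nm; fixed by the camera.
#' @param true_gain,true_offset per-band linear sensor coefficients
#'   (reflectance = DN * gain + offset); recycled to 12 bands.
#' @param dn_noise_sd additive Gaussian pixel noise on DN.
#' @param reflectance_noise_sd additive Gaussian noise on per-plot band
#'   reflectance (unitless).
#' @param traj_jitter_sd per-variety, per-stage Gaussian jitter around the
#'   baseline trajectory templates (percentage points of N).
#' @param water_fraction_ts fraction of each plot that is uncovered water at
#'   tillering stage, mixed linearly into the canopy signal.
#' @param water_reflectance per-band water reflectance (low everywhere,
#'   near zero in the NIR).
#' @param npen_floor saturation floor of the N-pen leaf meter (% N); readings
#'   below it cluster at the floor.
#' @param eqa_noise_sd,spad_noise_sd,npen_noise_sd ground-instrument noise.
#' @param spad_coef affine map `SPAD = a * N% + b` (unitless meter reading).
#' @param plant_density plants per square meter (`d` in LAI = LA_S * d).
#' @param plot_grid `c(rows, cols)` of the plot grid; defaults to the
#'   smallest near-square grid holding `n_varieties`.
#' @param plot_size_px plot side length in pixels; `plot_gap_px` the gap
#'   between plots; `panel_size_px` the calibration-panel side length.
#' @param model_i_coeffs quadratic N% ~ NDRE coefficients `c(a, b, c)` used
#'   to invert trajectories into reflectance.
#' @param model_ii_coeffs exponential N% x LAI ~ NDRE coefficients
#'   `c(alpha, beta)`.
#' @param lai_mode how LAI trajectories are generated: `"model_ii"`
#'   (default) derives `LAI = alpha * exp(beta * NDRE) / N%` from the true
#'   nitrogen trajectory so the field data are exactly consistent with both
#'   nitrogen models at zero noise; `"template"` uses `lai_template` plus
#'   jitter instead.
#' @param canopy_nir NIR (800 nm) canopy reflectance anchor.
#' @param background_reflectance flat reflectance of non-plot field pixels.
#' @param baseline_templates named list of 6-value N% trajectory templates
#'   cycled across non-high-NUE varieties.
#' @param lai_template 6-value LAI trajectory template; `lai_jitter_sd` its
#'   per-variety jitter.
#' @param high_nue_margin how far (in % N) the high-NUE varieties sit above
#'   the collection maximum at FHS and MRS.
#' @param gd_mean_days named `c(EM = , LM = )` mean growth durations;
#'   `gd_sd_days` their spread; high-NUE varieties are planted late-maturing.
#' @param quantize if `TRUE`, DN values are rounded and clamped to the 10-bit
#'   sensor range `[0, 1023]`; default keeps DN floating point.
#' @param dosage overrides for the dosage-trial block (see
#'   [generate_dosage_trial()]).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_varieties = 51,
                         seed = 1L,
                         high_nue_indices = 1L,
                         band_centers = BAND_CENTERS,
                         true_gain = 0.005,
                         true_offset = 0.01,
                         dn_noise_sd = 0.5,
                         reflectance_noise_sd = 0.004,
                         traj_jitter_sd = 0.2,
                         water_fraction_ts = 0.4,
                         water_reflectance = NULL,
                         npen_floor = 2.0,
                         eqa_noise_sd = 0.05,
                         spad_noise_sd = 1.0,
                         npen_noise_sd = 0.1,
                         spad_coef = c(a = 12, b = 8),
                         plant_density = 22.5,
                         plot_grid = NULL,
                         plot_size_px = 6L,
                         plot_gap_px = 2L,
                         panel_size_px = 6L,
                         model_i_coeffs = c(a = 5.75, b = 8.17, c = 0.58),
                         model_ii_coeffs = c(alpha = 1.06, beta = 4.57),
                         canopy_nir = 0.45,
                         background_reflectance = 0.12,
                         baseline_templates = NULL,
                         lai_mode = c("model_ii", "template"),
                         lai_template = c(1.0, 2.2, 3.2, 4.2, 4.0, 3.4),
                         lai_jitter_sd = 0.3,
                         high_nue_margin = 0.15,
                         gd_mean_days = c(EM = 85, LM = 115),
                         gd_sd_days = 4,
                         quantize = FALSE,
                         dosage = list()) {
  # normalize inputs that may arrive as (possibly unnamed) lists, e.g. from YAML
  band_centers <- as.numeric(unlist(band_centers))
  named_num <- function(x, nms) {
    x <- unlist(x)
    if (!is.null(names(x)) && all(nms %in% names(x))) x <- x[nms]
    stats::setNames(as.numeric(x), nms)
  }
  spad_coef <- named_num(spad_coef, c("a", "b"))
  gd_mean_days <- named_num(gd_mean_days, c("EM", "LM"))
  model_i_coeffs <- named_num(model_i_coeffs, c("a", "b", "c"))
  model_ii_coeffs <- named_num(model_ii_coeffs, c("alpha", "beta"))
  true_gain <- as.numeric(unlist(true_gain))
  true_offset <- as.numeric(unlist(true_offset))
  if (!is.null(water_reflectance)) {
    water_reflectance <- as.numeric(unlist(water_reflectance))
  }
  if (!is.null(baseline_templates)) {
    baseline_templates <- lapply(baseline_templates, function(t) as.numeric(unlist(t)))
  }
  lai_template <- as.numeric(unlist(lai_template))
  if (!is.null(plot_grid)) plot_grid <- as.integer(unlist(plot_grid))
  if (!identical(sort(band_centers), sort(BAND_CENTERS))) {
    stop("band_centers must be exactly the 12 camera centers: ",
         paste(BAND_CENTERS, collapse = ", "))
  }
  band_centers <- sort(band_centers)
  nb <- length(band_centers)
  if (n_varieties < 2) stop("n_varieties < 2: cannot form a collection")
  high_nue_indices <- as.integer(high_nue_indices)
  if (length(high_nue_indices) > 0 &&
      (any(high_nue_indices < 1) || any(high_nue_indices > n_varieties))) {
    stop("high_nue_indices must lie in 1..n_varieties")
  }
  if (water_fraction_ts < 0 || water_fraction_ts > 1) {
    stop("water_fraction_ts must be in [0, 1]")
  }
  sds <- c(dn_noise_sd, reflectance_noise_sd, traj_jitter_sd, eqa_noise_sd,
           spad_noise_sd, npen_noise_sd, lai_jitter_sd)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0")
  if (is.null(water_reflectance)) {
    # weak visible scatter, strong NIR absorption
    water_reflectance <- stats::setNames(
      c(0.06, 0.055, 0.05, 0.045, 0.03, 0.028, 0.02, 0.01,
        0.02, 0.015, 0.012, 0.01), band_names(band_centers))
  } else {
    water_reflectance <- rep_len(water_reflectance, nb)
    names(water_reflectance) <- band_names(band_centers)
  }
  if (is.null(baseline_templates)) {
    baseline_templates <- list(
      mid    = c(3.2, 3.0, 2.8, 2.5, 1.8, 1.2),
      lush   = c(3.6, 3.4, 3.1, 2.7, 1.9, 1.3),
      sparse = c(2.8, 2.6, 2.4, 2.1, 1.5, 1.0))
  }
  stopifnot(all(vapply(baseline_templates, length, 0L) == 6L),
            all(unlist(baseline_templates) > 0),
            length(lai_template) == 6L, all(lai_template > 0))
  if (is.null(plot_grid)) {
    rows <- floor(sqrt(n_varieties))
    plot_grid <- c(rows, ceiling(n_varieties / rows))
  }
  if (prod(plot_grid) < n_varieties) {
    stop("plot_grid (", plot_grid[1], " x ", plot_grid[2],
         ") cannot hold ", n_varieties, " plots")
  }
  cfg <- list(
    n_varieties = as.integer(n_varieties), seed = as.integer(seed),
    high_nue_indices = high_nue_indices, band_centers = band_centers,
    true_gain = stats::setNames(rep_len(true_gain, nb), band_names(band_centers)),
    true_offset = stats::setNames(rep_len(true_offset, nb), band_names(band_centers)),
    dn_noise_sd = dn_noise_sd, reflectance_noise_sd = reflectance_noise_sd,
    traj_jitter_sd = traj_jitter_sd, water_fraction_ts = water_fraction_ts,
    water_reflectance = water_reflectance, npen_floor = npen_floor,
    eqa_noise_sd = eqa_noise_sd, spad_noise_sd = spad_noise_sd,
    npen_noise_sd = npen_noise_sd, spad_coef = spad_coef,
    plant_density = plant_density, plot_grid = as.integer(plot_grid),
    plot_size_px = as.integer(plot_size_px),
    plot_gap_px = as.integer(plot_gap_px),
    panel_size_px = as.integer(panel_size_px),
    model_i_coeffs = model_i_coeffs,
    model_ii_coeffs = model_ii_coeffs,
    canopy_nir = canopy_nir, background_reflectance = background_reflectance,
    baseline_templates = baseline_templates,
    lai_mode = match.arg(lai_mode), lai_template = lai_template,
    lai_jitter_sd = lai_jitter_sd, high_nue_margin = high_nue_margin,
    gd_mean_days = gd_mean_days, gd_sd_days = gd_sd_days,
    quantize = isTRUE(quantize), dosage = dosage)
  class(cfg) <- "synth_config"
  cfg
}

# canopy spectral shape: visible/red-edge bands as ratios to the 720 nm value,
# NIR bands as ratios to the 800 nm value (liquid-water absorption at 950 nm)
CANOPY_SHAPE_VIS <- c(b490 = 0.30, b520 = 0.55, b550 = 0.70, b570 = 0.62,
                      b670 = 0.32, b680 = 0.34, b700 = 0.75)
CANOPY_SHAPE_NIR <- c(b850 = 0.99, b900 = 0.96, b950 = 0.88)

#' Invert the quadratic nitrogen model to its NDRE argument
#'
#' Solves `y = a x^2 + b x + c` for the larger root, which is the branch on
#' which NDRE increases with nitrogen. Admissible N% is `[c, a + b + c)`,
#' corresponding to NDRE in `[0, 1)`.
#'
#' @param n_pct nitrogen content (% dry mass), vectorized.
#' @param coeffs quadratic coefficients `c(a, b, c)`.
#' @return NDRE values in `[0, 1)`.
#' @export
invert_model_i <- function(n_pct, coeffs = c(a = 5.75, b = 8.17, c = 0.58)) {
  a <- coeffs[[1]]; b <- coeffs[[2]]; cc <- coeffs[[3]]
  lo <- cc; hi <- a + b + cc
  if (any(n_pct < lo | n_pct >= hi)) {
    stop(sprintf("N%% outside the invertible range [%g, %g)", lo, hi))
  }
  (-b + sqrt(b^2 - 4 * a * (cc - n_pct))) / (2 * a)
}

#' Generate per-variety nitrogen trajectories over the six growth stages
#'
#' Non-high-NUE varieties draw their stage-wise true N% from the configured
#' baseline templates (cycled across varieties) plus Gaussian jitter. Planted
#' high-NUE varieties are constructed against the realized collection: their
#' vegetative (TS..BS) values sit at an inner quantile of each stage's
#' distribution, their FHS and MRS values exceed the collection maximum by
#' `high_nue_margin`, and their booting-to-ripening decline rate is kept
#' below the median of the other varieties. LAI follows a jittered template
#' and growth duration is drawn from an early/late maturity mixture.
#'
#' @param config a [synth_config()].
#' @return A data frame with one row per variety x stage: `variety`, `stage`
#'   (ordered factor), `n_pct` (true canopy N%), `lai`, `gd_days`,
#'   `high_nue` (planted label).
#' @export
generate_trajectories <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_varieties
  withr::with_seed(config$seed, {
    tmpl <- config$baseline_templates
    # keep every trajectory comfortably inside the Model-I invertible range
    n_floor <- config$model_i_coeffs[["c"]] + 0.1
    base <- matrix(NA_real_, n, 6, dimnames = list(NULL, RICE_STAGES))
    for (v in seq_len(n)) {
      tv <- tmpl[[((v - 1) %% length(tmpl)) + 1]]
      base[v, ] <- pmax(tv + stats::rnorm(6, 0, config$traj_jitter_sd), n_floor)
    }
    lai <- matrix(pmax(rep(config$lai_template, each = n) +
                         stats::rnorm(6 * n, 0, config$lai_jitter_sd), 0.2),
                  n, 6, dimnames = list(NULL, RICE_STAGES), byrow = FALSE)
    late <- stats::runif(n) < 0.5
    gd <- ifelse(late, config$gd_mean_days[["LM"]], config$gd_mean_days[["EM"]]) +
      stats::rnorm(n, 0, config$gd_sd_days)
    gd <- pmax(round(gd), 60)

    hi <- config$high_nue_indices
    if (length(hi) > 0) {
      others <- base[-hi, , drop = FALSE]
      for (k in seq_along(hi)) {
        v <- hi[k]
        for (s in VEGETATIVE_STAGES) {
          base[v, s] <- stats::quantile(others[, s], 0.70, names = FALSE)
        }
        stagger <- config$high_nue_margin * (1 + 0.05 * (k - 1))
        base[v, "FHS"] <- max(others[, "FHS"]) + stagger
        base[v, "MRS"] <- max(others[, "MRS"]) + stagger
        # keep the post-booting decline strictly below the others' median
        med_decline <- stats::median((others[, "BS"] - others[, "MRS"]) / 2)
        min_mrs <- base[v, "BS"] - 2 * 0.8 * med_decline
        base[v, "MRS"] <- max(base[v, "MRS"], min_mrs)
        gd[v] <- round(config$gd_mean_days[["LM"]])
      }
    }
    if (config$lai_mode == "model_ii") {
      # LAI chosen so N% x LAI = alpha exp(beta NDRE) holds exactly at the
      # true (noiseless) NDRE of every plot
      x <- invert_model_i(base, config$model_i_coeffs)
      ab <- config$model_ii_coeffs
      lai <- ab[["alpha"]] * exp(ab[["beta"]] * x) / base
      dimnames(lai) <- dimnames(base)
    }
    out <- data.frame(
      variety = rep(seq_len(n), each = 6),
      stage = stage_factor(rep(RICE_STAGES, n)),
      n_pct = as.vector(t(base)),
      lai = as.vector(t(lai)),
      gd_days = rep(gd, each = 6),
      high_nue = rep(seq_len(n) %in% hi, each = 6))
    out
  })
}

trajectory_n_pct <- function(trajectory, stage) {
  if (is.data.frame(trajectory)) {
    i <- match(stage, as.character(trajectory$stage))
    if (is.na(i)) stop("stage ", stage, " absent from trajectory")
    trajectory$n_pct[i]
  } else {
    # named 6-vector in stage order
    trajectory[[stage]]
  }
}

#' Canopy reflectance vector implied by a nitrogen level
#'
#' Maps the stage's true N% through the inverse of the quadratic NDRE model
#' to an NDRE value, anchors the 800 nm band at `canopy_nir`, sets the
#' 720 nm band so that the pair reproduces that NDRE, and fills the remaining
#' bands from a smooth green-canopy spectral shape. At tillering stage the
#' result is the convex mixture
#' `water_fraction_ts * water + (1 - water_fraction_ts) * canopy`, emulating
#' the uncovered water background that biases early-season NDRE. Per-band
#' Gaussian reflectance noise is added from the current RNG state.
#'
#' @param trajectory one variety's rows of [generate_trajectories()] (or a
#'   named 6-vector of N% by stage).
#' @param stage one of the six stage codes.
#' @param config a [synth_config()].
#' @return Named per-band reflectance vector (`b490` ... `b950`).
#' @export
generate_plot_reflectance <- function(trajectory, stage, config) {
  stage <- check_stage(stage)[1]
  n_pct <- trajectory_n_pct(trajectory, stage)
  x <- invert_model_i(n_pct, config$model_i_coeffs)
  rho800 <- config$canopy_nir
  rho720 <- rho800 * (1 - x) / (1 + x)
  canopy <- stats::setNames(numeric(12), band_names(config$band_centers))
  canopy[names(CANOPY_SHAPE_VIS)] <- CANOPY_SHAPE_VIS * rho720
  canopy["b720"] <- rho720
  canopy["b800"] <- rho800
  canopy[names(CANOPY_SHAPE_NIR)] <- CANOPY_SHAPE_NIR * rho800
  rho <- canopy
  if (stage == "TS" && config$water_fraction_ts > 0) {
    f <- config$water_fraction_ts
    rho <- f * config$water_reflectance[names(canopy)] + (1 - f) * canopy
  }
  if (config$reflectance_noise_sd > 0) {
    rho <- rho + stats::rnorm(length(rho), 0, config$reflectance_noise_sd)
  }
  rho
}

scene_layout <- function(config, stage) {
  ps <- config$plot_size_px; gap <- config$plot_gap_px
  pan <- config$panel_size_px
  rows <- config$plot_grid[1]; cols <- config$plot_grid[2]
  strip <- pan + gap
  panel <- data.frame(
    role = "panel", id = paste0("panel_", seq_along(PANEL_REFLECTANCES)),
    variety = NA_integer_, stage = stage,
    reflectance = PANEL_REFLECTANCES,
    row0 = 0L, row1 = pan,
    col0 = (seq_along(PANEL_REFLECTANCES) - 1L) * (pan + gap),
    col1 = (seq_along(PANEL_REFLECTANCES) - 1L) * (pan + gap) + pan)
  v <- seq_len(config$n_varieties)
  r <- (v - 1L) %/% cols; cl <- (v - 1L) %% cols
  plots <- data.frame(
    role = "plot", id = paste0("plot_", v), variety = v, stage = stage,
    reflectance = NA_real_,
    row0 = strip + r * (ps + gap), row1 = strip + r * (ps + gap) + ps,
    col0 = cl * (ps + gap), col1 = cl * (ps + gap) + ps)
  layout <- rbind(panel, plots)
  nrow_px <- strip + rows * (ps + gap)
  ncol_px <- max(max(layout$col1), cols * (ps + gap))
  attr(layout, "dim_px") <- c(nrow_px, ncol_px)
  layout
}

#' Render one growth stage as a raw DN raster plus its layout
#'
#' Builds a 12-band digital-number raster containing the plot grid and the
#' six calibration panels (reflectances 0.03, 0.12, 0.24, 0.36, 0.56, 0.80),
#' applying the inverse sensor model `DN = (rho - offset)/gain` plus DN pixel
#' noise. Deterministic given `(config, stage)`.
#'
#' @param config a [synth_config()].
#' @param stage one of the six stage codes.
#' @param trajectories optional output of [generate_trajectories()]; if
#'   omitted it is regenerated from `config`.
#' @return A list with `stack` (a DN [band_stack()]) and `layout` (a data
#'   frame of half-open, 0-based pixel rectangles with columns `role`, `id`,
#'   `variety`, `stage`, `reflectance`, `row0`, `row1`, `col0`, `col1`).
#' @export
generate_scene <- function(config, stage, trajectories = NULL) {
  stopifnot(inherits(config, "synth_config"))
  stage <- check_stage(stage)[1]
  if (is.null(trajectories)) trajectories <- generate_trajectories(config)
  layout <- scene_layout(config, stage)
  dims <- attr(layout, "dim_px")
  stage_i <- match(stage, RICE_STAGES)
  withr::with_seed(config$seed + 1000L + stage_i, {
    nb <- length(config$band_centers)
    refl <- array(config$background_reflectance, c(dims[1], dims[2], nb))
    for (i in seq_len(nrow(layout))) {
      rect <- layout[i, ]
      rho <- if (rect$role == "panel") {
        rep(rect$reflectance, nb)
      } else {
        generate_plot_reflectance(
          trajectories[trajectories$variety == rect$variety, ], stage, config)
      }
      rr <- (rect$row0 + 1L):rect$row1
      cc <- (rect$col0 + 1L):rect$col1
      for (b in seq_len(nb)) refl[rr, cc, b] <- rho[b]
    }
    dn <- sweep(sweep(refl, 3, config$true_offset, "-"),
                3, config$true_gain, "/")
    if (config$dn_noise_sd > 0) {
      dn <- dn + array(stats::rnorm(length(dn), 0, config$dn_noise_sd), dim(dn))
    }
    if (config$quantize) dn <- pmin(pmax(round(dn), 0), 1023)
    list(stack = band_stack(dn, config$band_centers, "DN"), layout = layout)
  })
}

#' Simulate per-variety per-stage ground measurements
#'
#' Adds instrument readings to the true trajectories: `n_eqa` (elementary
#' quantitative analysis, the chemical reference) as true N% plus small
#' Gaussian noise; `spad` as an affine map of N% plus noise; `n_npen` as
#' noisy N% saturated below the meter's floor (readings cluster at
#' `npen_floor` when true N% is lower); `la_s` back-computed from LAI and
#' plant density so that `LAI = la_s * d` holds exactly.
#'
#' @param trajectories output of [generate_trajectories()].
#' @param config a [synth_config()].
#' @return `trajectories` augmented with `n_eqa`, `spad`, `n_npen`, `la_s`
#'   columns (plus the carried-through `lai`).
#' @export
generate_ground_measurements <- function(trajectories, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(trajectories)
  withr::with_seed(config$seed + 2L, {
    out <- trajectories
    out$n_eqa <- pmax(out$n_pct + stats::rnorm(n, 0, config$eqa_noise_sd), 0)
    out$spad <- config$spad_coef[["a"]] * out$n_pct + config$spad_coef[["b"]] +
      stats::rnorm(n, 0, config$spad_noise_sd)
    out$n_npen <- pmax(out$n_pct + stats::rnorm(n, 0, config$npen_noise_sd),
                       config$npen_floor)
    out$la_s <- out$lai / config$plant_density
    out
  })
}

#' Noise standard deviation that targets a given R-squared
#'
#' For additive Gaussian noise on a signal, `Var(noise) =
#' Var(signal) * (1 - R2) / R2` makes the population coefficient of
#' determination equal `R2`.
#'
#' @param signal numeric vector of noiseless responses.
#' @param r2 target coefficient of determination in (0, 1].
#' @return The noise standard deviation.
#' @export
noise_sd_for_r2 <- function(signal, r2) {
  stopifnot(r2 > 0, r2 <= 1)
  sqrt(stats::var(signal) * (1 - r2) / r2)
}

default_dosage_spec <- function() {
  treatments <- c(0, 120, 180, 240)
  list(
    treatments = treatments,
    n_per_group = 30L,
    varieties = c("HNUE", "CK"),
    # per-treatment group means; the high-NUE variety out-yields the check at
    # every dosage, with the widest gap at zero nitrogen
    gyp_mean = list(HNUE = c(38.5, 45.0, 47.0, 48.0),
                    CK   = c(20.6, 33.0, 40.0, 44.0)),
    epn_mean = list(HNUE = c(10.3, 12.0, 13.0, 13.5),
                    CK   = c(9.2, 11.5, 12.8, 13.4)),
    gnp_mean = list(HNUE = rep(140.6, 4), CK = rep(120.0, 4)),
    ssr_mean = list(HNUE = rep(92.1, 4), CK = rep(56.3, 4)),
    pl_mean  = list(HNUE = rep(20.8, 4), CK = rep(20.2, 4)),
    gyp_sd = 3.0, epn_sd = 0.8, gnp_sd = 8.0, ssr_sd = 3.0, pl_sd = 0.3)
}

#' Simulate the nitrogen dosage yield trial
#'
#' Generates per-plant yield components for two varieties (a high-NUE line
#' and a check) under the four nitrogen treatments 0, 120, 180 and 240
#' kg/ha. Group means are configured on the agronomic scale (grain yield per
#' plant, effective panicle number, grains per panicle, seed setting rate,
#' panicle length); grain counts and the 200-grain weight are derived so the
#' configured means are reproduced exactly at zero noise.
#'
#' @param config a [synth_config()]; its `dosage` list overrides entries of
#'   the default trial specification.
#' @return A data frame with one row per plant: `variety`, `treatment`
#'   (kg N/ha), `plant`, `epn`, `pl`, `gnp`, `full_grains`, `total_grains`,
#'   `weight_200`, `gyp`.
#' @export
generate_dosage_trial <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  spec <- utils::modifyList(default_dosage_spec(), config$dosage)
  if (spec$n_per_group < 2) stop("replicates < 2: t-test undefined")
  withr::with_seed(config$seed + 3L, {
    rows <- list()
    for (v in spec$varieties) {
      for (ti in seq_along(spec$treatments)) {
        n <- spec$n_per_group
        epn <- pmax(spec$epn_mean[[v]][ti] + stats::rnorm(n, 0, spec$epn_sd), 1)
        gnp <- pmax(spec$gnp_mean[[v]][ti] + stats::rnorm(n, 0, spec$gnp_sd), 10)
        ssr <- pmin(pmax(spec$ssr_mean[[v]][ti] +
                           stats::rnorm(n, 0, spec$ssr_sd), 5), 100)
        gyp <- pmax(spec$gyp_mean[[v]][ti] + stats::rnorm(n, 0, spec$gyp_sd), 1)
        pl <- pmax(spec$pl_mean[[v]][ti] + stats::rnorm(n, 0, spec$pl_sd), 5)
        full <- epn * gnp
        total <- full / (ssr / 100)
        weight_200 <- 200 * gyp / full
        rows[[length(rows) + 1]] <- data.frame(
          variety = v, treatment = spec$treatments[ti], plant = seq_len(n),
          epn = epn, pl = pl, gnp = gnp, full_grains = full,
          total_grains = total, weight_200 = weight_200, gyp = gyp)
      }
    }
    do.call(rbind, rows)
  })
}
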