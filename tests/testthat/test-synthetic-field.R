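test_that("config validation rejects impossible field setups", {
  expect_error(synth_config(n_varieties = 1), "cannot form a collection")
  expect_error(synth_config(high_nue_indices = 99), "high_nue_indices")
  expect_error(synth_config(water_fraction_ts = 1.5), "water_fraction_ts")
  expect_error(synth_config(dn_noise_sd = -1), "standard deviations")
  expect_error(synth_config(band_centers = c(490, 800)), "12 camera centers")
  expect_error(synth_config(n_varieties = 60, plot_grid = c(5, 5)),
               "cannot hold")
})

test_that("trajectory generation is deterministic and plants the high-NUE shape", {
  cfg <- synth_config(n_varieties = 20, seed = 7, high_nue_indices = 1)
  t1 <- generate_trajectories(cfg)
  t2 <- generate_trajectories(cfg)
  expect_identical(t1, t2)

  wide <- matrix(t1$n_pct, ncol = 6, byrow = TRUE,
                 dimnames = list(NULL, RICE_STAGES))
  # top-ranked reproductive nitrogen for the planted variety
  expect_equal(which.max(wide[, "FHS"]), 1)
  expect_equal(which.max(wide[, "MRS"]), 1)
  # vegetative values are inner (non-maximal) at every pre-heading stage
  for (s in c("TS", "JS", "PIS", "BS")) {
    pct <- 100 * mean(wide[, s] <= wide[1, s])
    expect_gt(pct, 40); expect_lt(pct, 95)
  }
  # post-booting decline slower than the collection median
  declines <- (wide[, "BS"] - wide[, "MRS"]) / 2
  expect_lt(declines[1], median(declines[-1]))
  # planted labels recorded
  expect_true(all(t1$high_nue[t1$variety == 1]))
  expect_false(any(t1$high_nue[t1$variety != 1]))
})

test_that("baseline trajectory templates decline after booting", {
  cfg <- synth_config()
  for (tmpl in cfg$baseline_templates) {
    expect_true(all(diff(tmpl[4:6]) < 0))
  }
})

test_that("quadratic model inversion covers exactly the admissible N% interval", {
  cf <- c(a = 5.75, b = 8.17, c = 0.58)
  expect_equal(invert_model_i(0.58, cf), 0)
  expect_equal(invert_model_i(6.9584, cf), 0.56, tolerance = 1e-12)
  expect_error(invert_model_i(0.5, cf), "invertible range")
  expect_error(invert_model_i(5.75 + 8.17 + 0.58, cf), "invertible range")
  # round trip over a grid
  y <- seq(0.6, 14, length.out = 50)
  x <- invert_model_i(y, cf)
  expect_equal(cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]], y, tolerance = 1e-10)
})

test_that("plot reflectance encodes the Model-I NDRE of the true nitrogen", {
  cfg <- zero_noise_config(water_fraction_ts = 0)
  traj <- c(TS = 0.58, JS = 6.9584, PIS = 3, BS = 2.5, FHS = 1.8, MRS = 1.2)
  ndre_of <- function(rho) (rho[["b800"]] - rho[["b720"]]) /
    (rho[["b800"]] + rho[["b720"]])
  expect_equal(ndre_of(generate_plot_reflectance(traj, "TS", cfg)), 0,
               tolerance = 1e-12)
  expect_equal(ndre_of(generate_plot_reflectance(traj, "JS", cfg)), 0.56,
               tolerance = 1e-12)
})

test_that("water mixing pulls tillering plots off the Model-I curve", {
  traj <- c(TS = 3.2, JS = 3, PIS = 2.8, BS = 2.5, FHS = 1.8, MRS = 1.2)
  cf <- c(a = 5.75, b = 8.17, c = 0.58)
  residual_at <- function(f) {
    cfg <- zero_noise_config(water_fraction_ts = f)
    rho <- generate_plot_reflectance(traj, "TS", cfg)
    ndre <- (rho[["b800"]] - rho[["b720"]]) / (rho[["b800"]] + rho[["b720"]])
    abs(cf[["a"]] * ndre^2 + cf[["b"]] * ndre + cf[["c"]] - traj[["TS"]])
  }
  expect_lt(residual_at(0), 1e-10)
  # brute force over a fraction grid: contamination grows monotonically
  res <- vapply(c(0.1, 0.2, 0.4, 0.6), residual_at, numeric(1))
  expect_gt(res[3], residual_at(0))
  expect_true(all(diff(res) > 0))
  # componentwise convex-hull bound of the mixture
  cfg4 <- zero_noise_config(water_fraction_ts = 0.4)
  cfg0 <- zero_noise_config(water_fraction_ts = 0)
  mixed <- generate_plot_reflectance(traj, "TS", cfg4)
  canopy <- generate_plot_reflectance(traj, "TS", cfg0)
  water <- cfg4$water_reflectance
  expect_true(all(mixed >= pmin(canopy, water) - 1e-12 &
                  mixed <= pmax(canopy, water) + 1e-12))
})

test_that("scenes embed recoverable panels and obey the sensor model", {
  cfg <- zero_noise_config(n_varieties = 6, seed = 5)
  sc <- generate_scene(cfg, "JS")
  expect_s3_class(sc$stack, "band_stack")
  expect_identical(sc$stack$value_kind, "DN")
  panels <- extract_panel_dns(sc$stack, sc$layout)
  # applying the true sensor coefficients to panel DN means recovers the
  # nominal reflectances exactly at zero noise
  for (b in seq_along(cfg$band_centers)) {
    rho <- panels$dn[, b] * cfg$true_gain[b] + cfg$true_offset[b]
    expect_equal(unname(rho), PANEL_REFLECTANCES, tolerance = 1e-10)
  }
  # identity sensor: DN equals reflectance
  cfg_id <- zero_noise_config(n_varieties = 6, seed = 5,
                              true_gain = 1, true_offset = 0)
  sc_id <- generate_scene(cfg_id, "JS")
  p_id <- extract_panel_dns(sc_id$stack, sc_id$layout)
  expect_equal(unname(p_id$dn[, 1]), PANEL_REFLECTANCES, tolerance = 1e-10)
  # determinism: identical rasters across runs
  sc2 <- generate_scene(cfg, "JS")
  expect_identical(sc$stack$values, sc2$stack$values)
  expect_identical(sc$layout, sc2$layout)
})

test_that("zero-noise sensor round trip is the identity", {
  cfg <- zero_noise_config(n_varieties = 6, seed = 9)
  traj <- generate_trajectories(cfg)
  sc <- generate_scene(cfg, "BS", traj)
  model <- fit_empirical_line(extract_panel_dns(sc$stack, sc$layout))
  refl <- apply_calibration(sc$stack, model)
  plots <- sc$layout[sc$layout$role == "plot", ]
  for (i in c(1, 4)) {
    got <- aggregate_plot(refl, plots[i, ])
    want <- generate_plot_reflectance(traj[traj$variety == plots$variety[i], ],
                                      "BS", cfg)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("ground measurements apply the N-pen floor and exact affine SPAD", {
  cfg <- zero_noise_config(n_varieties = 8, seed = 2)
  traj <- generate_trajectories(cfg)
  g <- generate_ground_measurements(traj, cfg)
  expect_equal(g$n_eqa, g$n_pct)
  # meter reads the floor whenever true N% is below it, the value otherwise
  expect_equal(g$n_npen, pmax(g$n_pct, cfg$npen_floor))
  expect_true(any(g$n_pct < 2) && all(g$n_npen[g$n_pct < 2] == 2.0))
  # zero noise: SPAD is exactly affine in N%, so r = 1
  expect_equal(pearson_r(g$spad, g$n_eqa), 1, tolerance = 1e-12)
  # LAI = LA_S * d holds by construction
  expect_equal(g$la_s * cfg$plant_density, g$lai, tolerance = 1e-12)
})

test_that("noise calibrated from the signal variance lands near the target R2", {
  sig <- 5.75 * seq(0.15, 0.62, length.out = 100)^2 + 1
  sd0 <- noise_sd_for_r2(sig, 0.7)
  expect_equal(sd0^2, var(sig) * 0.3 / 0.7, tolerance = 1e-12)
  r2s <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      y <- sig + rnorm(length(sig), 0, sd0)
      x <- seq(0.15, 0.62, length.out = 100)
      fit_model_i(x, y)$summary$r_squared
    })
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.7), 0.05)
})

test_that("dosage trial reproduces configured group means and is deterministic", {
  cfg0 <- synth_config(seed = 4, dosage = list(
    gyp_sd = 0, epn_sd = 0, gnp_sd = 0, ssr_sd = 0, pl_sd = 0))
  d0 <- generate_dosage_trial(cfg0)
  n0 <- d0[d0$treatment == 0, ]
  expect_equal(mean(n0$gyp[n0$variety == "HNUE"]), 38.5)
  expect_equal(mean(n0$gyp[n0$variety == "CK"]), 20.6)
  # high-NUE line out-yields the check at every treatment
  for (tr in unique(d0$treatment)) {
    sub <- d0[d0$treatment == tr, ]
    expect_gt(mean(sub$gyp[sub$variety == "HNUE"]),
              mean(sub$gyp[sub$variety == "CK"]))
  }
  # identical group configurations at zero noise -> t = 0
  tt <- two_sample_t(n0$gyp[n0$variety == "HNUE"] * 0 + 5,
                     n0$gyp[n0$variety == "CK"] * 0 + 5)
  expect_equal(tt$t, 0)
  cfg <- synth_config(seed = 4)
  expect_identical(generate_dosage_trial(cfg), generate_dosage_trial(cfg))
  expect_error(generate_dosage_trial(synth_config(dosage = list(n_per_group = 1))),
               "t-test undefined")
})
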