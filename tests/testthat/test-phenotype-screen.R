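test_that("stage series carry per-stage ranks with min-tie sharing", {
  recs <- series_records(list(
    a = c(3.0, 2.8, 2.6, 2.4, 2.2, 2.0),
    b = c(3.2, 3.0, 2.8, 2.6, 1.8, 1.4),
    c = c(2.8, 2.6, 2.4, 2.2, 1.6, 1.2)))
  s <- build_stage_series(recs, "n")
  fhs <- s[s$stage == "FHS", ]
  expect_equal(fhs$rank[order(fhs$variety)], c(1, 2, 3))
  # ties share the minimum rank
  recs2 <- series_records(list(a = rep(2, 6), b = rep(2, 6), c = c(rep(2, 5), 1)))
  s2 <- build_stage_series(recs2, "n")
  expect_equal(s2$rank[s2$stage == "TS"], c(1, 1, 1))
  expect_equal(sort(s2$rank[s2$stage == "MRS"]), c(1, 1, 3))
  # duplicate observations are an error, missing stages are explicit NAs
  expect_error(build_stage_series(rbind(recs, recs[1, ]), "n"), "duplicate")
  s3 <- build_stage_series(recs[-1, ], "n")
  expect_true(is.na(s3$value[s3$variety == "a" & s3$stage == "TS"]))
  expect_equal(nrow(s3), 18)
})

test_that("ranks at each stage are a permutation with ties of 1..n", {
  cfg <- synth_config(n_varieties = 15, seed = 31)
  g <- generate_ground_measurements(generate_trajectories(cfg), cfg)
  s <- build_stage_series(g, "n_eqa")
  for (st in RICE_STAGES) {
    r <- sort(s$rank[s$stage == st])
    expect_equal(r, as.numeric(rank(r, ties.method = "min")))
    expect_equal(min(r), 1)
    expect_lte(max(r), 15)
  }
})

test_that("decline rate is the mean per-stage drop from booting to ripening", {
  expect_equal(decline_rate(c(BS = 2.9, MRS = 2.2)), 0.35)
  expect_equal(decline_rate(c(BS = 2, MRS = 2)), 0)
  expect_equal(decline_rate(c(BS = 1.8, MRS = 2.2)), -0.2)  # still rising
  df <- data.frame(stage = RICE_STAGES, value = c(3, 2.9, 2.8, 2.6, 2.4, 2.0))
  expect_equal(decline_rate(df), 0.3)
  expect_error(decline_rate(c(BS = 2)), "MRS missing")
})

test_that("classifier recovers exactly the planted variety at zero noise", {
  cfg <- zero_noise_config(n_varieties = 51, seed = 17, high_nue_indices = 2)
  g <- generate_ground_measurements(generate_trajectories(cfg), cfg)
  s <- build_stage_series(g, "n_eqa")
  out <- classify_high_nue(s)
  expect_equal(out$variety[out$flagged], 2)
  expect_equal(out$rank_fhs[out$variety == 2], 1)
  expect_equal(out$rank_mrs[out$variety == 2], 1)
  # brute-force check of all three clauses for the flagged variety
  wide <- matrix(g$n_pct, ncol = 6, byrow = TRUE,
                 dimnames = list(NULL, RICE_STAGES))
  expect_equal(unname(which.max(wide[, "FHS"])), 2)
  pct <- vapply(c("TS", "JS", "PIS", "BS"),
                function(st) 100 * mean(wide[, st] <= wide[2, st]), numeric(1))
  expect_true(all(pct >= 40 & pct <= 95))
  dec <- (wide[, "BS"] - wide[, "MRS"]) / 2
  expect_lte(dec[2], quantile(dec, 0.5, names = FALSE))
})

test_that("a variety maximal at every stage fails the vegetative band", {
  base <- list(a = c(3.0, 2.8, 2.6, 2.4, 2.2, 2.0),
               b = c(2.9, 2.7, 2.5, 2.3, 2.1, 1.9),
               c = c(2.8, 2.6, 2.4, 2.2, 2.0, 1.8),
               d = c(2.7, 2.5, 2.3, 2.1, 1.9, 1.7),
               e = c(2.6, 2.4, 2.2, 2.0, 1.8, 1.6))
  base$top <- c(4, 3.9, 3.8, 3.7, 3.6, 3.55)   # early peak AND reproductive max
  s <- build_stage_series(series_records(base), "n")
  out <- classify_high_nue(s)
  expect_false(out$flagged[out$variety == "top"])
  expect_true(out$clause_reproductive[out$variety == "top"])
  expect_false(out$clause_vegetative[out$variety == "top"])
})

test_that("a vacuous rule flags every complete variety", {
  cfg <- synth_config(n_varieties = 8, seed = 23)
  g <- generate_ground_measurements(generate_trajectories(cfg), cfg)
  s <- build_stage_series(g, "n_eqa")
  lax <- phenotype_rule(reproductive_rank_max = 8,
                        vegetative_band = c(0, 100),
                        decline_quantile_max = 1)
  expect_true(all(classify_high_nue(s, lax)$flagged))
})

test_that("relaxing any rule threshold never un-flags a variety", {
  cfg <- synth_config(n_varieties = 20, seed = 41)
  g <- generate_ground_measurements(generate_trajectories(cfg), cfg)
  s <- build_stage_series(g, "n_eqa")
  base_rule <- phenotype_rule(reproductive_rank_max = 3,
                              vegetative_band = c(40, 90),
                              decline_quantile_max = 0.5)
  flagged0 <- classify_high_nue(s, base_rule)$flagged
  laxer <- list(
    phenotype_rule(6, c(40, 90), 0.5),
    phenotype_rule(3, c(20, 100), 0.5),
    phenotype_rule(3, c(40, 90), 0.9))
  for (r in laxer) {
    expect_true(all(classify_high_nue(s, r)$flagged >= flagged0))
  }
})

test_that("incomplete varieties are excluded with a warning, never flagged", {
  cfg <- zero_noise_config(n_varieties = 8, seed = 29, high_nue_indices = 1)
  g <- generate_ground_measurements(generate_trajectories(cfg), cfg)
  g <- g[!(g$variety == 3 & g$stage == "BS"), ]
  s <- build_stage_series(g, "n_eqa")
  expect_warning(out <- classify_high_nue(s), "excluded.*3")
  expect_true(out$excluded[out$variety == 3])
  expect_false(out$flagged[out$variety == 3])
  expect_equal(out$variety[out$flagged], 1)
  expect_error(classify_high_nue(s[s$variety <= 4, ]), "at least 5")
})

test_that("field traits implement the yield formulas with units reconciled", {
  # single plant, hand-checkable numbers
  r <- field_traits(epn = 10, full_grains = 90, total_grains = 100,
                    weight_200 = 5.788, treatment = 120,
                    plants_counted = 100, area_m2 = 5,
                    gyp = 20)
  expect_equal(r$ssr, 90)
  expect_equal(r$gnp, 9)
  expect_equal(r$tgw, 28.94)
  expect_equal(r$gy, 4000)
  expect_equal(r$nue, 4000 / 120, tolerance = 1e-12)
  # GYP derived from grain count and grain weight when not measured
  r2 <- field_traits(epn = 10, full_grains = 1000, total_grains = 1100,
                     weight_200 = 6, treatment = 0,
                     plants_counted = 100, area_m2 = 5)
  expect_equal(r2$gyp, 1000 * 6 / 200)
  expect_true(is.na(r2$nue))     # undefined at the zero-nitrogen treatment
  # moisture adjustment is an opt-in multiplicative deduction
  r3 <- field_traits(epn = 10, full_grains = 90, total_grains = 100,
                     weight_200 = 5.788, treatment = 120,
                     plants_counted = 100, area_m2 = 5, gyp = 20,
                     moisture_adjust = TRUE)
  expect_equal(r3$gy, 4000 * 0.865)
  expect_error(field_traits(10, 90, 0, 5, 120, 100, 5), "SSR undefined")
  expect_error(field_traits(10, 90, 100, 5, 120, 100, 0), "area")
})

test_that("field traits are dimensionally consistent", {
  base <- field_traits(epn = 10, full_grains = 90, total_grains = 100,
                       weight_200 = 5, treatment = 120,
                       plants_counted = 100, area_m2 = 5, gyp = 20)
  half <- field_traits(epn = 10, full_grains = 90, total_grains = 100,
                       weight_200 = 5, treatment = 120,
                       plants_counted = 100, area_m2 = 10, gyp = 20)
  dbl <- field_traits(epn = 10, full_grains = 90, total_grains = 100,
                      weight_200 = 5, treatment = 120,
                      plants_counted = 100, area_m2 = 5, gyp = 40)
  expect_equal(half$gy, base$gy / 2)
  expect_equal(dbl$gy, 2 * base$gy)
  expect_equal(dbl$nue, 2 * base$nue)
})

test_that("pooled t-test matches the direct formula, with defined limits", {
  out <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(out$t), 3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  # direct-formula oracle on random instances
  withr::with_seed(77, {
    for (i in 1:10) {
      a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
      out <- two_sample_t(a, b)
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      expect_equal(out$t, t_oracle, tolerance = 1e-10)
      expect_equal(out$p, 2 * pt(-abs(t_oracle), length(a) + length(b) - 2),
                   tolerance = 1e-10)
    }
  })
  expect_equal(two_sample_t(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))
  degen <- two_sample_t(c(3, 3), c(1, 1))
  expect_equal(degen$t, Inf); expect_equal(degen$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  # Welch variant reproduces stats::t.test defaults
  a <- c(1, 2, 3, 9); b <- c(2, 2.5, 3)
  w <- two_sample_t(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
})
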