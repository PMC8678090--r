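# shared fixtures: all synthetic, built in code

zero_noise_config <- function(n_varieties = 12, seed = 3, ...) {
  synth_config(n_varieties = n_varieties, seed = seed,
               reflectance_noise_sd = 0, dn_noise_sd = 0,
               eqa_noise_sd = 0, spad_noise_sd = 0, npen_noise_sd = 0, ...)
}

# independent OLS oracle: closed-form normal equations for rho = gain*dn + off
ols_oracle <- function(x, y, degree = 1) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # c(intercept, x, x^2, ...)
}

# a small uniform band stack with every pixel equal to `dn` per band
uniform_stack <- function(dn, nrow = 4, ncol = 5, kind = "DN") {
  arr <- array(rep(dn, each = nrow * ncol), c(nrow, ncol, length(dn)))
  band_stack(arr, BAND_CENTERS[seq_along(dn)], kind)
}

rect <- function(row0, row1, col0, col1) {
  data.frame(row0 = row0, row1 = row1, col0 = col0, col1 = col1)
}

# long-format records for a deterministic multi-variety stage series
series_records <- function(values_by_variety) {
  do.call(rbind, lapply(names(values_by_variety), function(v) {
    data.frame(variety = v, stage = RICE_STAGES,
               n = values_by_variety[[v]])
  }))
}
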