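#' @rdname fit_model_i
#' @param observed,fitted,n_coef internal: observed and fitted responses and
#'   the number of estimated coefficients (including the intercept/scale).
#' @keywords internal
fit_summary <- function(observed, fitted, n_coef) {
  n <- length(observed)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(observed^2))) 0
        else 1 - ss_res / ss_tot
  k <- n_coef - 1                      # predictors excluding intercept/scale
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_coef)
  f <- (r2 / k) / ((1 - r2) / (n - n_coef))
  p <- if (is.nan(f)) NA_real_ else stats::pf(f, k, n - n_coef, lower.tail = FALSE)
  pr <- if (stats::var(fitted) > 0 && stats::var(observed) > 0) {
    stats::cor(observed, fitted)
  } else NA_real_
  list(n = n, r_squared = r2, adj_r_squared = adj, pearson_r = pr, p_value = p)
}

#' Drop tillering-stage records before model fitting
#'
#' At tillering the canopy does not yet cover the paddy water, whose low
#' reflectance in every band biases NDRE upward; those records are excluded
#' from nitrogen model fitting. Row order is otherwise preserved.
#'
#' @param records data frame with a `stage` column.
#' @return `records` without its TS rows.
#' @export
exclude_tillering <- function(records) {
  check_stage(records$stage)
  out <- records[as.character(records$stage) != "TS", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the quadratic canopy nitrogen model (Model I)
#'
#' Least-squares fit of `N% = a * NDRE^2 + b * NDRE + c`, the
#' estimation model linking plot-level NDRE to chemically measured canopy
#' nitrogen over the five post-tillering stages.
#'
#' @param x NDRE values.
#' @param y canopy nitrogen (% dry mass).
#' @return An object of class `nitrogen_model_i`: coefficients `a`, `b`, `c`
#'   and a fit summary (`n`, pseudo and adjusted R-squared, Pearson r of
#'   observed vs fitted, F-test p-value).
#' @export
fit_model_i <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 4) stop("need at least 4 points to fit the quadratic")
  if (length(unique(x)) < 3) {
    stop("rank-deficient design: fewer than 3 distinct NDRE values")
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  coefs <- c(a = unname(cf[["I(x^2)"]]), b = unname(cf[["x"]]),
             c = unname(cf[["(Intercept)"]]))
  structure(list(coefficients = coefs,
                 summary = fit_summary(y, stats::fitted(fit), 3L)),
            class = "nitrogen_model_i")
}

#' @rdname fit_model_i
#' @param object a fitted `nitrogen_model_i`.
#' @param x NDRE values at which to predict.
#' @param ... unused.
#' @return `predict()` returns estimated N% (vectorized).
#' @export
predict.nitrogen_model_i <- function(object, x, ...) {
  cf <- object$coefficients
  cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]]
}

#' @export
print.nitrogen_model_i <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Model I: N%% = %.4g NDRE^2 + %.4g NDRE + %.4g  (n = %d, R2 = %.3f)\n",
              cf[["a"]], cf[["b"]], cf[["c"]], x$summary$n, x$summary$r_squared))
  invisible(x)
}

#' Fit the exponential canopy nitrogen model (Model II)
#'
#' Nonlinear least squares on the original scale for
#' `N% x LAI = alpha * exp(beta * NDRE)`, the canopy-structure-aware model.
#' The fit is initialized from ordinary least squares on `log(y)` when all
#' responses are positive, otherwise from `start`.
#'
#' @param x NDRE values.
#' @param y canopy nitrogen times leaf area index (N% x LAI).
#' @param start fallback starting values `c(alpha = , beta = )` used when the
#'   log-linear initializer is unavailable (some `y <= 0`).
#' @return An object of class `nitrogen_model_ii`: coefficients `alpha`,
#'   `beta` and a fit summary with pseudo R-squared `1 - SSres/SStot`.
#' @export
fit_model_ii <- function(x, y, start = c(alpha = 1, beta = 1)) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3) stop("need at least 3 points to fit the exponential")
  if (length(unique(x)) < 2) {
    stop("rank-deficient design: all NDRE values identical")
  }
  if (all(y > 0)) {
    ols <- stats::lm(log(y) ~ x)
    start <- c(alpha = exp(unname(stats::coef(ols)[1])),
               beta = unname(stats::coef(ols)[2]))
  } else {
    start <- c(alpha = unname(start[["alpha"]]), beta = unname(start[["beta"]]))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ alpha * exp(beta * x),
                      start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e)))
  ci <- fit$convInfo
  if (!is.null(ci) && !isTRUE(ci$isConv)) {
    stop("exponential fit did not converge after ", ci$finIter,
         " iterations (", ci$stopMessage, ")")
  }
  cf <- stats::coef(fit)
  structure(list(coefficients = c(alpha = unname(cf[["alpha"]]),
                                  beta = unname(cf[["beta"]])),
                 summary = fit_summary(y, stats::fitted(fit), 2L)),
            class = "nitrogen_model_ii")
}

#' @rdname fit_model_ii
#' @param object a fitted `nitrogen_model_ii`.
#' @param ... unused.
#' @return `predict()` returns estimated N% x LAI (vectorized).
#' @export
predict.nitrogen_model_ii <- function(object, x, ...) {
  cf <- object$coefficients
  cf[["alpha"]] * exp(cf[["beta"]] * x)
}

#' @export
print.nitrogen_model_ii <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Model II: N%% x LAI = %.4g exp(%.4g NDRE)  (n = %d, R2 = %.3f)\n",
              cf[["alpha"]], cf[["beta"]], x$summary$n, x$summary$r_squared))
  invisible(x)
}

#' Leaf area index from single-plant leaf area and plant density
#'
#' `LAI = LA_S * d`, with `LA_S` the green leaf area of a representative
#' plant (m^2) and `d` the plant density (plants per m^2).
#'
#' @param la_s single-plant leaf area (m^2), `>= 0`.
#' @param d plant density (plants/m^2), `> 0`.
#' @return LAI (unitless).
#' @export
lai_from_leaf_area <- function(la_s, d) {
  if (any(la_s < 0)) stop("leaf area must be >= 0")
  if (any(d <= 0)) stop("plant density must be > 0")
  la_s * d
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}

#' Simple linear regression with fit summary
#'
#' @param x,y numeric vectors (n >= 3, x not all identical).
#' @return List with `slope`, `intercept` and `summary` (as in
#'   [fit_model_i()]).
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2) stop("degenerate design: x values all identical")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       summary = fit_summary(y, stats::fitted(fit), 2L))
}

#' Split varieties into early- and late-maturation groups
#'
#' Growth duration (days from transplanting to maturation) at or above the
#' cutoff assigns a variety to the late-maturation (LM) group, below it to
#' early maturation (EM). The 100-day default separates middle-season rice
#' from early/late-season rice.
#'
#' @param varieties data frame with `variety` and `gd_days` columns.
#' @param cutoff_days maturity cutoff in days.
#' @return List with elements `EM` and `LM`, each a subset of `varieties`
#'   with a `maturity_group` column added; the partition is exhaustive and
#'   disjoint.
#' @export
split_by_gd <- function(varieties, cutoff_days = 100) {
  gd <- varieties$gd_days
  if (is.null(gd) || anyNA(gd)) {
    missing <- if (is.null(gd)) varieties$variety else varieties$variety[is.na(gd)]
    stop("growth duration missing for varieties: ",
         paste(missing, collapse = ", "))
  }
  varieties$maturity_group <- ifelse(gd >= cutoff_days, "LM", "EM")
  list(EM = varieties[varieties$maturity_group == "EM", , drop = FALSE],
       LM = varieties[varieties$maturity_group == "LM", , drop = FALSE])
}

#' Stage-wise Pearson correlation table
#'
#' Computes one correlation per growth stage per measure pair (the layout of
#' the stage-by-instrument correlation tables), using all varieties with
#' complete values in that cell. Cells with fewer than 3 complete pairs or
#' zero variance are flagged rather than dropped.
#'
#' @param records data frame with `stage` and the measure columns.
#' @param pairs list of length-2 character vectors naming measure columns.
#' @return Data frame with `stage`, `measure_x`, `measure_y`, `n`, `r`, `p`,
#'   `flag` (`""` or `"insufficient_n"`).
#' @export
stage_correlation_table <- function(records, pairs) {
  check_stage(records$stage)
  stages <- intersect(RICE_STAGES, unique(as.character(records$stage)))
  rows <- list()
  for (s in stages) {
    sub <- records[as.character(records$stage) == s, , drop = FALSE]
    for (pr in pairs) {
      stopifnot(length(pr) == 2)
      if (!all(pr %in% names(records))) {
        stop("measure column(s) not found: ",
             paste(setdiff(pr, names(records)), collapse = ", "))
      }
      xy <- sub[, pr]
      ok <- stats::complete.cases(xy)
      x <- xy[ok, 1]; y <- xy[ok, 2]
      if (sum(ok) < 3 || stats::var(x) == 0 || stats::var(y) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          stage = s, measure_x = pr[1], measure_y = pr[2], n = sum(ok),
          r = NA_real_, p = NA_real_, flag = "insufficient_n")
      } else {
        ct <- stats::cor.test(x, y)
        rows[[length(rows) + 1]] <- data.frame(
          stage = s, measure_x = pr[1], measure_y = pr[2], n = sum(ok),
          r = unname(ct$estimate), p = ct$p.value, flag = "")
      }
    }
  }
  do.call(rbind, rows)
}
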