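#' Multiband raster container
#'
#' A minimal in-memory container for a 12-band image: a numeric array
#' `[rows, cols, bands]` in row-major pixel convention (0-based rectangles,
#' half-open), band-center wavelengths, and whether values are raw digital
#' numbers (DN) or surface reflectance.
#'
#' @param values numeric array `[rows, cols, bands]` (a matrix is promoted to
#'   one band).
#' @param band_centers strictly increasing wavelengths in nm, one per band.
#' @param value_kind `"DN"` or `"reflectance"`.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(values, band_centers, value_kind = c("DN", "reflectance")) {
  value_kind <- match.arg(value_kind)
  band_centers <- as.numeric(band_centers)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  if (dim(values)[3] != length(band_centers)) {
    stop("band count mismatch: ", dim(values)[3], " planes vs ",
         length(band_centers), " band centers")
  }
  if (is.unsorted(band_centers, strictly = TRUE)) {
    stop("band_centers must be strictly increasing")
  }
  dimnames(values) <- list(NULL, NULL, band_names(band_centers))
  structure(list(values = values, band_centers = band_centers,
                 value_kind = value_kind),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_stack> %d x %d px, %d bands (%s), values: %s\n",
              d[1], d[2], d[3],
              paste(x$band_centers, collapse = "/"), x$value_kind))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$values)

# half-open 0-based rectangle -> 1-based index ranges, with bounds checks
rect_indices <- function(rect, dims, what = "rectangle") {
  r0 <- rect[["row0"]]; r1 <- rect[["row1"]]
  c0 <- rect[["col0"]]; c1 <- rect[["col1"]]
  if (r1 <= r0 || c1 <= c0) stop(what, " is empty")
  if (r0 < 0 || c0 < 0 || r1 > dims[1] || c1 > dims[2]) {
    stop(what, " out of raster bounds")
  }
  list(rows = (r0 + 1L):r1, cols = (c0 + 1L):c1)
}

#' Construct a calibration panel set
#'
#' @param reflectance known panel reflectances (in (0, 1]).
#' @param dn matrix of mean DN, one row per panel, one column per band.
#' @param band_centers band wavelengths (nm).
#' @return An object of class `calibration_panels`.
#' @export
calibration_panels <- function(reflectance, dn, band_centers = BAND_CENTERS) {
  dn <- as.matrix(dn)
  if (length(reflectance) < 2) stop("fewer than 2 calibration panels")
  if (any(reflectance <= 0 | reflectance > 1)) {
    stop("panel reflectances must lie in (0, 1]")
  }
  if (anyDuplicated(reflectance)) stop("panel reflectances must be distinct")
  stopifnot(nrow(dn) == length(reflectance), ncol(dn) == length(band_centers))
  colnames(dn) <- band_names(band_centers)
  structure(list(reflectance = as.numeric(reflectance), dn = dn,
                 band_centers = band_centers),
            class = "calibration_panels")
}

#' Extract mean panel DN values from a scene
#'
#' Averages the interior pixels of every `role == "panel"` rectangle in the
#' layout, per band. Rectangles are 0-based and half-open.
#'
#' @param stack a DN [band_stack()].
#' @param layout a layout data frame as produced by [generate_scene()] (rows
#'   with `role`, `reflectance`, `row0`, `row1`, `col0`, `col1`).
#' @return A [calibration_panels()] object.
#' @export
extract_panel_dns <- function(stack, layout) {
  stopifnot(inherits(stack, "band_stack"))
  panels <- layout[layout$role == "panel", , drop = FALSE]
  if (nrow(panels) < 2) stop("layout contains fewer than 2 panels")
  dims <- dim(stack$values)
  dn <- t(vapply(seq_len(nrow(panels)), function(i) {
    ix <- rect_indices(panels[i, ], dims, paste0("panel ", panels$id[i]))
    apply(stack$values[ix$rows, ix$cols, , drop = FALSE], 3, mean)
  }, numeric(dims[3])))
  calibration_panels(panels$reflectance, dn, stack$band_centers)
}

#' Fit the per-band empirical-line calibration
#'
#' Ordinary least squares of known panel reflectance on mean panel DN,
#' independently for each band: `rho = DN * gain + offset`. This is the
#' empirical line method: the standard way to convert raw multispectral
#' digital numbers to surface reflectance using ground targets of known,
#' spectrally flat reflectance.
#'
#' @param panels a [calibration_panels()] object.
#' @return An object of class `empirical_line_model` with per-band `gain`,
#'   `offset`, residual `rmse`, and `n_panels`.
#' @export
fit_empirical_line <- function(panels) {
  stopifnot(inherits(panels, "calibration_panels"))
  rho <- panels$reflectance
  nb <- ncol(panels$dn)
  gain <- offset <- rmse <- stats::setNames(numeric(nb), colnames(panels$dn))
  for (b in seq_len(nb)) {
    dn <- panels$dn[, b]
    if (max(dn) - min(dn) < .Machine$double.eps * 100 * max(1, abs(max(dn)))) {
      stop("degenerate calibration: all panel DNs identical in band ",
           colnames(panels$dn)[b])
    }
    fit <- stats::lm(rho ~ dn)
    gain[b] <- stats::coef(fit)[["dn"]]
    offset[b] <- stats::coef(fit)[["(Intercept)"]]
    rmse[b] <- sqrt(mean(stats::residuals(fit)^2))
  }
  structure(list(gain = gain, offset = offset, rmse = rmse,
                 n_panels = length(rho), band_centers = panels$band_centers),
            class = "empirical_line_model")
}

#' @export
print.empirical_line_model <- function(x, ...) {
  cat("<empirical_line_model> ", x$n_panels, " panels\n", sep = "")
  print(data.frame(band = x$band_centers, gain = x$gain, offset = x$offset,
                   rmse = x$rmse, row.names = NULL))
  invisible(x)
}

#' Convert a DN raster to surface reflectance
#'
#' Applies `rho = DN * gain + offset` pixel-wise, per band. No clipping by
#' default, so calibration errors stay visible; `clip = TRUE` bounds the
#' output to `[0, 1.2]`.
#'
#' @param stack a DN [band_stack()].
#' @param model an [fit_empirical_line()] model with matching band count.
#' @param clip clip output reflectance to `[0, 1.2]`?
#' @return A reflectance [band_stack()].
#' @export
apply_calibration <- function(stack, model, clip = FALSE) {
  stopifnot(inherits(stack, "band_stack"),
            inherits(model, "empirical_line_model"))
  if (stack$value_kind != "DN") stop("stack does not hold DN values")
  if (dim(stack$values)[3] != length(model$gain)) {
    stop("band-count mismatch: stack has ", dim(stack$values)[3],
         " bands, model has ", length(model$gain))
  }
  rho <- sweep(sweep(stack$values, 3, model$gain, "*"), 3, model$offset, "+")
  if (clip) rho <- pmin(pmax(rho, 0), 1.2)
  band_stack(rho, stack$band_centers, "reflectance")
}
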