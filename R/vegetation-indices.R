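#' Vegetation index definitions
#'
#' The five indices used for canopy nitrogen estimation, built from the
#' 550, 570, 670, 720 and 800 nm bands:
#' \itemize{
#'   \item NDRE = (rho800 - rho720) / (rho800 + rho720)
#'   \item NDVI = (rho800 - rho670) / (rho800 + rho670)
#'   \item NDGI = (rho800 - rho570) / (rho800 + rho570)
#'   \item CI_rededge = rho800 / rho720 - 1
#'   \item CI_green = rho800 / rho550 - 1
#' }
#' @export
VI_NAMES <- c("NDVI", "NDRE", "CI_rededge", "CI_green", "NDGI")

VI_BANDS <- list(
  NDVI = c(800, 670), NDRE = c(800, 720), NDGI = c(800, 570),
  CI_rededge = c(800, 720), CI_green = c(800, 550))

#' Mean plot reflectance over a layout rectangle
#'
#' Arithmetic mean of the interior pixels per band, using the shared
#' half-open 0-based rectangle convention.
#'
#' @param stack a reflectance [band_stack()].
#' @param rect a one-row data frame (or named vector/list) with `row0`,
#'   `row1`, `col0`, `col1`.
#' @return Named per-band mean reflectance (`b490` ... `b950`).
#' @export
aggregate_plot <- function(stack, rect) {
  stopifnot(inherits(stack, "band_stack"))
  ix <- rect_indices(rect, dim(stack$values), "plot rectangle")
  m <- apply(stack$values[ix$rows, ix$cols, , drop = FALSE], 3, mean)
  stats::setNames(m, band_names(stack$band_centers))
}

# band lookup is by exact nominal center; no nearest-band fallback
get_band <- function(reflectance, center) {
  nm <- paste0("b", center)
  if (!nm %in% names(reflectance)) {
    stop("missing band ", center, " nm (expected element '", nm, "')")
  }
  v <- reflectance[[nm]]
  if (!is.finite(v)) stop("non-finite reflectance in band ", center, " nm")
  v
}

#' Compute one vegetation index from per-band reflectance
#'
#' @param reflectance named per-band reflectance vector (names `b490` ...
#'   `b950`, as returned by [aggregate_plot()]).
#' @param index one of `VI_NAMES`.
#' @return The index value (unitless).
#' @export
compute_vi <- function(reflectance, index) {
  index <- match.arg(index, VI_NAMES)
  bands <- VI_BANDS[[index]]
  num <- get_band(reflectance, bands[1])
  den <- get_band(reflectance, bands[2])
  if (index %in% c("NDVI", "NDRE", "NDGI")) {
    if (num + den == 0) stop("undefined index: zero denominator in ", index)
    (num - den) / (num + den)
  } else {
    if (den == 0) stop("undefined index: zero denominator in ", index)
    num / den - 1
  }
}

#' Long-format vegetation index table
#'
#' One row per (variety, stage, index), computed from plot-mean reflectance
#' (index-of-means, the convention matching a single reported index per
#' plot). Rows are sorted by variety, then phenological stage order, then
#' index name.
#'
#' @param records data frame with `variety`, `stage` and reflectance columns
#'   `b490` ... `b950` (only bands required by the requested indices need be
#'   present).
#' @param indices character vector of indices to compute (subset of
#'   `VI_NAMES`).
#' @return Data frame with columns `variety`, `stage`, `index`, `value`.
#' @export
vi_table <- function(records, indices = VI_NAMES) {
  if (nrow(records) == 0) stop("records is empty")
  if (length(indices) == 0) {
    return(data.frame(variety = records$variety[0], stage = character(0),
                      index = character(0), value = numeric(0)))
  }
  indices <- vapply(indices, match.arg, "", choices = VI_NAMES)
  check_stage(records$stage)
  key <- paste(records$variety, records$stage, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    bcols <- grep("^b[0-9]+$", names(records), value = TRUE)
    for (k in unique(dup)) {
      sub <- records[key == k, bcols, drop = FALSE]
      if (nrow(unique(sub)) > 1) {
        stop("conflicting reflectance for duplicated (variety, stage): ",
             gsub("\r", " / ", k))
      }
    }
    records <- records[!duplicated(key), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(indices, function(ix) {
    vals <- vapply(seq_len(nrow(records)), function(i) {
      compute_vi(unlist(records[i, grep("^b[0-9]+$", names(records))]), ix)
    }, numeric(1))
    data.frame(variety = records$variety, stage = as.character(records$stage),
               index = ix, value = vals)
  }))
  out <- out[order(out$variety, stage_factor(out$stage), out$index), ]
  rownames(out) <- NULL
  out
}
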