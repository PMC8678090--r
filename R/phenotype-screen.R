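#' Assemble per-variety growth-stage nitrogen series with ranks
#'
#' Builds one six-stage trajectory per variety for a chosen nitrogen measure
#' and ranks varieties within each stage (rank 1 = highest value; ties share
#' the minimum rank). Stages absent for a variety appear as `NA`.
#'
#' @param records data frame with `variety`, `stage` and the measure column.
#' @param measure name of the column holding the nitrogen measure (e.g.
#'   `"n_eqa"`, a Model-I `"n_uav"` estimate, or a Model-II `"n_lai_uav"`).
#' @return A data frame of class `stage_series` with one row per variety x
#'   stage: `variety`, `stage`, `value`, `rank`; the measure label is kept in
#'   attribute `"measure"`.
#' @export
build_stage_series <- function(records, measure) {
  if (!measure %in% names(records)) stop("measure column not found: ", measure)
  check_stage(records$stage)
  if (length(unique(records$variety)) < 2) {
    stop("need at least 2 varieties to build a series collection")
  }
  key <- paste(records$variety, records$stage, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (variety, stage) records: ",
         paste(gsub("\r", "/", unique(key[duplicated(key)])), collapse = ", "))
  }
  varieties <- unique(records$variety)
  grid <- expand.grid(stage = RICE_STAGES, variety = varieties,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("variety", "stage")]
  i <- match(paste(grid$variety, grid$stage, sep = "\r"), key)
  grid$value <- records[[measure]][i]
  grid$stage <- stage_factor(grid$stage)
  grid$rank <- stats::ave(grid$value, grid$stage, FUN = function(v) {
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(-v[ok], ties.method = "min")
    r
  })
  grid <- grid[order(grid$variety, grid$stage), ]
  rownames(grid) <- NULL
  structure(grid, measure = measure, class = c("stage_series", "data.frame"))
}

#' Post-booting nitrogen decline rate
#'
#' Mean per-stage drop over the booting -> full heading -> milk ripening
#' interval: `(value(BS) - value(MRS)) / 2`. Larger values mean faster
#' decline; a negative rate (nitrogen still rising) is allowed.
#'
#' @param series one variety's series: a data frame with `stage` and `value`
#'   columns, or a named vector with `BS` and `MRS` elements.
#' @return The decline rate, in measure units per stage step.
#' @export
decline_rate <- function(series) {
  get_val <- function(s) {
    v <- if (is.data.frame(series)) {
      series$value[match(s, as.character(series$stage))]
    } else if (s %in% names(series)) series[[s]] else NULL
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      stop("stage ", s, " missing: decline rate undefined")
    }
    v
  }
  (get_val("BS") - get_val("MRS")) / 2
}

#' Quantitative rule for the high-NUE dynamic phenotype
#'
#' Operationalizes the qualitative phenotype description — moderately high
#' vegetative nitrogen, the collection's highest reproductive nitrogen, and a
#' slow post-booting decline — as three testable clauses.
#'
#' @param reproductive_rank_max maximum allowed rank at both FHS and MRS
#'   (default 1 = top-ranked).
#' @param vegetative_band percentile interval `[lo, hi]` that each of TS, JS,
#'   PIS and BS must fall inside (moderate-high, but not the very top).
#' @param decline_quantile_max quantile of the collection's decline rates the
#'   variety must not exceed (default 0.5 = below the median).
#' @return An object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(reproductive_rank_max = 1,
                           vegetative_band = c(40, 95),
                           decline_quantile_max = 0.5) {
  stopifnot(length(vegetative_band) == 2,
            all(vegetative_band >= 0), all(vegetative_band <= 100),
            vegetative_band[1] <= vegetative_band[2],
            reproductive_rank_max >= 1,
            decline_quantile_max >= 0, decline_quantile_max <= 1)
  structure(list(reproductive_rank_max = reproductive_rank_max,
                 vegetative_band = vegetative_band,
                 decline_quantile_max = decline_quantile_max),
            class = "phenotype_rule")
}

#' Classify varieties against the high-NUE dynamic phenotype
#'
#' A variety is flagged when (i) its rank is at most
#' `reproductive_rank_max` at both FHS and MRS, (ii) each of its TS, JS, PIS
#' and BS values lies within the `vegetative_band` percentiles of that
#' stage's distribution (percentile = 100 x empirical CDF over complete
#' varieties), and (iii) its [decline_rate()] does not exceed the collection
#' quantile `decline_quantile_max`. Varieties with missing stages are
#' excluded with a warning and never flagged silently.
#'
#' @param series a [build_stage_series()] collection (>= 5 varieties).
#' @param rule a [phenotype_rule()].
#' @return Data frame with one row per variety: `variety`, `flagged`,
#'   per-clause diagnostics (`clause_reproductive`, `clause_vegetative`,
#'   `clause_decline`), `rank_fhs`, `rank_mrs`, `decline`, `excluded`.
#' @export
classify_high_nue <- function(series, rule = phenotype_rule()) {
  stopifnot(inherits(series, "stage_series") || is.data.frame(series))
  varieties <- unique(series$variety)
  if (length(varieties) < 5) {
    stop("need at least 5 varieties for percentile-based classification")
  }
  wide <- lapply(varieties, function(v) {
    sub <- series[series$variety == v, ]
    stats::setNames(sub$value[match(RICE_STAGES, as.character(sub$stage))],
                    RICE_STAGES)
  })
  names(wide) <- as.character(varieties)
  complete <- !vapply(wide, anyNA, TRUE)
  if (any(!complete)) {
    warning("excluded (missing stages): ",
            paste(varieties[!complete], collapse = ", "))
  }
  cv <- varieties[complete]
  vals <- do.call(rbind, wide[complete])     # varieties x stages
  declines <- (vals[, "BS"] - vals[, "MRS"]) / 2
  decline_cut <- stats::quantile(declines, rule$decline_quantile_max,
                                 names = FALSE)
  out <- data.frame(variety = varieties, flagged = FALSE,
                    clause_reproductive = NA, clause_vegetative = NA,
                    clause_decline = NA, rank_fhs = NA_real_,
                    rank_mrs = NA_real_, decline = NA_real_,
                    excluded = !complete)
  for (j in seq_along(cv)) {
    v <- cv[j]
    i <- match(v, varieties)
    rank_at <- function(s) {
      series$rank[series$variety == v & as.character(series$stage) == s]
    }
    rf <- rank_at("FHS"); rm_ <- rank_at("MRS")
    c1 <- rf <= rule$reproductive_rank_max && rm_ <= rule$reproductive_rank_max
    pct <- vapply(VEGETATIVE_STAGES, function(s) {
      100 * mean(vals[, s] <= vals[j, s])
    }, numeric(1))
    c2 <- all(pct >= rule$vegetative_band[1] & pct <= rule$vegetative_band[2])
    c3 <- declines[j] <= decline_cut
    out$clause_reproductive[i] <- c1
    out$clause_vegetative[i] <- c2
    out$clause_decline[i] <- c3
    out$rank_fhs[i] <- rf; out$rank_mrs[i] <- rm_
    out$decline[i] <- declines[j]
    out$flagged[i] <- c1 && c2 && c3
  }
  out
}

#' Field yield and nitrogen-use-efficiency traits
#'
#' Aggregates per-plant yield components into the standard trait record:
#' seed setting rate `SSR = 100 * full / total` (%), grains per panicle
#' `GNP = full / EPN`, thousand-grain weight `TGW = 5 * weight_200` (g),
#' grain yield per plant `GYP` (g, total full-grain weight), area-scaled
#' grain yield `GY = GYP * plants / area * 10` (kg/ha; the factor 10 folds
#' the 10,000 m^2/ha scale-up and the g-to-kg conversion), and
#' `NUE = GY / N_applied` (kg grain per kg N), defined only for nonzero
#' nitrogen treatments.
#'
#' @param epn effective panicle number per plant.
#' @param full_grains,total_grains full and total grain counts per plant.
#' @param weight_200 weight of 200 grains (g) per plant.
#' @param treatment nitrogen dosage (kg/ha); 0 leaves NUE undefined (`NA`).
#' @param plants_counted number of harvested plants the yield scales from.
#' @param area_m2 field area occupied by those plants (m^2).
#' @param gyp optional measured grain yield per plant (g); by default derived
#'   as `full_grains * weight_200 / 200`.
#' @param pl optional panicle length (cm), averaged through.
#' @param moisture_adjust deduct the 13.5% standard moisture content from GY
#'   (combine-harvest convention; off by default).
#' @return One-row data frame: `treatment`, `n_plants`, `epn`, `pl`, `gnp`,
#'   `ssr`, `tgw`, `gyp`, `gy`, `nue`.
#' @export
field_traits <- function(epn, full_grains, total_grains, weight_200,
                         treatment, plants_counted, area_m2,
                         gyp = NULL, pl = NA_real_, moisture_adjust = FALSE) {
  if (any(c(epn, full_grains, total_grains, weight_200) < 0, na.rm = TRUE)) {
    stop("counts and weights must be >= 0")
  }
  if (area_m2 <= 0) stop("area must be > 0")
  if (any(total_grains == 0)) stop("total grains = 0: SSR undefined")
  if (any(epn == 0)) stop("EPN = 0: grains per panicle undefined")
  if (is.null(gyp)) gyp <- full_grains * weight_200 / 200
  ssr <- 100 * full_grains / total_grains
  gnp <- full_grains / epn
  tgw <- 5 * weight_200
  gy <- mean(gyp) * plants_counted / area_m2 * 10
  if (moisture_adjust) gy <- gy * (1 - 0.135)
  nue <- if (treatment > 0) gy / treatment else NA_real_
  data.frame(treatment = treatment, n_plants = length(epn),
             epn = mean(epn), pl = mean(pl), gnp = mean(gnp),
             ssr = mean(ssr), tgw = mean(tgw), gyp = mean(gyp),
             gy = gy, nue = nue)
}

#' Two-sample t-test with defined degenerate limits
#'
#' Student's pooled-variance two-sample t-test (two-sided) by default, with
#' the Welch variant behind a flag. When both groups are constant the test is
#' returned in its defined limit: `t = 0, p = 1` for equal means, `t` of
#' matching sign infinite and `p = 0` otherwise.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal-variance) variant?
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
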