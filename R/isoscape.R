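#' Isoscape model parameters
#'
#' Coefficients of the two empirical linear relations behind the otolith
#' delta-18O isoscape: the temperature dependence of otolith delta-18O
#' (fractionation line, slope strictly negative) and per-region
#' salinity--seawater-delta-18O relations (VSMOW), plus a constant offset
#' absorbing the VSMOW-to-VPDB scale conversion.
#'
#' The defaults are documented placeholders of realistic magnitude for
#' temperate NW-Pacific waters, intended for tests and synthetic data; for
#' real inference they must be replaced with coefficients calibrated for the
#' species and region under study (they are inputs, not constants of the
#' method).
#'
#' @param frac_slope permil per degC, must be negative (otolith delta-18O
#'   decreases with temperature).
#' @param frac_intercept permil.
#' @param water_scale_offset permil, added to the predicted seawater value
#'   (scale conversion; default 0, i.e. conversion folded into the salinity
#'   intercepts).
#' @param sal_relations data frame `region_id`, `slope` (permil/psu),
#'   `intercept` (permil); one row per region of the environment grid.
#' @return A list of class `iso_params`.
#' @export
iso_params <- function(frac_slope = -0.18, frac_intercept = 2.7,
                       water_scale_offset = 0,
                       sal_relations = data.frame(region_id = 1L,
                                                  slope = 0.42,
                                                  intercept = -14.3)) {
  if (!is.finite(frac_slope) || frac_slope >= 0)
    stop("frac_slope must be negative: otolith delta-18O decreases with ",
         "temperature")
  stopifnot(all(c("region_id", "slope", "intercept") %in%
                  names(sal_relations)))
  structure(list(frac_slope = frac_slope, frac_intercept = frac_intercept,
                 water_scale_offset = water_scale_offset,
                 sal_relations = sal_relations), class = "iso_params")
}

#' Arithmetic grid of assumed hatch dates
#'
#' @param start,end `Date` (or ISO-8601 strings); `start <= end`.
#' @param step_days positive integer spacing.
#' @return A `Date` vector starting at `start`, stepping by `step_days`,
#'   never exceeding `end`.
#' @examples
#' hatch_date_grid("2015-04-15", "2015-05-15", 3)  # 11 dates
#' @export
hatch_date_grid <- function(start, end, step_days = 3) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable date")
  if (start > end) stop("start must not be after end")
  if (step_days < 1) stop("step_days must be >= 1")
  seq(start, end, by = paste(as.integer(step_days), "days"))
}

#' Mean temperature and salinity fields over an ontogenetic window
#'
#' Per-cell arithmetic means of `temp` and `sal` over the days
#' `hatch_date + window[1] ... hatch_date + window[2]` (closed; day 0 is the
#' hatch date, so the larval window `c(0, 60)` spans 61 days).  Under the
#' default strict missing-data mode a cell is missing if any day is missing;
#' `min_coverage < 1` instead requires that fraction of days present.
#'
#' @param env an `env_field`.
#' @param hatch_date a `Date` scalar.
#' @param window closed dph interval, e.g. `c(0, 60)`.
#' @param min_coverage required fraction of non-missing days per cell
#'   (1 = strict).
#' @return A list with matrices `temp` and `sal` of dim `(lat, lon)`.
#' @export
window_mean_fields <- function(env, hatch_date, window,
                               min_coverage = 1) {
  stopifnot(inherits(env, "env_field"), length(window) == 2)
  hatch_date <- as.Date(hatch_date)
  days <- hatch_date + seq(window[1], window[2])
  idx <- match(days, env$day)
  if (anyNA(idx))
    stop("environment day axis does not cover ", hatch_date, " + [",
         window[1], ", ", window[2], "] dph")
  avg <- function(a) {
    sub <- a[idx, , , drop = FALSE]
    m <- apply(sub, c(2, 3), function(v) {
      cov <- mean(!is.na(v))
      if (cov < min_coverage || cov == 0) NA_real_ else mean(v, na.rm = TRUE)
    })
    m
  }
  list(temp = avg(env$temp), sal = avg(env$sal))
}

#' Predict seawater delta-18O from salinity
#'
#' Linear per-region relation `d18O_w = slope * S + intercept` (VSMOW).
#'
#' @param sal salinity (psu), any shape.
#' @param region_id region identifiers, recycled against `sal`.
#' @param params an `iso_params`.
#' @return Seawater delta-18O, same shape as `sal`.
#' @export
predict_water_d18O <- function(sal, region_id, params) {
  rel <- params$sal_relations
  m <- match(as.integer(region_id), rel$region_id)
  if (anyNA(m[!is.na(region_id)]))
    stop("no salinity relation for region_id ",
         paste(unique(region_id[is.na(m)]), collapse = ", "))
  out <- rel$slope[m] * sal + rel$intercept[m]
  if (!is.null(dim(sal))) dim(out) <- dim(sal)
  out
}

#' Predict otolith delta-18O from temperature and seawater delta-18O
#'
#' Linear thermometry form
#' `d18O_oto = frac_slope * T + frac_intercept + d18O_w + water_scale_offset`
#' (permil VPDB).  Purely local: equal inputs give equal outputs.
#'
#' @param temp temperature (degC).
#' @param d18O_w seawater delta-18O.
#' @param params an `iso_params`.
#' @return Predicted otolith delta-18O.
#' @export
predict_otolith_d18O <- function(temp, d18O_w, params) {
  params$frac_slope * temp + params$frac_intercept + d18O_w +
    params$water_scale_offset
}

#' Build an otolith delta-18O isoscape for one hatch date and window
#'
#' Averages the environment over the window, then applies the salinity and
#' fractionation relations per cell (`order = "average_first"`, the
#' default).  Because both relations are linear, transforming daily and
#' then averaging (`order = "transform_first"`) is identical on complete
#' data and differs only in missing-data handling.
#'
#' @inheritParams window_mean_fields
#' @param params an `iso_params`.
#' @param order `"average_first"` or `"transform_first"`.
#' @return An object of class `isoscape`: list with `d18O` matrix
#'   `(lat, lon)`, `lat`, `lon`, `hatch_date`, `window`, `params`.
#' @export
build_isoscape <- function(env, hatch_date, window, params,
                           min_coverage = 1,
                           order = c("average_first", "transform_first")) {
  order <- match.arg(order)
  stopifnot(inherits(params, "iso_params"))
  hatch_date <- as.Date(hatch_date)
  if (order == "average_first") {
    mf <- window_mean_fields(env, hatch_date, window, min_coverage)
    w <- predict_water_d18O(mf$sal, env$region_id, params)
    d <- predict_otolith_d18O(mf$temp, w, params)
  } else {
    days <- hatch_date + seq(window[1], window[2])
    idx <- match(days, env$day)
    if (anyNA(idx)) stop("environment day axis does not cover the window")
    nd <- length(idx)
    daily <- array(NA_real_, c(nd, length(env$lat), length(env$lon)))
    for (j in seq_len(nd)) {
      w <- predict_water_d18O(env$sal[idx[j], , ], env$region_id, params)
      daily[j, , ] <- predict_otolith_d18O(env$temp[idx[j], , ], w, params)
    }
    d <- apply(daily, c(2, 3), function(v) {
      cov <- mean(!is.na(v))
      if (cov < min_coverage || cov == 0) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  structure(list(d18O = d, lat = env$lat, lon = env$lon,
                 hatch_date = hatch_date, window = window, params = params),
            class = "isoscape")
}

#' Boolean assignment mask from an isoscape and an observed band
#'
#' A cell matches iff its predicted otolith delta-18O lies inside the
#' closed interval `[mu - sigma, mu + sigma]` (the observed mean +/- 1 SD
#' band of the group being located).  Missing cells are `FALSE` and counted
#' in the `n_missing` attribute.
#'
#' @param isoscape an `isoscape`.
#' @param mu,sigma observed band centre and half-width (permil);
#'   `sigma >= 0`.
#' @return Logical matrix `(lat, lon)` with attribute `n_missing`.
#' @export
assignment_mask <- function(isoscape, mu, sigma) {
  stopifnot(inherits(isoscape, "isoscape"), sigma >= 0)
  d <- isoscape$d18O
  m <- !is.na(d) & d >= mu - sigma & d <= mu + sigma
  attr(m, "n_missing") <- sum(is.na(d))
  m
}

#' Aggregate per-hatch-date masks into a match-count grid
#'
#' @param masks list of logical matrices sharing one shape (one per hatch
#'   date); names (or the `hatch_dates` argument) identify the dates.
#' @param hatch_dates optional `Date` vector matching `masks`.
#' @return An object of class `assignment_result`: list with `counts`
#'   (integer matrix, elementwise sum of the masks), `masks`,
#'   `hatch_dates`.
#' @export
aggregate_hatch_masks <- function(masks, hatch_dates = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1)
  dm <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dm))
    stop("masks must share one shape")
  counts <- Reduce(`+`, lapply(masks, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  structure(list(counts = counts, masks = masks,
                 hatch_dates = hatch_dates %||%
                   (if (!is.null(names(masks))) as.Date(names(masks)) else
                      NULL)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf(
    "assignment_result: %d hatch dates, %d/%d cells matched at least once\n",
    length(x$masks), sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Export matching cells of an assignment result as coordinates
#'
#' @param result an `assignment_result`.
#' @param lat,lon grid coordinate vectors.
#' @return Data frame `lat`, `lon`, `n_matches` for cells with at least one
#'   match.
#' @export
matches_table <- function(result, lat, lon) {
  idx <- which(result$counts > 0, arr.ind = TRUE)
  out <- data.frame(lat = lat[idx[, 1]], lon = lon[idx[, 2]],
                    n_matches = result$counts[idx])
  out[order(out$lat, out$lon), , drop = FALSE]
}
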