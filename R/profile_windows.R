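#' Acid-fractionation correction for otolith delta-18O
#'
#' Carbonate reacted with phosphoric acid at 72 degC carries a
#' temperature-dependent acid-fractionation offset relative to the
#' conventional 25 degC digestion; subtracting 0.09 permil from
#' 72 degC-analysed aragonite delta-18O puts both on a common scale.
#' Values analysed at 25 degC are already comparable and pass through
#' unchanged.  delta-13C needs no correction.
#'
#' @param d18O numeric vector of delta-18O values (permil VPDB).
#' @param acid_temp character vector (recycled), `"25C"` or `"72C"`.
#' @param offset correction constant in permil (default 0.09).
#' @return Corrected delta-18O vector.
#' @examples
#' correct_acid_fractionation(0, "72C")   # -0.09
#' correct_acid_fractionation(-1, "25C")  # -1
#' @export
correct_acid_fractionation <- function(d18O, acid_temp, offset = 0.09) {
  if (any(!acid_temp %in% c("25C", "72C")))
    stop("unknown acid_temp: ",
         paste(setdiff(unique(acid_temp), c("25C", "72C")), collapse = ", "))
  stopifnot(all(is.finite(d18O)))
  d18O - ifelse(acid_temp == "72C", offset, 0)
}

#' Apply the acid correction to every segment of a dataset, once
#'
#' Corrected datasets carry an `acid_corrected` attribute; applying the
#' correction a second time is an error (the shift is silent and would be
#' undetectable after the fact).
#'
#' @param dataset an `otl_dataset`.
#' @param offset correction constant in permil.
#' @return The dataset with corrected `d18O_permil` and the guard attribute.
#' @export
acid_correct_dataset <- function(dataset, offset = 0.09) {
  stopifnot(inherits(dataset, "otl_dataset"))
  if (isTRUE(attr(dataset, "acid_corrected")))
    stop("dataset is already acid-corrected; refusing to apply twice")
  dataset$segments$d18O_permil <- correct_acid_fractionation(
    dataset$segments$d18O_permil, dataset$segments$acid_temp, offset)
  attr(dataset, "acid_corrected") <- TRUE
  dataset
}

#' Fit a mean radius--age curve from reference fish with increment readings
#'
#' For fish whose daily increments were not read, milling distances are
#' converted to ages with the mean relationship between otolith radius and
#' age of other fish from the same cohort (year, season, region).  The curve
#' is a piecewise-linear interpolant through the mean radius at each observed
#' age; any non-monotonicity from sampling noise is resolved by an isotonic
#' (pool-adjacent-violators) adjustment.
#'
#' @param radius_um,age_dph numeric vectors of paired (radius, age)
#'   observations pooled over the reference fish.
#' @param cohort a label naming the reference cohort (used in messages).
#' @return An object of class `radius_age_curve` with anchor vectors
#'   `radius` and `age` (both strictly increasing).
#' @export
fit_radius_age_curve <- function(radius_um, age_dph, cohort = "reference") {
  ok <- is.finite(radius_um) & is.finite(age_dph)
  radius_um <- radius_um[ok]; age_dph <- age_dph[ok]
  if (!length(radius_um))
    stop("no (radius, age) reference observations for cohort ", cohort)
  ages <- sort(unique(age_dph))
  mean_r <- vapply(ages, function(a) mean(radius_um[age_dph == a]), 0)
  mean_r <- pava(mean_r)          # enforce non-decreasing mean radius
  keep <- !duplicated(mean_r)     # collapse flat runs to keep strict map
  ages <- ages[keep]; mean_r <- mean_r[keep]
  if (length(ages) < 2)
    stop("reference cohort ", cohort,
         " has fewer than two distinct usable ages")
  structure(list(radius = mean_r, age = ages, cohort = cohort),
            class = "radius_age_curve")
}

# pool-adjacent-violators for a non-decreasing sequence (unit weights)
pava <- function(y) {
  n <- length(y)
  val <- y; w <- rep(1, n); idx <- seq_len(n); m <- n
  i <- 1L
  while (i < m) {
    if (val[i] > val[i + 1] + 1e-12) {
      nv <- (w[i] * val[i] + w[i + 1] * val[i + 1]) / (w[i] + w[i + 1])
      val[i] <- nv; w[i] <- w[i] + w[i + 1]
      val <- val[-(i + 1)]; w <- w[-(i + 1)]; idx <- idx[-(i + 1)]
      m <- m - 1L
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  rep(val, times = diff(c(idx, n + 1L)))
}

#' Evaluate a radius--age curve
#'
#' Maps milling distance (radius from the core, um) to estimated age (dph).
#' Queries outside the anchor hull are clamped to the hull boundary with a
#' warning.
#'
#' @param curve a `radius_age_curve`.
#' @param radius_um numeric vector of radii.
#' @param quiet suppress the clamping warning.
#' @return Estimated ages (dph).
#' @export
predict_age <- function(curve, radius_um, quiet = FALSE) {
  stopifnot(inherits(curve, "radius_age_curve"))
  out_hull <- radius_um < min(curve$radius) | radius_um > max(curve$radius)
  if (any(out_hull) && !quiet)
    warning(sum(out_hull), " radius value(s) outside the reference hull; ",
            "clamped")
  approx(curve$radius, curve$age, xout = radius_um, rule = 2)$y
}

#' @rdname predict_age
#' @description `predict_radius()` is the inverse mapping (age to mean
#'   radius), used e.g. to impute the otolith radius at 60 dph for fish
#'   without increment readings.
#' @param age_dph numeric vector of ages.
#' @export
predict_radius <- function(curve, age_dph, quiet = FALSE) {
  stopifnot(inherits(curve, "radius_age_curve"))
  out_hull <- age_dph < min(curve$age) | age_dph > max(curve$age)
  if (any(out_hull) && !quiet)
    warning(sum(out_hull), " age value(s) outside the reference hull; clamped")
  approx(curve$age, curve$radius, xout = age_dph, rule = 2)$y
}

#' Assign estimated age ranges to micromill segments
#'
#' Fills `est_age_start_dph`/`est_age_end_dph` from the radius--age curve for
#' segments that do not already carry increment-based age readings (those are
#' left untouched), and imputes `radius_at_60dph_um` from the curve where
#' absent.
#'
#' @param segments a segment data frame (one or more fish).
#' @param curve a `radius_age_curve`.
#' @return The segment data frame with completed age columns.
#' @export
assign_segment_ages <- function(segments, curve) {
  no_age <- is.na(segments$est_age_start_dph) | is.na(segments$est_age_end_dph)
  if (any(no_age)) {
    segments$est_age_start_dph[no_age] <-
      predict_age(curve, segments$dist_start_um[no_age], quiet = TRUE)
    segments$est_age_end_dph[no_age] <-
      predict_age(curve, segments$dist_end_um[no_age], quiet = TRUE)
  }
  if ("radius_at_60dph_um" %in% names(segments)) {
    no_r <- is.na(segments$radius_at_60dph_um)
    if (any(no_r))
      segments$radius_at_60dph_um[no_r] <- predict_radius(curve, 60,
                                                          quiet = TRUE)
  }
  segments
}

#' Rescale a milled profile to an ontogenetic window
#'
#' Implements the rescaling rule for heterogeneous micromill profiles: a
#' segment contributes to a window iff the median of its estimated age range
#' lies inside the closed window; contributing segments are averaged with
#' weights proportional to the width of the milling area.  The default
#' weight is the physical width in um; `weight = "day_span"` weights by the
#' estimated day span instead.
#'
#' @param segments segment data frame for one fish, with age columns filled.
#' @param window closed age interval in dph, e.g. `c(0, 60)` (larval) or
#'   `c(106, 120)` (juvenile).
#' @param quantity `"d18O"` or `"d13C"`.
#' @param weight `"width_um"` (default) or `"day_span"`.
#' @return The weighted mean (permil), or `NA_real_` if no segment
#'   qualifies — absence is a value, not an error.
#' @export
window_value <- function(segments, window, quantity = c("d18O", "d13C"),
                         weight = c("width_um", "day_span")) {
  quantity <- match.arg(quantity)
  weight <- match.arg(weight)
  stopifnot(length(window) == 2, window[1] <= window[2])
  med <- (segments$est_age_start_dph + segments$est_age_end_dph) / 2
  sel <- !is.na(med) & med >= window[1] & med <= window[2]
  if (!any(sel)) return(NA_real_)
  w <- if (weight == "width_um")
    segments$dist_end_um[sel] - segments$dist_start_um[sel]
  else
    segments$est_age_end_dph[sel] - segments$est_age_start_dph[sel]
  v <- if (quantity == "d18O") segments$d18O_permil[sel] else
    segments$d13C_permil[sel]
  if (any(w <= 0)) stop("non-positive segment weight")
  sum(w * v) / sum(w)
}

#' Extract per-fish stage values for the two ontogenetic windows
#'
#' Runs the full profile-windows stage on an acid-corrected dataset: fits a
#' radius--age curve per (year, season, region) cohort from fish with
#' increment readings (season = calendar quarter of the capture date),
#' completes missing segment ages, and rescales every profile to the larval
#' and juvenile windows.
#'
#' Fish with no qualifying larval segment are excluded with a warning (they
#' cannot enter any downstream analysis).  `juvenile_d18O` and
#' `radius_at_60dph_um` are `NA` where not milled or not measured.
#'
#' @param dataset an acid-corrected `otl_dataset` (see
#'   [acid_correct_dataset()]).
#' @param larval,juvenile closed dph windows.
#' @param weight passed to [window_value()].
#' @return A `stage_values` data frame: `fish_id`, `region`, `age`,
#'   `year_class`, `larval_d18O`, `larval_d13C`, `juvenile_d18O`,
#'   `radius_at_60dph_um`, `has_increments`, `label` (initialised to
#'   `pacific_offshore` for Pacific-offshore fish, else `unclassified`).
#' @export
extract_stage_values <- function(dataset, larval = c(0, 60),
                                 juvenile = c(106, 120),
                                 weight = c("width_um", "day_span")) {
  stopifnot(inherits(dataset, "otl_dataset"))
  weight <- match.arg(weight)
  if (!isTRUE(attr(dataset, "acid_corrected")))
    warning("dataset is not flagged acid-corrected; ",
            "assuming values are already on the 25C scale")
  s <- dataset$samples
  g <- dataset$segments
  has_age <- !is.na(g$est_age_start_dph) & !is.na(g$est_age_end_dph)
  inc_fish <- unique(g$fish_id[has_age])
  quarter <- function(d) (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L
  s$season <- quarter(s$capture_date)
  s$cohort <- paste(format(s$capture_date, "%Y"), s$season, s$region,
                    sep = "/")

  # one radius--age curve per cohort, from increment-read fish
  curves <- list()
  for (ck in unique(s$cohort)) {
    ids <- intersect(s$fish_id[s$cohort == ck], inc_fish)
    gi <- g[g$fish_id %in% ids, , drop = FALSE]
    gi <- gi[!is.na(gi$est_age_start_dph) & !is.na(gi$est_age_end_dph), ,
             drop = FALSE]
    if (nrow(gi) >= 2) {
      curves[[ck]] <- fit_radius_age_curve(
        c(gi$dist_start_um, gi$dist_end_um),
        c(gi$est_age_start_dph, gi$est_age_end_dph), cohort = ck)
    }
  }

  rows <- vector("list", nrow(s))
  dropped <- character()
  for (i in seq_len(nrow(s))) {
    id <- s$fish_id[i]
    gi <- g[g$fish_id == id, , drop = FALSE]
    if (!nrow(gi)) { dropped <- c(dropped, id); next }
    fish_has_inc <- id %in% inc_fish
    if (anyNA(gi$est_age_start_dph) || anyNA(gi$est_age_end_dph)) {
      cv <- curves[[s$cohort[i]]]
      if (is.null(cv)) { dropped <- c(dropped, id); next }
      gi <- assign_segment_ages(gi, cv)
    }
    l18 <- window_value(gi, larval, "d18O", weight)
    if (is.na(l18)) { dropped <- c(dropped, id); next }
    rows[[i]] <- data.frame(
      fish_id = id, region = s$region[i], age = s$age[i],
      year_class = s$year_class[i],
      larval_d18O = l18,
      larval_d13C = window_value(gi, larval, "d13C", weight),
      juvenile_d18O = window_value(gi, juvenile, "d18O", weight),
      radius_at_60dph_um =
        if (all(is.na(gi$radius_at_60dph_um))) NA_real_ else
          gi$radius_at_60dph_um[!is.na(gi$radius_at_60dph_um)][1],
      has_increments = fish_has_inc,
      label = if (s$region[i] == "PacificOffshore") "pacific_offshore" else
        "unclassified",
      label_source = if (s$region[i] == "PacificOffshore") "fixed" else
        NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped))
    warning(length(dropped), " fish without a usable larval-window value ",
            "excluded: ", paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  sv <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(sv)) sv <- data.frame(
    fish_id = character(), region = character(), age = integer(),
    year_class = integer(), larval_d18O = numeric(), larval_d13C = numeric(),
    juvenile_d18O = numeric(), radius_at_60dph_um = numeric(),
    has_increments = logical(), label = character(),
    label_source = character(), stringsAsFactors = FALSE)
  rownames(sv) <- NULL
  class(sv) <- c("stage_values", "data.frame")
  sv
}
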