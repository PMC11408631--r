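#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-data generator.  The group
#' delta-18O moments default to the values observed for the three
#' provenance groups of Japanese sardine (permil VPDB, mean and SD):
#' locals larval −0.7 ± 0.4 and juvenile −1.5 ± 0.4, nonlocals −0.3 ± 0.2
#' and −0.2 ± 0.3, Pacific-offshores −0.1 ± 0.3 and 0.1 ± 0.3.  Analytical
#' noise defaults to 0.10 permil (1 sigma), inside the 0.06--0.13 permil
#' precision range of the carbonate systems emulated, and micromill segment
#' widths are drawn from 30--160 um.  delta-13C is modelled as
#' non-informative noise around group means (no environmental model), since
#' it does not discriminate the groups.
#'
#' When `calibrate_moments` is `TRUE` (default) each fish's forward-modelled
#' daily delta-18O series is shifted by a smooth ontogenetic correction so
#' that its larval/juvenile window means equal the configured group targets
#' plus the fish's biological deviate; the environment then contributes the
#' within-window structure.  With `FALSE` the otolith records the raw
#' forward model of the occupied cells (used for geolocation experiments).
#'
#' @param years integer vector of year-classes to simulate.
#' @param n_local,n_nonlocal,n_offshore cohort sizes (total across years).
#' @param grid list `lat = c(min, max, step)`, `lon = c(min, max, step)`.
#' @param env list: `base_temp` (degC at the southern grid edge),
#'   `lat_gradient` (degC per degree northward, > 0 means north colder),
#'   `seasonal_amp` (degC), `noise_sd` (degC), `sal_base` (psu),
#'   `coastal_patch` (list `lat`, `lon` ranges and `delta` psu for the
#'   less-saline coastal bay signature).
#' @param groups per-group list of `larval_mean`, `larval_sd`,
#'   `juvenile_mean`, `juvenile_sd`, `d13C_mean`, `d13C_sd`,
#'   `growth_multiplier`.
#' @param measurement list `analytical_sd_d18O`, `analytical_sd_d13C`,
#'   `seg_width_um = c(min, max)`.
#' @param growth list `rate_um_per_day`, `fish_sd` (lognormal sigma of the
#'   per-fish growth multiplier).
#' @param iso an [iso_params()] used as the forward model.
#' @param calibrate_moments logical, see Details.
#' @param frac_no_juvenile,frac_no_increments fractions of age-1 SJ-ECS
#'   fish lacking the juvenile milling / the increment reading.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(years = c(2013L, 2014L, 2015L),
                       n_local = 120, n_nonlocal = 60, n_offshore = 40,
                       grid = list(lat = c(30, 46, 1), lon = c(128, 148, 1)),
                       env = list(base_temp = 23, lat_gradient = 0.6,
                                  seasonal_amp = 4, noise_sd = 0.1,
                                  sal_base = 34.2,
                                  coastal_patch = list(lat = c(35, 38),
                                                       lon = c(136, 138),
                                                       delta = -1.5)),
                       groups = list(
                         local = list(larval_mean = -0.7, larval_sd = 0.4,
                                      juvenile_mean = -1.5,
                                      juvenile_sd = 0.4,
                                      d13C_mean = -6.2, d13C_sd = 0.4,
                                      growth_multiplier = 1.0),
                         nonlocal = list(larval_mean = -0.3,
                                         larval_sd = 0.2,
                                         juvenile_mean = -0.2,
                                         juvenile_sd = 0.3,
                                         d13C_mean = -6.1, d13C_sd = 0.4,
                                         growth_multiplier = 1.25),
                         pacific_offshore = list(larval_mean = -0.1,
                                                 larval_sd = 0.3,
                                                 juvenile_mean = 0.1,
                                                 juvenile_sd = 0.3,
                                                 d13C_mean = -6.0,
                                                 d13C_sd = 0.4,
                                                 growth_multiplier = 1.2)),
                       measurement = list(analytical_sd_d18O = 0.10,
                                          analytical_sd_d13C = 0.10,
                                          seg_width_um = c(30, 160)),
                       growth = list(rate_um_per_day = 5, fish_sd = 0.10),
                       iso = iso_params(),
                       calibrate_moments = TRUE,
                       frac_no_juvenile = 0.3,
                       frac_no_increments = 0.15) {
  stopifnot(all(vapply(groups, function(g) g$larval_sd >= 0 &&
                         g$juvenile_sd >= 0, TRUE)),
            n_local >= 0, n_nonlocal >= 0, n_offshore >= 0)
  structure(list(years = as.integer(years), n_local = n_local,
                 n_nonlocal = n_nonlocal, n_offshore = n_offshore,
                 grid = grid, env = env, groups = groups,
                 measurement = measurement, growth = growth, iso = iso,
                 calibrate_moments = isTRUE(calibrate_moments),
                 frac_no_juvenile = frac_no_juvenile,
                 frac_no_increments = frac_no_increments),
            class = "sim_config")
}

#' Simulate a seasonal temperature/salinity environment
#'
#' Temperature is `base_temp - lat_gradient * (lat - lat_min) +
#' seasonal_amp * cos(2 pi (doy - 227) / 365)` — colder northward, warmest
#' in mid-August — plus a small smooth noise surface (three random
#' low-order sinusoid modes).  Salinity is `sal_base` with an optional
#' low-salinity coastal patch.  Deterministic given `seed`.
#'
#' @param config a `sim_config`.
#' @param year calendar year of the field.
#' @param seed integer seed.
#' @param days optional `Date` vector; default Jan 1 -- Oct 31 of `year`.
#' @return An `env_field`.
#' @export
simulate_environment <- function(config, year, seed, days = NULL) {
  g <- config$grid
  lat <- seq(g$lat[1], g$lat[2], by = g$lat[3])
  lon <- seq(g$lon[1], g$lon[2], by = g$lon[3])
  if (length(lat) < 2 || length(lon) < 2)
    stop("degenerate grid: need at least 2 cells per axis")
  if (is.null(days))
    days <- seq(as.Date(sprintf("%d-01-01", year)),
                as.Date(sprintf("%d-10-31", year)), by = "1 day")
  e <- config$env
  doy <- as.integer(format(days, "%j"))
  nd <- length(days); nlat <- length(lat); nlon <- length(lon)
  seas <- e$seasonal_amp * cos(2 * pi * (doy - 227) / 365)
  base <- outer(rep(1, nd), e$base_temp - e$lat_gradient * (lat - lat[1]))
  temp <- array(rep(base + seas, times = nlon), c(nd, nlat, nlon))
  if (e$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(stage_seed(seed, paste0("env", year)))
    for (m in 1:3) {
      a <- rnorm(1, sd = e$noise_sd / sqrt(3))
      ph <- runif(3, 0, 2 * pi)
      fl <- runif(1, 1, 3); fo <- runif(1, 1, 3); fd <- runif(1, 1, 4)
      mode <- a *
        outer(sin(2 * pi * fd * doy / 365 + ph[1]),
              sin(2 * pi * fl * (lat - lat[1]) / diff(range(lat)) + ph[2]))
      lonm <- sin(2 * pi * fo * (lon - lon[1]) / diff(range(lon)) + ph[3])
      temp <- temp + outer(mode, lonm)
    }
  }
  sal <- array(e$sal_base, c(nd, nlat, nlon))
  cp <- e$coastal_patch
  if (!is.null(cp)) {
    ii <- which(lat >= cp$lat[1] & lat <= cp$lat[2])
    jj <- which(lon >= cp$lon[1] & lon <= cp$lon[2])
    sal[, ii, jj] <- sal[, ii, jj] + cp$delta
  }
  env_field(lat = lat, lon = lon, day = days, temp = temp, sal = sal)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# movement templates: residence box / start-to-end drift, in (lat, lon)
trajectory_templates <- list(
  local = list(kind = "resident", box = list(lat = c(33, 36),
                                             lon = c(130, 134))),
  nonlocal = list(kind = "drift", from = c(33.5, 130), to = c(43, 140)),
  pacific_offshore = list(kind = "drift", from = c(33, 142),
                          to = c(42.5, 146))
)

#' Simulate a fish trajectory and its environmental exposure
#'
#' `local` fish reside at one warm coastal cell (drawn inside the template
#' box) and experience the seasonal warming of that cell; `nonlocal` and
#' `pacific_offshore` fish drift linearly from a warm southern start to a
#' cold northern position over the first 120 days, then hold.  Positions
#' are snapped to grid cells and clamped to the grid with a warning if the
#' template leaves it.
#'
#' @param template `"local"`, `"nonlocal"` or `"pacific_offshore"`.
#' @param env an `env_field` covering `hatch_date + n_days`.
#' @param hatch_date `Date`.
#' @param seed integer seed (per fish).
#' @param n_days trajectory length in days (default 140).
#' @return A data frame (one row per day of life): `age`, `date`, `lat`,
#'   `lon`, `temp`, `sal`.
#' @export
simulate_trajectory <- function(template, env, hatch_date, seed,
                                n_days = 140) {
  tpl <- trajectory_templates[[template]]
  if (is.null(tpl)) stop("unknown template: ", template)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ages <- 0:(n_days - 1)
  dates <- as.Date(hatch_date) + ages
  if (tpl$kind == "resident") {
    la <- runif(1, tpl$box$lat[1], tpl$box$lat[2])
    lo <- runif(1, tpl$box$lon[1], tpl$box$lon[2])
    lat_path <- rep(la, n_days); lon_path <- rep(lo, n_days)
  } else {
    jit <- rnorm(2, sd = 0.5)
    f <- pmin(ages / 120, 1)
    lat_path <- tpl$from[1] + jit[1] + f * (tpl$to[1] - tpl$from[1])
    lon_path <- tpl$from[2] + jit[2] + f * (tpl$to[2] - tpl$from[2])
  }
  out_of_grid <- lat_path < min(env$lat) | lat_path > max(env$lat) |
    lon_path < min(env$lon) | lon_path > max(env$lon)
  if (any(out_of_grid))
    warning("trajectory left the grid on ", sum(out_of_grid),
            " day(s); clamped")
  ii <- pmin(pmax(round((lat_path - env$lat[1]) /
                          (env$lat[2] - env$lat[1])) + 1, 1),
             length(env$lat))
  jj <- pmin(pmax(round((lon_path - env$lon[1]) /
                          (env$lon[2] - env$lon[1])) + 1, 1),
             length(env$lon))
  tt <- match(dates, env$day)
  if (anyNA(tt)) stop("environment does not cover the trajectory dates")
  idx <- cbind(tt, ii, jj)
  data.frame(age = ages, date = dates, lat = env$lat[ii], lon = env$lon[jj],
             temp = env$temp[idx], sal = env$sal[idx])
}

# daily true otolith series along a history; day i occupies radius
# [r(i), r(i+1)], window mean over [a, b] dph = mean of days a..b-1
true_daily_d18O <- function(history, config, group, dev_larval,
                            dev_juvenile) {
  w <- predict_water_d18O(history$sal, rep(1L, nrow(history)), config$iso)
  raw <- predict_otolith_d18O(history$temp, w, config$iso)
  if (!config$calibrate_moments) return(raw + dev_larval)
  gs <- config$groups[[group]]
  mL <- mean(raw[history$age >= 0 & history$age <= 59])
  mJ <- mean(raw[history$age >= 106 & history$age <= 119])
  dL <- gs$larval_mean + dev_larval - mL
  dJ <- gs$juvenile_mean + dev_juvenile - mJ
  slope <- (dJ - dL) / (112.5 - 29.5)
  corr <- dL + slope * (pmin(pmax(history$age, 29.5), 112.5) - 29.5)
  raw + corr
}

#' Render a micromill otolith profile from a true history
#'
#' Radius grows linearly (`rate_um_per_day` times a per-fish lognormal
#' multiplier); micromill segments partition the radius axis with widths
#' drawn from the configured range (or at explicit `boundaries`); each
#' segment value is the growth-weighted mean of the daily true values its
#' radius span covers, plus Gaussian analytical noise; delta-13C is group
#' mean plus fish deviate plus noise.
#'
#' @param history trajectory data frame from [simulate_trajectory()].
#' @param group group name (keys of `config$groups`).
#' @param config a `sim_config`.
#' @param seed per-fish seed.
#' @param max_mill_age oldest age (dph) covered by milling; 100 emulates a
#'   fish whose juvenile portion was not milled.
#' @param boundaries optional explicit radius boundaries (um) overriding
#'   random segmentation.
#' @return A list: `segments` data frame (dataset schema), `truth` one-row
#'   data frame (`true_larval_d18O`, `true_juvenile_d18O`,
#'   `radius_at_60dph_um`, `growth_multiplier`), `daily` (ages, radii and
#'   true daily values).
#' @export
render_otolith_profile <- function(history, group, config, seed,
                                   max_mill_age = NULL, boundaries = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gs <- config$groups[[group]]
  n_days <- nrow(history)
  mult <- gs$growth_multiplier * rlnorm(1, 0, config$growth$fish_sd)
  dr <- config$growth$rate_um_per_day * mult
  dev_L <- rnorm(1, 0, gs$larval_sd)
  dev_J <- rnorm(1, 0, gs$juvenile_sd)
  delta <- true_daily_d18O(history, config, group, dev_L, dev_J)
  d13C_fish <- gs$d13C_mean + rnorm(1, 0, gs$d13C_sd)

  max_age <- if (is.null(max_mill_age)) n_days else min(max_mill_age, n_days)
  R <- dr * max_age
  if (is.null(boundaries)) {
    wr <- config$measurement$seg_width_um
    b <- 0
    while (b[length(b)] < R)
      b <- c(b, b[length(b)] + runif(1, wr[1], wr[2]))
    b[length(b)] <- R
    if (length(b) > 2 && diff(b)[length(b) - 1] < 1e-6)
      b <- b[-(length(b) - 1)]
    boundaries <- b
  }
  nseg <- length(boundaries) - 1
  r_lo <- boundaries[-length(boundaries)]
  r_hi <- boundaries[-1]
  day_lo <- dr * (history$age)        # radius at start of each day
  day_hi <- dr * (history$age + 1)
  seg_val <- numeric(nseg)
  for (s in seq_len(nseg)) {
    wts <- pmax(0, pmin(r_hi[s], day_hi) - pmax(r_lo[s], day_lo))
    seg_val[s] <- sum(wts * delta) / sum(wts)
  }
  noise <- config$measurement$analytical_sd_d18O
  d18O_meas <- seg_val + rnorm(nseg, 0, noise)
  d13C_meas <- d13C_fish + rnorm(nseg, 0,
                                 config$measurement$analytical_sd_d13C)
  segs <- data.frame(
    dist_start_um = r_lo, dist_end_um = r_hi,
    d18O_permil = d18O_meas, d13C_permil = d13C_meas,
    est_age_start_dph = r_lo / dr, est_age_end_dph = r_hi / dr,
    radius_at_60dph_um = 60 * dr, stringsAsFactors = FALSE)
  truth <- data.frame(
    true_larval_d18O = mean(delta[history$age <= 59]),
    true_juvenile_d18O = if (max_age >= 120)
      mean(delta[history$age >= 106 & history$age <= 119]) else NA_real_,
    radius_at_60dph_um = 60 * dr, growth_multiplier = mult,
    true_d13C = d13C_fish, stringsAsFactors = FALSE)
  list(segments = segs, truth = truth,
       daily = data.frame(age = history$age, radius_start = day_lo,
                          radius_end = day_hi, d18O = delta))
}

#' Generate a full synthetic cohort dataset
#'
#' Emits fish across regions, year-classes and ages with the sampling
#' structure the analysis expects: locals as age-0 summer captures in the
#' three SJ-ECS regions plus age-1 winter--spring captures (West Kyushu,
#' Oki Islands, Noto Peninsula); nonlocals as age-1 spring captures around
#' the Oki Islands and Noto Peninsula; Pacific-offshores as age-0 autumn
#' captures.  Configured fractions of age-1 SJ-ECS fish lack the juvenile
#' milling and/or the increment reading, exercising the discriminant path.
#' Deterministic per seed.
#'
#' @param config a `sim_config`.
#' @param seed master integer seed.
#' @return A list: `dataset` (an uncorrected `otl_dataset` whose 72C-batch
#'   delta-18O values still carry the acid-fractionation offset), `truth`
#'   (per-fish true labels and window values), `envs` (list of `env_field`
#'   per year).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  envs <- list()
  for (y in config$years)
    envs[[as.character(y)]] <- simulate_environment(config, y,
                                                    stage_seed(seed, "env"))
  plan <- cohort_plan(config)
  samples <- list(); segments <- list(); truth <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    env <- envs[[as.character(p$year_class)]]
    fseed <- stage_seed(seed, paste0("fish", i))
    hatch <- as.Date(sprintf("%d-04-15", p$year_class)) +
      (fseed %% 31L)                       # mid-April to mid-May
    hist <- simulate_trajectory(p$group, env, hatch, fseed)
    prof <- render_otolith_profile(
      hist, p$group, config, stage_seed(seed, paste0("meas", i)),
      max_mill_age = if (p$no_juvenile) 100 else NULL)
    segs <- prof$segments
    if (p$no_increments) {
      segs$est_age_start_dph <- NA_real_
      segs$est_age_end_dph <- NA_real_
      segs$radius_at_60dph_um <- NA_real_
    }
    # batch acid chemistry: odd batches 72C (offset re-added), even 25C
    acid <- if (i %% 2L == 1L) "72C" else "25C"
    if (acid == "72C") segs$d18O_permil <- segs$d18O_permil + 0.09
    segs$acid_temp <- acid
    id <- sprintf("F%04d", i)
    segs <- cbind(fish_id = id, segs, stringsAsFactors = FALSE)
    segs <- segs[, c("fish_id", "dist_start_um", "dist_end_um",
                     "d18O_permil", "d13C_permil", "acid_temp",
                     "est_age_start_dph", "est_age_end_dph",
                     "radius_at_60dph_um")]
    capture <- capture_date_for(p, fseed)
    sl <- sample_length(p, fseed)
    samples[[i]] <- data.frame(
      fish_id = id, region = p$region, capture_date = capture,
      year_class = p$year_class, age = p$age, standard_length_mm = sl,
      batch_id = paste0(p$region, "_", format(capture, "%Y%m")),
      stringsAsFactors = FALSE)
    truth[[i]] <- cbind(
      data.frame(fish_id = id, true_label = p$group, hatch_date = hatch,
                 template = p$group, region = p$region, age = p$age,
                 year_class = p$year_class,
                 no_juvenile = p$no_juvenile,
                 no_increments = p$no_increments,
                 stringsAsFactors = FALSE),
      prof$truth)
    segments[[i]] <- segs
  }
  samples <- do.call(rbind, samples)
  segments <- do.call(rbind, segments)
  truth <- do.call(rbind, truth)
  rownames(samples) <- rownames(segments) <- rownames(truth) <- NULL
  ds <- structure(list(samples = samples,
                       segments = segments[order(segments$fish_id,
                                                 segments$dist_start_um), ],
                       rejects = data.frame(file = character(),
                                            line = integer(),
                                            reason = character())),
                  class = "otl_dataset")
  rownames(ds$segments) <- NULL
  list(dataset = ds, truth = truth, envs = envs)
}

# deterministic cohort layout: group, region, age, year-class, missingness
cohort_plan <- function(config) {
  rows <- list()
  add <- function(group, n, regions, age) {
    if (n <= 0) return()
    yc <- rep(config$years, length.out = n)
    rg <- rep(regions, length.out = n)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, region = rg, age = age, year_class = yc,
      stringsAsFactors = FALSE)
  }
  nl <- config$n_local
  n0 <- round(nl * 0.5); n1wk <- round(nl * 0.2); n1on <- nl - n0 - n1wk
  add("local", n0, SJECS_REGIONS, 0L)
  add("local", n1wk, "WestKyushu", 1L)
  add("local", n1on, c("OkiIslands", "NotoPeninsula"), 1L)
  add("nonlocal", config$n_nonlocal, c("OkiIslands", "NotoPeninsula"), 1L)
  add("pacific_offshore", config$n_offshore, "PacificOffshore", 0L)
  plan <- do.call(rbind, rows)
  # missingness only among age-1 SJ-ECS fish, spread deterministically
  age1 <- which(plan$age == 1L)
  plan$no_juvenile <- FALSE
  plan$no_increments <- FALSE
  if (length(age1)) {
    # strides coprime with the year-class cycle so missingness spreads
    # evenly over year-classes and regions
    j <- seq_along(age1)
    if (config$frac_no_juvenile > 0)
      plan$no_juvenile[age1[(j * 3L) %% 10L <
                              10 * config$frac_no_juvenile]] <- TRUE
    if (config$frac_no_increments > 0)
      plan$no_increments[age1[(j * 7L) %% 20L <
                                20 * config$frac_no_increments]] <- TRUE
  }
  plan
}

capture_date_for <- function(p, fseed) {
  if (p$age == 0L) {
    # July-December of the hatch year (age-0 summer/autumn captures)
    as.Date(sprintf("%d-08-15", p$year_class)) + (fseed %% 75L)
  } else {
    # February-May of the following year
    as.Date(sprintf("%d-02-05", p$year_class + 1L)) + (fseed %% 110L)
  }
}

sample_length <- function(p, fseed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(fseed, "length"))
  if (p$age == 0L) min(rnorm(1, 125, 8), 149.5) else
    min(rnorm(1, 145, 6), 159.5)
}
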