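# small deterministic environment used across the isoscape tests
toy_env <- function(nd = 130, lat = seq(34, 40, 0.5),
                    lon = seq(130, 136, 0.5),
                    start = as.Date("2015-04-01"),
                    temp_fun = function(day, la, lo) 20 - 0.5 * (la - 34),
                    sal = 34) {
  days <- seq(start, by = "1 day", length.out = nd)
  tarr <- array(NA_real_, c(nd, length(lat), length(lon)))
  for (d in seq_len(nd)) for (i in seq_along(lat))
    tarr[d, i, ] <- temp_fun(d - 1, lat[i], lon)
  sarr <- array(sal, dim(tarr))
  env_field(lat, lon, days, tarr, sarr)
}

test_that("hatch date grids follow calendar arithmetic", {
  g <- hatch_date_grid("2015-04-15", "2015-05-15", 3)
  expect_length(g, 11)
  expect_identical(g[1], as.Date("2015-04-15"))
  expect_identical(g[11], as.Date("2015-05-15"))
  expect_identical(hatch_date_grid("2015-02-01", "2015-02-01", 3),
                   as.Date("2015-02-01"))
  # marginal-spawning-month scenarios are just different endpoints
  feb <- hatch_date_grid("2015-02-01", "2015-02-28", 3)
  expect_true(all(format(feb, "%m") == "02"))
  expect_error(hatch_date_grid("2015-05-15", "2015-04-15", 3), "start")
  expect_error(hatch_date_grid("2015-04-15", "2015-05-15", 0), "step")
})

test_that("window means average the covered days and propagate missing", {
  env <- toy_env(temp_fun = function(day, la, lo) 15)
  mf <- window_mean_fields(env, as.Date("2015-04-01"), c(0, 60))
  expect_true(all(mf$temp == 15))
  # linear warming 0.1 degC/day from day 0: mean over [0, 60] is 3.0
  env2 <- toy_env(temp_fun = function(day, la, lo) 0.1 * day)
  mf2 <- window_mean_fields(env2, as.Date("2015-04-01"), c(0, 60))
  expect_equal(unique(as.vector(mf2$temp)), 3.0, tolerance = 1e-12)
  # a single missing day knocks the cell out under strict mode
  env3 <- env
  env3$temp[5, 2, 3] <- NA
  mf3 <- window_mean_fields(env3, as.Date("2015-04-01"), c(0, 60))
  expect_true(is.na(mf3$temp[2, 3]))
  expect_false(anyNA(mf3$temp[-2, ]))
  # but survives a relaxed coverage requirement
  mf4 <- window_mean_fields(env3, as.Date("2015-04-01"), c(0, 60),
                            min_coverage = 0.8)
  expect_false(is.na(mf4$temp[2, 3]))
  expect_error(window_mean_fields(env, as.Date("2015-09-01"), c(0, 60)),
               "cover")
})

test_that("seawater and otolith d18O predictions are the linear relations", {
  p0 <- iso_params(sal_relations = data.frame(region_id = 1L, slope = 0,
                                              intercept = 0))
  expect_equal(predict_water_d18O(c(30, 34, 38), 1L, p0), c(0, 0, 0))
  p1 <- iso_params(sal_relations = data.frame(region_id = 1L, slope = 0.5,
                                              intercept = -17))
  expect_equal(predict_water_d18O(34, 1L, p1), 0)
  s <- seq(30, 36, 0.5)
  expect_true(all(diff(predict_water_d18O(s, 1L, p1)) > 0))
  expect_error(predict_water_d18O(34, 99L, p1), "region_id 99")

  p2 <- iso_params(frac_slope = -0.2, frac_intercept = 2)
  expect_equal(predict_otolith_d18O(15, 0, p2), -1.0)
  temps <- seq(5, 28, 0.5)
  expect_true(all(diff(predict_otolith_d18O(temps, 0, p2)) < 0))
  expect_error(iso_params(frac_slope = 0.1), "negative")
})

test_that("isoscapes compose the scalar operations cell by cell", {
  set.seed(31)
  env <- toy_env(nd = 70)
  env$temp <- array(rnorm(length(env$temp), 18, 3), dim(env$temp))
  env$sal <- array(rnorm(length(env$sal), 34, 0.4), dim(env$sal))
  pars <- iso_params()
  iso <- build_isoscape(env, as.Date("2015-04-01"), c(0, 60), pars)
  # brute-force per-cell oracle
  idx <- 1:61
  for (trial in 1:25) {
    i <- sample(length(env$lat), 1); j <- sample(length(env$lon), 1)
    tbar <- mean(env$temp[idx, i, j]); sbar <- mean(env$sal[idx, i, j])
    expected <- pars$frac_slope * tbar + pars$frac_intercept +
      (pars$sal_relations$slope * sbar + pars$sal_relations$intercept)
    expect_equal(iso$d18O[i, j], expected, tolerance = 1e-12)
  }
  # on complete data the transform-then-average route is identical
  iso2 <- build_isoscape(env, as.Date("2015-04-01"), c(0, 60), pars,
                         order = "transform_first")
  expect_equal(iso2$d18O, iso$d18O, tolerance = 1e-12)
  # uniform environment gives a uniform isoscape
  envu <- toy_env(nd = 70, temp_fun = function(day, la, lo) 16)
  isou <- build_isoscape(envu, as.Date("2015-04-01"), c(0, 60), pars)
  expect_equal(max(isou$d18O) - min(isou$d18O), 0)
  # warming a subgrid strictly lowers its predicted d18O, others equal
  envw <- envu
  envw$temp[, 1:3, ] <- envw$temp[, 1:3, ] + 2
  isow <- build_isoscape(envw, as.Date("2015-04-01"), c(0, 60), pars)
  expect_true(all(isow$d18O[1:3, ] < isou$d18O[1:3, ]))
  expect_equal(isow$d18O[-(1:3), ], isou$d18O[-(1:3), ])
})

test_that("assignment masks are closed intervals with nesting in sigma", {
  env <- toy_env(nd = 70)
  pars <- iso_params()
  iso <- build_isoscape(env, as.Date("2015-04-01"), c(0, 60), pars)
  iso$d18O[1, 1] <- -0.2; iso$d18O[1, 2] <- -0.6
  m <- assignment_mask(iso, mu = -0.3, sigma = 0.2)
  expect_true(m[1, 1])         # -0.2 inside [-0.5, -0.1]
  expect_false(m[1, 2])        # -0.6 outside
  # closed interval: exactly mu +/- sigma matches
  iso$d18O[2, 1] <- -0.5
  expect_true(assignment_mask(iso, -0.3, 0.2)[2, 1])
  # sigma = 0 keeps exact matches only
  iso$d18O[3, 1] <- -0.3
  m0 <- assignment_mask(iso, -0.3, 0)
  expect_true(m0[3, 1])
  expect_identical(sum(m0), sum(iso$d18O == -0.3))
  # missing cells are FALSE and counted
  iso$d18O[4, 1] <- NA
  mm <- assignment_mask(iso, -0.3, 10)
  expect_false(mm[4, 1])
  expect_identical(attr(mm, "n_missing"), 1L)
  # nesting: mask(s1) within mask(s2) for s1 <= s2, random isoscapes
  set.seed(41)
  for (rep in 1:20) {
    iso$d18O <- matrix(rnorm(length(iso$d18O), -1, 0.5), nrow(iso$d18O))
    s2 <- runif(1, 0.1, 1); s1 <- runif(1, 0, s2)
    m1 <- assignment_mask(iso, -1, s1); m2 <- assignment_mask(iso, -1, s2)
    expect_true(all(m2[m1]))
    expect_gte(sum(m2), sum(m1))
  }
})

test_that("hatch-date masks aggregate to elementwise counts", {
  set.seed(43)
  masks <- lapply(1:5, function(i) matrix(runif(12) < 0.5, 3, 4))
  names(masks) <- format(as.Date("2015-04-15") + 3 * (0:4), "%Y-%m-%d")
  agg <- aggregate_hatch_masks(masks)
  brute <- matrix(0L, 3, 4)
  for (m in masks) brute <- brute + m
  expect_identical(agg$counts, brute)
  expect_lte(max(agg$counts), 5)
  single <- aggregate_hatch_masks(masks[1])
  expect_identical(single$counts, matrix(as.integer(masks[[1]]), 3, 4))
  expect_error(aggregate_hatch_masks(list(masks[[1]], matrix(TRUE, 2, 2))),
               "shape")
  mt <- matches_table(agg, lat = c(34, 35, 36), lon = c(130, 131, 132, 133))
  expect_identical(sum(mt$n_matches), sum(agg$counts))
})

test_that("juvenile-window masks sit poleward of larval masks when warming", {
  # north-cold gradient plus seasonal warming: the same isotope band moves
  # north between the larval and juvenile windows
  env <- toy_env(nd = 200, lat = seq(32, 44, 0.5),
                 temp_fun = function(day, la, lo)
                   22 - 0.8 * (la - 32) + 6 * day / 200)
  pars <- iso_params()
  hatch <- as.Date("2015-04-15")
  isoL <- build_isoscape(env, hatch, c(0, 60), pars)
  isoJ <- build_isoscape(env, hatch, c(106, 120), pars)
  band <- c(mu = mean(isoL$d18O), sigma = 0.3)
  mL <- assignment_mask(isoL, band["mu"], band["sigma"])
  mJ <- assignment_mask(isoJ, band["mu"], band["sigma"])
  expect_gt(sum(mL), 0); expect_gt(sum(mJ), 0)
  lat_of <- function(m) mean(env$lat[which(m, arr.ind = TRUE)[, 1]])
  expect_gt(lat_of(mJ), lat_of(mL))
})
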