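# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data files.

make_samples <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(fish_id = r[[1]], region = r[[2]],
               capture_date = as.Date(r[[3]]),
               year_class = as.integer(r[[4]]), age = as.integer(r[[5]]),
               standard_length_mm = as.numeric(r[[6]]),
               batch_id = if (length(r) >= 7) r[[7]] else "b1",
               stringsAsFactors = FALSE)))
}

make_segments <- function(fish_id, bounds, d18O, d13C = NULL,
                          acid_temp = "25C", ages = NULL,
                          radius60 = NA_real_) {
  n <- length(bounds) - 1
  if (is.null(d13C)) d13C <- rep(-6, n)
  if (is.null(ages)) ages <- bounds / 5   # 5 um/day linear growth
  data.frame(fish_id = fish_id,
             dist_start_um = bounds[-length(bounds)],
             dist_end_um = bounds[-1],
             d18O_permil = d18O, d13C_permil = d13C,
             acid_temp = acid_temp,
             est_age_start_dph = ages[-length(ages)],
             est_age_end_dph = ages[-1],
             radius_at_60dph_um = radius60,
             stringsAsFactors = FALSE)
}

as_dataset <- function(samples, segments, corrected = TRUE) {
  ds <- structure(list(samples = samples, segments = segments,
                       rejects = data.frame(file = character(),
                                            line = integer(),
                                            reason = character())),
                  class = "otl_dataset")
  if (corrected) attr(ds, "acid_corrected") <- TRUE
  ds
}

# minimal stage_values row constructor for the classification tests
make_sv <- function(fish_id, region, age, year_class, larval_d18O,
                    larval_d13C = -6, juvenile_d18O = NA_real_,
                    radius = 300, label = "unclassified",
                    label_source = NA_character_, has_increments = TRUE) {
  sv <- data.frame(fish_id = fish_id, region = region, age = as.integer(age),
                   year_class = as.integer(year_class),
                   larval_d18O = larval_d18O, larval_d13C = larval_d13C,
                   juvenile_d18O = juvenile_d18O,
                   radius_at_60dph_um = radius,
                   has_increments = has_increments, label = label,
                   label_source = label_source, stringsAsFactors = FALSE)
  class(sv) <- c("stage_values", "data.frame")
  sv
}

# brute-force oracle for the window rescaling rule: filter segments by
# median-of-age-range in the closed window, width-weighted mean
bf_window <- function(seg, window, quantity = "d18O",
                      weight = "width_um") {
  num <- 0; den <- 0
  for (i in seq_len(nrow(seg))) {
    med <- (seg$est_age_start_dph[i] + seg$est_age_end_dph[i]) / 2
    if (!is.na(med) && med >= window[1] && med <= window[2]) {
      w <- if (weight == "width_um")
        seg$dist_end_um[i] - seg$dist_start_um[i]
      else seg$est_age_end_dph[i] - seg$est_age_start_dph[i]
      v <- if (quantity == "d18O") seg$d18O_permil[i] else
        seg$d13C_permil[i]
      num <- num + w * v; den <- den + w
    }
  }
  if (den == 0) NA_real_ else num / den
}

# random profile generator for property tests (ages consistent with
# distances under a random linear growth rate)
random_profile <- function(n_seg = 8, rate = runif(1, 3, 8)) {
  b <- cumsum(c(0, runif(n_seg, 20, 180)))
  make_segments("FX", b, d18O = rnorm(n_seg, -1, 0.5),
                d13C = rnorm(n_seg, -6, 0.5), ages = b / rate)
}

# brute-force studentized range CDF: P(Q_{k,df} <= q) by nested numerical
# integration of the standard double-integral definition
ptukey_bruteforce <- function(q, k, df) {
  range_cdf <- function(w) {
    if (w <= 0) return(0)
    k * stats::integrate(function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1),
      -Inf, Inf, rel.tol = 1e-10)$value
  }
  # density of S = sqrt(chi2_df / df)
  fs <- function(s) 2 * s * df * stats::dchisq(s^2 * df, df)
  stats::integrate(Vectorize(function(s) fs(s) * range_cdf(q * s)),
                   0, Inf, rel.tol = 1e-8)$value
}

# small random labeled cohort in stage_values form
random_labeled_sv <- function(n_local = 20, n_nonlocal = 15, seed = 1) {
  set.seed(seed)
  rbind(
    make_sv(sprintf("L%02d", 1:n_local), "OkiIslands", 1, 2015,
            rnorm(n_local, -0.7, 0.4), rnorm(n_local, -6.2, 0.4),
            juvenile_d18O = -1.5, radius = rnorm(n_local, 300, 30),
            label = "local", label_source = "threshold"),
    make_sv(sprintf("N%02d", 1:n_nonlocal), "NotoPeninsula", 1, 2015,
            rnorm(n_nonlocal, -0.3, 0.2), rnorm(n_nonlocal, -6.1, 0.4),
            juvenile_d18O = -0.2, radius = rnorm(n_nonlocal, 375, 35),
            label = "nonlocal", label_source = "threshold"))
}

expect_file_md5_equal <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
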