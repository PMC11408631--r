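#' Read, validate and write otolith sample datasets
#'
#' `load_dataset()` reads the two tabular artifacts of a study — a sample
#' metadata table and a micromill segment table — joins them on `fish_id`,
#' quarantines unparseable rows, and returns an `otl_dataset`.
#'
#' Expected CSV schemas (UTF-8, comma-separated, dot decimal, ISO-8601 dates):
#'
#' * `samples.csv`: `fish_id, region, capture_date, year_class, age,
#'   standard_length_mm, batch_id`
#' * `segments.csv`: `fish_id, dist_start_um, dist_end_um, d18O_permil,
#'   d13C_permil, acid_temp, est_age_start_dph, est_age_end_dph,
#'   radius_at_60dph_um` (the last three may be empty; `radius_at_60dph_um`
#'   is a per-fish value repeated on each of its rows)
#'
#' `region` must be one of `WestKyushu`, `OkiIslands`, `NotoPeninsula`,
#' `PacificOffshore`; `acid_temp` one of `25C`, `72C`.
#'
#' Rows that cannot be parsed (bad date, non-numeric measurement, unknown
#' factor level) are reported with their file line numbers and removed; they
#' never abort the load.  A missing mandatory column or a duplicated
#' `fish_id` in the sample table is a hard error.
#'
#' @param samples_path,segments_path paths to the two CSV files.
#' @return An object of class `otl_dataset`: a list with elements `samples`
#'   (data frame), `segments` (data frame ordered by fish and distance),
#'   `rejects` (data frame of quarantined rows with `file`, `line`, `reason`).
#' @seealso [validate_dataset()], [write_dataset()]
#' @export
load_dataset <- function(samples_path, segments_path) {
  samples_raw <- read.csv(samples_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  segments_raw <- read.csv(segments_path, stringsAsFactors = FALSE,
                           colClasses = "character")

  need_s <- c("fish_id", "region", "capture_date", "year_class", "age",
              "standard_length_mm", "batch_id")
  need_g <- c("fish_id", "dist_start_um", "dist_end_um", "d18O_permil",
              "d13C_permil", "acid_temp")
  miss <- setdiff(need_s, names(samples_raw))
  if (length(miss))
    stop("samples file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(need_g, names(segments_raw))
  if (length(miss))
    stop("segments file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(samples_raw$fish_id))
    stop("duplicate fish_id in samples: ",
         paste(unique(samples_raw$fish_id[duplicated(samples_raw$fish_id)]),
               collapse = ", "))

  rejects <- data.frame(file = character(), line = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  note <- function(file, line, reason) {
    rejects[nrow(rejects) + 1L, ] <<- list(file, line, reason)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  samples <- data.frame(
    fish_id = samples_raw$fish_id,
    region = samples_raw$region,
    capture_date = as.Date(samples_raw$capture_date, format = "%Y-%m-%d"),
    year_class = suppressWarnings(as.integer(samples_raw$year_class)),
    age = suppressWarnings(as.integer(samples_raw$age)),
    standard_length_mm = num(samples_raw$standard_length_mm),
    batch_id = samples_raw$batch_id,
    stringsAsFactors = FALSE
  )
  bad <- is.na(samples$capture_date) | is.na(samples$year_class) |
    is.na(samples$age) | !samples$age %in% c(0L, 1L) |
    is.na(samples$standard_length_mm) | !samples$region %in% ALL_REGIONS
  if (nrow(samples_raw) == 0) bad <- logical(0)
  for (i in which(bad)) note("samples", i + 1L, "unparseable or invalid row")
  samples <- samples[!bad, , drop = FALSE]

  opt_num <- function(col) {
    if (col %in% names(segments_raw)) num(segments_raw[[col]]) else
      rep(NA_real_, nrow(segments_raw))
  }
  segments <- data.frame(
    fish_id = segments_raw$fish_id,
    dist_start_um = num(segments_raw$dist_start_um),
    dist_end_um = num(segments_raw$dist_end_um),
    d18O_permil = num(segments_raw$d18O_permil),
    d13C_permil = num(segments_raw$d13C_permil),
    acid_temp = segments_raw$acid_temp,
    est_age_start_dph = opt_num("est_age_start_dph"),
    est_age_end_dph = opt_num("est_age_end_dph"),
    radius_at_60dph_um = opt_num("radius_at_60dph_um"),
    stringsAsFactors = FALSE
  )
  bad <- is.na(segments$dist_start_um) | is.na(segments$dist_end_um) |
    !is.finite(segments$d18O_permil) | !is.finite(segments$d13C_permil) |
    !segments$acid_temp %in% c("25C", "72C") |
    !segments$fish_id %in% samples$fish_id
  if (nrow(segments_raw) == 0) bad <- logical(0)
  for (i in which(bad)) note("segments", i + 1L, "unparseable or orphan row")
  segments <- segments[!bad, , drop = FALSE]
  segments <- segments[order(segments$fish_id, segments$dist_start_um), ,
                       drop = FALSE]
  rownames(samples) <- rownames(segments) <- NULL

  structure(list(samples = samples, segments = segments, rejects = rejects),
            class = "otl_dataset")
}

#' @export
print.otl_dataset <- function(x, ...) {
  cat("otl_dataset:", nrow(x$samples), "fish,",
      nrow(x$segments), "micromill segments,",
      nrow(x$rejects), "rejected rows\n")
  invisible(x)
}

#' Validate an otolith dataset against the sampling-protocol rules
#'
#' Checks, without mutating the data:
#' * the age assignment rule — age 0 iff standard length < 150 mm and
#'   capture month July--December; age 1 iff SL < 160 mm and capture month
#'   January--June (strict inequalities);
#' * year-class consistency — capture year for age 0, capture year − 1 for
#'   age 1;
#' * segment geometry — positive width, no overlap between the ordered
#'   segments of one fish;
#' * finite isotope values.
#'
#' @param dataset an `otl_dataset` from [load_dataset()] or
#'   [generate_cohort()].
#' @return A data frame of violations with columns `fish_id`, `rule`,
#'   `detail`; zero rows when the dataset is clean.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "otl_dataset"))
  v <- list()
  add <- function(fish_id, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(fish_id = fish_id, rule = rule,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  s <- dataset$samples
  if (nrow(s)) {
    month <- as.integer(format(s$capture_date, "%m"))
    yr <- as.integer(format(s$capture_date, "%Y"))
    ok0 <- s$standard_length_mm < 150 & month >= 7 & month <= 12
    ok1 <- s$standard_length_mm < 160 & month >= 1 & month <= 6
    for (i in seq_len(nrow(s))) {
      if (s$age[i] == 0L && !ok0[i])
        add(s$fish_id[i], "age/month rule",
            sprintf("age-0 fish with SL %.1f mm captured in month %d",
                    s$standard_length_mm[i], month[i]))
      if (s$age[i] == 1L && !ok1[i])
        add(s$fish_id[i], "age/month rule",
            sprintf("age-1 fish with SL %.1f mm captured in month %d",
                    s$standard_length_mm[i], month[i]))
      expect_yc <- yr[i] - s$age[i]
      if (s$year_class[i] != expect_yc)
        add(s$fish_id[i], "year-class rule",
            sprintf("year_class %d but capture year %d at age %d",
                    s$year_class[i], yr[i], s$age[i]))
    }
  }
  g <- dataset$segments
  if (nrow(g)) {
    neg <- g$dist_end_um <= g$dist_start_um
    for (i in which(neg))
      add(g$fish_id[i], "segment width",
          sprintf("non-positive width %.1f-%.1f um",
                  g$dist_start_um[i], g$dist_end_um[i]))
    for (id in unique(g$fish_id)) {
      gi <- g[g$fish_id == id, , drop = FALSE]
      gi <- gi[order(gi$dist_start_um), , drop = FALSE]
      if (nrow(gi) > 1) {
        ov <- gi$dist_start_um[-1] < gi$dist_end_um[-nrow(gi)] - 1e-9
        if (any(ov)) add(id, "segment overlap",
                         sprintf("%d overlapping segment pair(s)", sum(ov)))
      }
    }
    nf <- !is.finite(g$d18O_permil) | !is.finite(g$d13C_permil)
    for (i in which(nf)) add(g$fish_id[i], "non-finite isotope value", "")
  }
  if (!length(v))
    return(data.frame(fish_id = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Write a dataset back to its two CSV artifacts
#'
#' Inverse of [load_dataset()]: `write_dataset()` then `load_dataset()` is
#' the identity on all fields.
#'
#' @param dataset an `otl_dataset`.
#' @param samples_path,segments_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, samples_path, segments_path) {
  stopifnot(inherits(dataset, "otl_dataset"))
  s <- dataset$samples
  s$capture_date <- format(s$capture_date, "%Y-%m-%d")
  write.csv(s, samples_path, row.names = FALSE, quote = FALSE, na = "")
  write.csv(dataset$segments, segments_path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(c(samples_path, segments_path))
}

#' Write named result tables plus a JSON manifest
#'
#' Each table becomes `<name>.csv` under `out_dir`; the manifest records row
#' counts, file md5 checksums and an optional configuration hash, so a rerun
#' on identical inputs is bit-stable and verifiable.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list; hashed into the manifest.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (length(tables) && is.null(names(tables)))
    stop("tables must be a named list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    for (cl in names(tab)) if (inherits(tab[[cl]], "Date"))
      tab[[cl]] <- format(tab[[cl]], "%Y-%m-%d")
    write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
    entries[[nm]] <- list(file = basename(path), rows = nrow(tables[[nm]]),
                          md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(tables = entries,
                   config_hash = if (is.null(config)) NA_character_ else
                     config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the deparsed configuration; stable across sessions for plain lists
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Gridded temperature/salinity environment fields
#'
#' An `env_field` holds 10 m depth temperature and salinity on a regular
#' lat-lon grid with a daily time axis, plus an integer `region_id` per cell
#' used to look up region-specific salinity--seawater-delta-18O relations.
#'
#' @param lat,lon cell-center coordinate vectors (decimal degrees, strictly
#'   increasing, regular spacing; `lat` northward, `lon` eastward).
#' @param day `Date` vector (consecutive days).
#' @param temp,sal numeric arrays of dim `(day, lat, lon)`; `NA` marks
#'   missing cells (e.g. land).
#' @param region_id integer matrix of dim `(lat, lon)`; defaults to 1
#'   everywhere.
#' @return An object of class `env_field`.
#' @export
env_field <- function(lat, lon, day, temp, sal, region_id = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon), inherits(day, "Date"))
  dm <- c(length(day), length(lat), length(lon))
  if (!identical(dim(temp), as.integer(dm)))
    stop("temp must have dim (day, lat, lon) = (",
         paste(dm, collapse = ", "), ")")
  if (!identical(dim(sal), dim(temp)))
    stop("temp and sal arrays must share shape")
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("lat must be increasing")
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("lon must be increasing")
  if (is.null(region_id))
    region_id <- matrix(1L, length(lat), length(lon))
  structure(list(lat = lat, lon = lon, day = day, temp = temp, sal = sal,
                 region_id = region_id), class = "env_field")
}

#' @export
print.env_field <- function(x, ...) {
  cat(sprintf("env_field: %d days (%s..%s), %d x %d lat x lon grid\n",
              length(x$day), min(x$day), max(x$day),
              length(x$lat), length(x$lon)))
  invisible(x)
}

#' Read / write environment fields as netCDF
#'
#' Fields are stored with dims `(lon, lat, time)`, `time` in days since
#' 1970-01-01, variables `temp_10m` (degC), `sal_10m` (psu) and `region_id`,
#' and a `_FillValue` attribute honoured for missing data.
#'
#' @param path netCDF file path.
#' @param env an `env_field` (for writing).
#' @return `read_env_field()` returns an `env_field`; `write_env_field()`
#'   returns `path` invisibly.
#' @export
write_env_field <- function(env, path) {
  stopifnot(inherits(env, "env_field"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", env$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", env$lat)
  dtime <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(env$day), unlim = FALSE)
  fill <- 1e30
  vt <- ncdf4::ncvar_def("temp_10m", "degC", list(dlon, dlat, dtime), fill,
                         prec = "double")
  vs <- ncdf4::ncvar_def("sal_10m", "psu", list(dlon, dlat, dtime), fill,
                         prec = "double")
  vr <- ncdf4::ncvar_def("region_id", "", list(dlon, dlat), -1L,
                         prec = "integer")
  nc <- ncdf4::nc_create(path, list(vt, vs, vr))
  on.exit(ncdf4::nc_close(nc))
  # internal layout is (day, lat, lon); netCDF wants (lon, lat, time)
  perm <- function(a) aperm(a, c(3, 2, 1))
  ncdf4::ncvar_put(nc, vt, perm(env$temp))
  ncdf4::ncvar_put(nc, vs, perm(env$sal))
  ncdf4::ncvar_put(nc, vr, t(env$region_id))
  invisible(path)
}

#' @rdname write_env_field
#' @export
read_env_field <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  day <- as.Date(as.numeric(ncdf4::ncvar_get(nc, "time")),
                 origin = "1970-01-01")
  get3 <- function(v) {
    a <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)  # (lon, lat, time)
    aperm(a, c(3, 2, 1))
  }
  region <- ncdf4::ncvar_get(nc, "region_id", collapse_degen = FALSE)
  env_field(lat = lat, lon = lon, day = day,
            temp = get3("temp_10m"), sal = get3("sal_10m"),
            region_id = matrix(as.integer(t(region)), length(lat),
                               length(lon)))
}
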