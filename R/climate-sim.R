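#' Configuration for the synthetic climate grid
#'
#' Describes a regular lat-lon grid of monthly mean temperature and
#' precipitation. The temperature model is
#' `T(cell, month) = base_temp + base_gradient * (lat - mid_lat)
#'  + seasonal_amplitude * cos(2 * pi * (month - peak) / 12)
#'  + trend * decades_elapsed + a(cell, year) + e(cell, month)`
#' where `a` is a stationary AR(1) annual anomaly per cell (standard
#' deviation `interannual_sd`, lag-1 autocorrelation `ar1_coef`) and `e` is
#' independent monthly weather noise (`monthly_sd`). The seasonal peak month
#' is January for southern-hemisphere cells and July otherwise.
#' Precipitation is i.i.d. lognormal with the given mean and standard
#' deviation (mm/month).
#'
#' @param lat_range,lon_range Numeric length-2, degrees (cell centers span
#'   these ranges inclusive).
#' @param resolution Grid spacing in degrees; default 0.5.
#' @param start,end Length-2 integer `c(year, month)` bounds (inclusive).
#' @param base_temp Mean temperature at the latitudinal midpoint, degrees C.
#' @param base_gradient Degrees C per degree latitude.
#' @param seasonal_amplitude Seasonal half-range, degrees C.
#' @param interannual_sd Stationary SD of the annual AR(1) anomaly, degrees C.
#' @param ar1_coef Lag-1 autocorrelation of the annual anomaly, in `[0, 1)`.
#' @param trend Warming trend, degrees C per decade.
#' @param monthly_sd SD of independent monthly weather noise, degrees C.
#' @param precip_mean,precip_sd Precipitation mean and SD, mm/month.
#' @return A `climate_config` list.
#' @export
climate_config <- function(lat_range = c(-10, -5.5), lon_range = c(20, 24.5),
                           resolution = 0.5,
                           start = c(1985, 1), end = c(2014, 12),
                           base_temp = 25, base_gradient = -0.5,
                           seasonal_amplitude = 2, interannual_sd = 0.4,
                           ar1_coef = 0.4, trend = 0.15, monthly_sd = 1,
                           precip_mean = 80, precip_sd = 40) {
  cfg <- list(lat_range = lat_range, lon_range = lon_range,
              resolution = resolution, start = start, end = end,
              base_temp = base_temp, base_gradient = base_gradient,
              seasonal_amplitude = seasonal_amplitude,
              interannual_sd = interannual_sd, ar1_coef = ar1_coef,
              trend = trend, monthly_sd = monthly_sd,
              precip_mean = precip_mean, precip_sd = precip_sd)
  if (resolution <= 0) abort_hg("resolution must be > 0", "climate_config_error")
  if (ar1_coef < 0 || ar1_coef >= 1) {
    abort_hg("ar1_coef must be in [0, 1)", "climate_config_error")
  }
  if (ym_index(start[1], start[2]) > ym_index(end[1], end[2])) {
    abort_hg("start must precede end", "climate_config_error")
  }
  if (diff(lat_range) < 0 || diff(lon_range) < 0) {
    abort_hg("empty spatial extent", "climate_config_error")
  }
  structure(cfg, class = "climate_config")
}

#' Generate a synthetic monthly climate grid
#'
#' Realizes the process described in [climate_config()] on a regular grid.
#' Deterministic for a given `(config, seed)` pair; the climate stream is
#' independent of the cohort and crop streams derived from the same master
#' seed.
#'
#' @param config A [climate_config()].
#' @param seed Integer master seed.
#' @return A `climate_grid` object: list with `cells` (tibble `cell, lat,
#'   lon`), `months` (integer month indices, see [ym_index()]), `res`, and
#'   matrices `temp`, `precip` of dimension cells x months. Use
#'   [as_tibble()][tibble::as_tibble] for a long view.
#' @export
generate_climate_grid <- function(config, seed = 1) {
  stopifnot(inherits(config, "climate_config"))
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$resolution)
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$resolution)
  if (length(lat) == 0 || length(lon) == 0) {
    abort_hg("empty spatial extent", "climate_config_error")
  }
  cells <- tidyr::expand_grid(lat = lat, lon = lon)
  cells <- dplyr::mutate(cells, cell = dplyr::row_number(), .before = 1)
  months <- seq(ym_index(config$start[1], config$start[2]),
                ym_index(config$end[1], config$end[2]))
  nc <- nrow(cells); nm <- length(months)
  years <- unique(ym_year(months))
  ny <- length(years)

  withr::with_seed(substream_seed(seed, "climate"), {
    # annual AR(1) anomaly per cell, stationary SD = interannual_sd
    phi <- config$ar1_coef
    a <- matrix(0, nc, ny)
    if (config$interannual_sd > 0) {
      a[, 1] <- stats::rnorm(nc, 0, config$interannual_sd)
      if (ny > 1) {
        innov_sd <- config$interannual_sd * sqrt(1 - phi^2)
        for (y in 2:ny) a[, y] <- phi * a[, y - 1] + stats::rnorm(nc, 0, innov_sd)
      }
    }
    eps <- if (config$monthly_sd > 0) {
      matrix(stats::rnorm(nc * nm, 0, config$monthly_sd), nc, nm)
    } else matrix(0, nc, nm)
    precip <- if (config$precip_sd > 0) {
      sdlog <- sqrt(log(1 + (config$precip_sd / config$precip_mean)^2))
      meanlog <- log(config$precip_mean) - sdlog^2 / 2
      matrix(stats::rlnorm(nc * nm, meanlog, sdlog), nc, nm)
    } else matrix(config$precip_mean, nc, nm)

    mid_lat <- mean(config$lat_range)
    base <- config$base_temp + config$base_gradient * (cells$lat - mid_lat)
    peak <- ifelse(cells$lat < 0, 1, 7)
    mon <- ym_month(months)
    seas <- config$seasonal_amplitude *
      cos(2 * pi * outer(peak, mon, `-`) / 12)   # nc x nm
    trend <- config$trend * (months - months[1]) / 120
    temp <- matrix(base, nc, nm) + seas +
      matrix(trend, nc, nm, byrow = TRUE) +
      a[, match(ym_year(months), years), drop = FALSE] + eps
  })

  structure(list(cells = cells, months = months, res = config$resolution,
                 temp = temp, precip = precip, config = config),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf(
    "<climate_grid> %d cells (%.2f deg), %d months (%d-%02d to %d-%02d)\n",
    nrow(x$cells), x$res, length(x$months),
    ym_year(x$months[1]), ym_month(x$months[1]),
    ym_year(x$months[length(x$months)]), ym_month(x$months[length(x$months)])))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble climate_grid
#' @export
as_tibble.climate_grid <- function(x, ...) {
  long <- tidyr::expand_grid(cell = x$cells$cell, ym = x$months)
  long$lat <- x$cells$lat[long$cell]
  long$lon <- x$cells$lon[long$cell]
  long$year <- ym_year(long$ym)
  long$month <- ym_month(long$ym)
  long$temp <- as.vector(t(x$temp))[
    (long$cell - 1) * length(x$months) + match(long$ym, x$months)]
  long$precip <- as.vector(t(x$precip))[
    (long$cell - 1) * length(x$months) + match(long$ym, x$months)]
  tibble::as_tibble(long)
}

#' Write or read a climate grid as long CSV
#'
#' Interchange format: one row per (cell, month) with columns
#' `lat, lon, year, month, temp, precip`. The grid geometry (resolution,
#' extents) is recovered from the coordinates on read.
#'
#' @param grid A `climate_grid`.
#' @param path File path.
#' @return `read_climate_csv()` returns a `climate_grid`;
#'   `write_climate_csv()` returns `path` invisibly.
#' @export
write_climate_csv <- function(grid, path) {
  long <- as_tibble(grid)
  utils::write.csv(
    as.data.frame(long[, c("lat", "lon", "year", "month", "temp", "precip")]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  long <- utils::read.csv(path)
  lat <- sort(unique(long$lat)); lon <- sort(unique(long$lon))
  res <- if (length(lat) > 1) min(diff(lat)) else if (length(lon) > 1) min(diff(lon)) else 0.5
  cells <- tidyr::expand_grid(lat = lat, lon = lon)
  cells <- dplyr::mutate(cells, cell = dplyr::row_number(), .before = 1)
  long$ym <- ym_index(long$year, long$month)
  months <- sort(unique(long$ym))
  if (!all(diff(months) == 1L)) {
    abort_hg("climate CSV has temporal gaps", "climate_config_error")
  }
  key_cell <- match(paste(long$lat, long$lon), paste(cells$lat, cells$lon))
  idx <- cbind(key_cell, match(long$ym, months))
  temp <- matrix(NA_real_, nrow(cells), length(months)); temp[idx] <- long$temp
  precip <- matrix(NA_real_, nrow(cells), length(months)); precip[idx] <- long$precip
  if (any(is.na(temp))) abort_hg("climate CSV is not a complete grid",
                                 "climate_config_error")
  structure(list(cells = cells, months = months, res = res,
                 temp = temp, precip = precip, config = NULL),
            class = "climate_grid")
}

#' Regional monthly temperature projections
#'
#' Builds per-region monthly series for 2015-2100 as a synthetic stand-in
#' for an ensemble-mean climate projection: the year-2015 values equal the
#' region's recent monthly climatology exactly (mean over the grid's last
#' `clim_years` calendar years, averaged over the region's cells), and later
#' years add a linear warming ramp of `warming_per_decade * (year - 2015) /
#' 10`, plus optional i.i.d. noise for years after 2015.
#'
#' @param regions Tibble with columns `cell`, `region` mapping grid cells to
#'   named regions. Every region must own at least one cell.
#' @param grid A `climate_grid`.
#' @param warming_per_decade Degrees C per decade.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd SD of monthly noise added for years > 2015, degrees C.
#' @param years Projection years; default `2015:2100`.
#' @param clim_years Number of trailing grid years in the climatology.
#' @return Tibble `region, year, month, temp`.
#' @export
generate_projection_series <- function(regions, grid, warming_per_decade,
                                       seed = 1, noise_sd = 0,
                                       years = 2015:2100, clim_years = 10) {
  stopifnot(inherits(grid, "climate_grid"))
  if (!all(c("cell", "region") %in% names(regions))) {
    abort_hg("regions must have columns cell, region", "projection_input_error")
  }
  if (any(!regions$cell %in% grid$cells$cell)) {
    abort_hg("regions reference cells outside the grid", "projection_input_error")
  }
  grid_years <- unique(ym_year(grid$months))
  use_years <- utils::tail(grid_years, clim_years)
  keep <- ym_year(grid$months) %in% use_years
  mon <- ym_month(grid$months)[keep]

  out <- purrr::map_dfr(split(regions$cell, regions$region), function(cl) {
    if (length(cl) == 0) abort_hg("region with no cells", "projection_input_error")
    sub <- grid$temp[cl, keep, drop = FALSE]
    clim <- vapply(1:12, function(m) mean(sub[, mon == m, drop = FALSE]),
                   numeric(1))
    tidyr::expand_grid(year = years, month = 1:12) |>
      dplyr::mutate(temp = clim[.data$month] +
                      warming_per_decade * (.data$year - 2015) / 10)
  }, .id = "region")
  if (noise_sd > 0) {
    withr::with_seed(substream_seed(seed, "projection"), {
      noise <- stats::rnorm(nrow(out), 0, noise_sd)
    })
    out$temp <- out$temp + ifelse(out$year > 2015, noise, 0)
  }
  tibble::as_tibble(out)
}
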