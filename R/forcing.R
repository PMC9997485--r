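#' Configuration for the synthetic meteorological forcing generator
#'
#' Builds the parameter list consumed by [generate_forcing()]. Each
#' meteorological variable is modelled as an annual mean plus a seasonal
#' cosine cycle plus an AR(1) anomaly; air temperature additionally carries
#' a linear secular warming trend. Shortwave radiation is not drawn
#' independently: it is derived from the simulated cloud-cover series and
#' clear-sky solar geometry so that radiation, cloudiness and the cloud
#' estimator of [estimate_cloud_cover()] are mutually consistent.
#'
#' The defaults emulate a mid-latitude continental climate typical of the
#' north German lowlands (annual mean air temperature near 9.5 degC, July
#' maximum, mean wind speed near 3 m s^-1) driving a small monomictic
#' gravel-pit lake. The default warming trend of 0.035 degC a^-1 is the
#' preset's calibrated value reproducing an epilimnion warming rate near
#' 0.05 degC a^-1 over a four-decade simulation.
#'
#' @param start_year,end_year first and last simulated calendar year
#'   (inclusive); the series is daily.
#' @param latitude site latitude in degrees north, used for solar geometry.
#' @param air_temp_mean,air_temp_amp annual mean and seasonal half-amplitude
#'   of air temperature (degC).
#' @param air_temp_trend secular linear trend of air temperature
#'   (degC a^-1), applied centred on the period midpoint so that the
#'   configured annual mean is the whole-period mean.
#' @param air_temp_phi,air_temp_sd AR(1) coefficient (in `[0,1)`) and
#'   innovation standard deviation (degC) of the daily air-temperature
#'   anomaly.
#' @param wind_u_mean,wind_u_amp,wind_v_mean,wind_v_amp mean and seasonal
#'   half-amplitude of the E-W and N-S wind components (m s^-1).
#' @param wind_phi,wind_sd AR(1) coefficient and innovation sd of wind
#'   anomalies (m s^-1).
#' @param pressure_mean,pressure_amp,pressure_phi,pressure_sd air pressure
#'   climatology (hPa).
#' @param rh_mean,rh_amp,rh_phi,rh_sd relative humidity climatology (%);
#'   winter maximum (phase opposite to temperature).
#' @param cloud_mean,cloud_amp,cloud_phi,cloud_sd cloud fraction
#'   climatology (0-1), winter maximum.
#' @param precip_wet_prob,precip_mean_amount daily wet-day probability and
#'   mean wet-day precipitation (mm d^-1).
#' @param transmissivity clear-sky atmospheric transmissivity used to scale
#'   top-of-atmosphere radiation.
#' @param seed integer seed making the generated series reproducible.
#'
#' @return A list of class `"forcing_config"`.
#' @seealso [generate_forcing()], [make_picontrol_variants()]
#' @export
forcing_config <- function(start_year = 1980, end_year = 2021,
                           latitude = 52.2,
                           air_temp_mean = 9.5, air_temp_amp = 9.5,
                           air_temp_trend = 0.035,
                           air_temp_phi = 0.75, air_temp_sd = 1.7,
                           wind_u_mean = 2.4, wind_u_amp = 0.8,
                           wind_v_mean = 0.6, wind_v_amp = 0.4,
                           wind_phi = 0.7, wind_sd = 1.1,
                           pressure_mean = 1013, pressure_amp = 3,
                           pressure_phi = 0.8, pressure_sd = 4,
                           rh_mean = 78, rh_amp = 8,
                           rh_phi = 0.7, rh_sd = 5,
                           cloud_mean = 0.60, cloud_amp = 0.12,
                           cloud_phi = 0.6, cloud_sd = 0.15,
                           precip_wet_prob = 0.5,
                           precip_mean_amount = 2.2,
                           transmissivity = 0.75,
                           seed = 1L) {
  if (end_year < start_year)
    stop("period must span at least one year")
  phis <- c(air_temp_phi, wind_phi, pressure_phi, rh_phi, cloud_phi)
  if (any(phis < 0 | phis >= 1))
    stop("AR(1) coefficients must lie in [0, 1)")
  sds <- c(air_temp_sd, wind_sd, pressure_sd, rh_sd, cloud_sd)
  if (any(sds < 0))
    stop("noise standard deviations must be non-negative")
  if (abs(latitude) > 90)
    stop("latitude outside [-90, 90]")
  cfg <- as.list(environment())
  class(cfg) <- "forcing_config"
  cfg
}

## AR(1) anomaly series: phi * previous + innovation, stationary start.
ar1_series <- function(n, phi, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, sd = sd)
  x <- numeric(n)
  x[1] <- innov[1] / sqrt(1 - phi^2)
  if (n > 1) for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i]
  x
}

## Seasonal cosine with maximum at `peak_doy` (day of year).
seasonal_cycle <- function(doy, amp, peak_doy = 201) {
  amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Daily-mean clear-sky shortwave radiation
#'
#' Top-of-atmosphere daily-mean insolation from solar geometry (declination,
#' sunset hour angle, eccentricity correction) scaled by a fixed atmospheric
#' transmissivity.
#'
#' @param latitude degrees north.
#' @param doy day of year (1-366), vectorised.
#' @param transmissivity fraction of top-of-atmosphere radiation reaching
#'   the surface under clear sky (default 0.75).
#' @return clear-sky shortwave in W m^-2 (daily mean).
#' @export
clear_sky_radiation <- function(latitude, doy, transmissivity = 0.75) {
  if (abs(latitude) > 90) stop("latitude outside [-90, 90]")
  phi <- latitude * pi / 180
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  cos_ws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  ws <- acos(cos_ws)
  s0 <- 1361
  toa <- s0 / pi * e0 *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  pmax(0, transmissivity * toa)
}

#' Dew-point temperature from air temperature and relative humidity
#'
#' Magnus approximation: saturation vapour pressure
#' e_s(T) = 6.112 exp(17.62 T / (243.12 + T)) hPa, dew point is the
#' temperature at which e = rh/100 * e_s(T) saturates.
#'
#' @param air_temp air temperature (degC).
#' @param rel_humidity relative humidity (%), clamped to `[1, 100]` to keep
#'   the logarithm finite.
#' @return dew point (degC), never above `air_temp`.
#' @export
dewpoint_magnus <- function(air_temp, rel_humidity) {
  rh <- pmin(100, pmax(1, rel_humidity))
  a <- 17.62; b <- 243.12
  gamma <- log(rh / 100) + a * air_temp / (b + air_temp)
  pmin(air_temp, b * gamma / (a - gamma))
}

## Saturation vapour pressure (hPa), Magnus form.
sat_vapour_pressure <- function(temp) {
  6.112 * exp(17.62 * temp / (243.12 + temp))
}

#' Generate a synthetic daily meteorological forcing series
#'
#' Produces a daily `meteo_series` data frame over the configured period:
#' wind components, air temperature (seasonal cycle + centred linear trend +
#' AR(1) anomaly), pressure, relative humidity, cloud fraction, shortwave
#' radiation derived from cloud cover and clear-sky geometry through the
#' linear daily-mean attenuation `SW = SW_clear (1 - 0.75 c)`, precipitation
#' as a seeded wet-day/amount process, and a Magnus dew point consistent
#' with temperature and humidity. Anomalies are added to the deseasonalised
#' signal and physical bounds (humidity 0-100, cloud 0-1, non-negative
#' radiation and precipitation) are enforced by clamping, which the anomaly
#' construction keeps rare.
#'
#' The generator is fully deterministic given `config$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param config a [forcing_config()] object.
#' @return A data frame of class `"meteo_series"` with columns `date`,
#'   `wind_u`, `wind_v`, `air_temp`, `pressure`, `rel_humidity`, `dewpoint`,
#'   `shortwave`, `precip`, `cloud`, carrying `config` as an attribute.
#' @examples
#' met <- generate_forcing(forcing_config(1980, 1984, seed = 42))
#' range(met$rel_humidity)
#' @export
generate_forcing <- function(config) {
  stopifnot(inherits(config, "forcing_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31", config$end_year)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  t_years <- as.numeric(dates - dates[1]) / 365.25
  t_mid <- mean(t_years)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed)

  air_temp <- config$air_temp_mean +
    seasonal_cycle(doy, config$air_temp_amp) +
    config$air_temp_trend * (t_years - t_mid) +
    ar1_series(n, config$air_temp_phi, config$air_temp_sd)
  wind_u <- config$wind_u_mean +
    seasonal_cycle(doy, config$wind_u_amp, peak_doy = 15) +
    ar1_series(n, config$wind_phi, config$wind_sd)
  wind_v <- config$wind_v_mean +
    seasonal_cycle(doy, config$wind_v_amp, peak_doy = 15) +
    ar1_series(n, config$wind_phi, config$wind_sd)
  pressure <- config$pressure_mean +
    seasonal_cycle(doy, config$pressure_amp, peak_doy = 15) +
    ar1_series(n, config$pressure_phi, config$pressure_sd)
  rh <- config$rh_mean +
    seasonal_cycle(doy, config$rh_amp, peak_doy = 15) +
    ar1_series(n, config$rh_phi, config$rh_sd)
  rh <- pmin(100, pmax(0, rh))
  cloud <- config$cloud_mean +
    seasonal_cycle(doy, config$cloud_amp, peak_doy = 15) +
    ar1_series(n, config$cloud_phi, config$cloud_sd)
  cloud <- pmin(1, pmax(0, cloud))

  sw_clear <- clear_sky_radiation(config$latitude, doy, config$transmissivity)
  shortwave <- pmax(0, sw_clear * (1 - 0.75 * cloud))

  wet <- stats::runif(n) < config$precip_wet_prob
  precip <- ifelse(wet, stats::rexp(n, rate = 1 / config$precip_mean_amount), 0)

  out <- data.frame(
    date = dates,
    wind_u = wind_u, wind_v = wind_v,
    air_temp = air_temp,
    pressure = pressure,
    rel_humidity = rh,
    dewpoint = dewpoint_magnus(air_temp, rh),
    shortwave = shortwave,
    precip = precip,
    cloud = cloud
  )
  attr(out, "config") <- config
  class(out) <- c("meteo_series", "data.frame")
  out
}

#' Detrended counterfactual forcing variants
#'
#' Emulates pre-industrial control ("piControl") climate: each variant is
#' regenerated from the factual series' configuration with the secular
#' air-temperature trend removed and the anomaly noise re-drawn from a
#' distinct sub-seed. The variants are re-centred on the period-start
#' climatology (the factual trend term is applied centred on the period
#' midpoint, so the annual mean is shifted down by `trend * t_mid`): the
#' counterfactual climate stays at the level the factual climate had at
#' the start of the period, and the factual-minus-counterfactual
#' difference grows with the accumulated warming.
#'
#' @param forcing a `meteo_series` from [generate_forcing()].
#' @param n_variants number of counterfactual realisations (default 4).
#' @param seed integer; variant `i` uses sub-seed `seed + i`.
#' @return A list of `n_variants` `meteo_series` objects with identical
#'   timestamps and zero secular trend.
#' @export
make_picontrol_variants <- function(forcing, n_variants = 4, seed = 100L) {
  stopifnot(inherits(forcing, "meteo_series"))
  if (n_variants < 1) stop("n_variants must be >= 1")
  config <- attr(forcing, "config")
  if (is.null(config)) stop("forcing carries no generation config")
  dates <- forcing$date
  t_mid <- mean(as.numeric(dates - dates[1]) / 365.25)
  lapply(seq_len(n_variants), function(i) {
    cfg <- config
    cfg$air_temp_mean <- cfg$air_temp_mean - cfg$air_temp_trend * t_mid
    cfg$air_temp_trend <- 0
    cfg$seed <- as.integer(seed + i)
    generate_forcing(cfg)
  })
}

#' Fit a per-variable linear bias correction between two forcing series
#'
#' Ordinary least squares of the reference on the raw series, variable by
#' variable, over the overlapping timestamps. Used to emulate the chained
#' correction of reanalysis data against a station and of station data
#' against on-lake measurements.
#'
#' @param reference,raw `meteo_series` (or plain data frames with a `date`
#'   column) with overlapping dates.
#' @param variables character vector of columns to fit; defaults to all
#'   shared numeric columns.
#' @return An object of class `"bias_model"`: per variable the intercept,
#'   slope, residual standard deviation and correlation.
#' @export
fit_bias_correction <- function(reference, raw, variables = NULL) {
  common <- intersect(as.numeric(reference$date), as.numeric(raw$date))
  if (length(common) < 2) stop("no (or too short) timestamp overlap")
  iref <- match(common, as.numeric(reference$date))
  iraw <- match(common, as.numeric(raw$date))
  if (is.null(variables)) {
    variables <- intersect(names(reference), names(raw))
    variables <- variables[vapply(reference[variables], is.numeric, logical(1))]
    variables <- setdiff(variables, "date")
  }
  fits <- lapply(variables, function(v) {
    x <- raw[[v]][iraw]; y <- reference[[v]][iref]
    if (length(unique(x)) < 2)
      stop("raw series for '", v, "' is constant; slope undefined")
    fit <- stats::lm.fit(cbind(1, x), y)
    res <- fit$residuals
    list(intercept = unname(fit$coefficients[1]),
         slope = unname(fit$coefficients[2]),
         residual_sd = stats::sd(res),
         correlation = if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_)
  })
  names(fits) <- variables
  structure(list(coefficients = fits, n = length(common)),
            class = "bias_model")
}

#' Apply a fitted linear bias correction to a forcing series
#'
#' Maps each variable through `intercept + slope * raw` and re-clamps
#' physical bounds (relative humidity to 0-100, cloud to 0-1, shortwave and
#' precipitation to non-negative). Corrections chain: applying model B to
#' the output of model A equals the composed affine map on unclamped values.
#'
#' @param raw a `meteo_series` (or data frame) to correct.
#' @param model a `"bias_model"` from [fit_bias_correction()]; must cover
#'   every variable in `variables`.
#' @param variables columns to correct; defaults to all variables in the
#'   model that are present in `raw`.
#' @return The corrected series, same class and shape as `raw`.
#' @export
apply_bias_correction <- function(raw, model, variables = NULL) {
  stopifnot(inherits(model, "bias_model"))
  if (is.null(variables)) {
    variables <- intersect(names(model$coefficients), names(raw))
  }
  missing_v <- setdiff(variables, names(model$coefficients))
  if (length(missing_v))
    stop("model lacks coefficients for: ", paste(missing_v, collapse = ", "))
  out <- raw
  for (v in variables) {
    cf <- model$coefficients[[v]]
    out[[v]] <- cf$intercept + cf$slope * raw[[v]]
  }
  if ("rel_humidity" %in% variables)
    out$rel_humidity <- pmin(100, pmax(0, out$rel_humidity))
  if ("cloud" %in% variables)
    out$cloud <- pmin(1, pmax(0, out$cloud))
  for (v in intersect(c("shortwave", "precip"), variables))
    out[[v]] <- pmax(0, out[[v]])
  out
}

#' @export
print.bias_model <- function(x, ...) {
  cat("Linear bias-correction model (", x$n, " overlapping steps)\n", sep = "")
  tab <- do.call(rbind, lapply(x$coefficients, function(cf)
    data.frame(intercept = cf$intercept, slope = cf$slope,
               residual_sd = cf$residual_sd, r = cf$correlation)))
  print(round(tab, 4))
  invisible(x)
}

#' Estimate cloud cover from shortwave radiation, humidity and latitude
#'
#' Inverts the linear daily-mean cloud attenuation
#' `SW = SW_clear (1 - 0.75 c)` using the clear-sky radiation from
#' [clear_sky_radiation()]:
#' `c = (1 - SW/SW_clear)/0.75`, then applies a mild humidity
#' adjustment `c * (1 + 0.2 (RH - 70)/100)` (neutral at 70 % relative
#' humidity) and clamps to `[0, 1]`. Steps with no modelled daylight
#' (polar night) are filled by linear interpolation from neighbouring
#' values.
#'
#' @param latitude degrees north.
#' @param series a `meteo_series` with `shortwave` and `rel_humidity`.
#' @return numeric vector of cloud fractions in `[0, 1]`, one per row.
#' @export
estimate_cloud_cover <- function(latitude, series) {
  if (abs(latitude) > 90) stop("latitude outside [-90, 90]")
  if (is.null(series$shortwave) || is.null(series$rel_humidity))
    stop("series must contain shortwave and rel_humidity")
  doy <- as.integer(format(series$date, "%j"))
  cfg <- attr(series, "config")
  tau <- if (!is.null(cfg)) cfg$transmissivity else 0.75
  sw_clear <- clear_sky_radiation(latitude, doy, tau)
  ratio <- ifelse(sw_clear > 1, series$shortwave / sw_clear, NA_real_)
  cc <- pmax(0, pmin(1, (1 - pmin(1, ratio)) / 0.75))
  cc <- cc * (1 + 0.2 * (series$rel_humidity - 70) / 100)
  cc <- pmin(1, pmax(0, cc))
  if (anyNA(cc)) {
    idx <- seq_along(cc)
    ok <- !is.na(cc)
    if (!any(ok)) stop("no daylight steps to estimate cloud cover from")
    cc[!ok] <- stats::approx(idx[ok], cc[ok], xout = idx[!ok], rule = 2)$y
  }
  cc
}

#' Write / read a forcing series as CSV
#'
#' Plain-text interchange: ISO-8601 dates, one column per variable.
#'
#' @param series a `meteo_series`.
#' @param path file path.
#' @return `read_meteo_csv` returns a `meteo_series`;
#'   `write_meteo_csv` returns `path` invisibly.
#' @export
write_meteo_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meteo_csv
#' @export
read_meteo_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  class(df) <- c("meteo_series", "data.frame")
  df
}

## Validate the structural invariants of a meteo series; used by tests and
## defensive checks in the simulator.
check_meteo_series <- function(series) {
  stopifnot(
    all(diff(as.numeric(series$date)) == diff(as.numeric(series$date))[1]),
    all(series$rel_humidity >= 0 & series$rel_humidity <= 100),
    all(series$cloud >= 0 & series$cloud <= 1),
    all(series$shortwave >= 0),
    all(series$precip >= 0)
  )
  invisible(TRUE)
}
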