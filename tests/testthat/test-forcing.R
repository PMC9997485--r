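test_that("generation is deterministic and respects physical bounds", {
  cfg <- forcing_config(1990, 1994, seed = 42)
  a <- generate_forcing(cfg)
  b <- generate_forcing(cfg)
  expect_identical(a, b)
  expect_true(all(a$rel_humidity >= 0, a$rel_humidity <= 100,
                  a$cloud >= 0, a$cloud <= 1,
                  a$shortwave >= 0, a$precip >= 0))
  expect_equal(unique(diff(as.numeric(a$date))), 1)
  ## generator leaves the caller's RNG stream untouched
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generate_forcing(cfg)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("meteo invariants hold across random configurations", {
  set.seed(99)
  for (i in 1:8) {
    cfg <- forcing_config(
      2000, 2001,
      air_temp_mean = runif(1, 5, 15), air_temp_amp = runif(1, 5, 12),
      air_temp_trend = runif(1, 0, 0.1),
      air_temp_phi = runif(1, 0, 0.95), air_temp_sd = runif(1, 0, 4),
      rh_sd = runif(1, 0, 12), cloud_sd = runif(1, 0, 0.3),
      seed = i)
    m <- generate_forcing(cfg)
    expect_true(all(m$rel_humidity >= 0 & m$rel_humidity <= 100))
    expect_true(all(m$cloud >= 0 & m$cloud <= 1))
    expect_true(all(m$shortwave >= 0))
    expect_true(all(m$precip >= 0))
    expect_true(all(m$dewpoint <= m$air_temp + 1e-9))
  }
})

test_that("noise-free series are periodic and the trend is linear", {
  cfg <- forcing_config(1980, 2019, air_temp_trend = 0,
                        air_temp_sd = 0, wind_sd = 0, pressure_sd = 0,
                        rh_sd = 0, cloud_sd = 0, seed = 1)
  m <- generate_forcing(cfg)
  yr <- as.integer(format(m$date, "%Y"))
  doy <- as.integer(format(m$date, "%j"))
  y1 <- m$air_temp[yr == 1980 & doy <= 365]
  y40 <- m$air_temp[yr == 2019 & doy <= 365]
  expect_equal(y1, y40, tolerance = 1e-12)

  cfg2 <- forcing_config(1980, 2019, air_temp_trend = 0.04,
                         air_temp_sd = 0, wind_sd = 0, pressure_sd = 0,
                         rh_sd = 0, cloud_sd = 0, seed = 1)
  m2 <- generate_forcing(cfg2)
  d <- mean(m2$air_temp[yr == 2019]) - mean(m2$air_temp[yr == 1980])
  expect_equal(d, 39 * 0.04, tolerance = 0.02)
})

test_that("AR(1) anomaly recovers its lag-1 autocorrelation", {
  ## Monte-Carlo check against the stated AR(1) process, ~10^4 steps
  cfg <- forcing_config(1980, 2007, air_temp_trend = 0,
                        air_temp_phi = 0.8, air_temp_sd = 1,
                        seed = 5)
  m <- generate_forcing(cfg)
  doy <- as.integer(format(m$date, "%j"))
  clim <- ave(m$air_temp, doy)                   # remove seasonal cycle
  resid <- m$air_temp - clim
  r1 <- stats::cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(r1 - 0.8), 0.05)
})

test_that("configuration errors are rejected", {
  expect_error(forcing_config(2000, 1999), "period")
  expect_error(forcing_config(air_temp_phi = 1), "AR\\(1\\)")
  expect_error(forcing_config(air_temp_sd = -1), "non-negative")
  expect_error(clear_sky_radiation(95, 100), "latitude")
})

test_that("piControl variants detrend, re-noise and preserve structure", {
  fac <- generate_forcing(forcing_config(1980, 2019,
                                         air_temp_trend = 0.04, seed = 3))
  vars <- make_picontrol_variants(fac, n_variants = 4, seed = 50)
  expect_length(vars, 4)
  for (v in vars) expect_identical(v$date, fac$date)
  ## pairwise different noise realisations
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(isTRUE(all.equal(vars[[i]]$air_temp,
                                  vars[[j]]$air_temp)))
  ## Sen's slope of annual means not significantly different from zero
  yr <- as.integer(format(fac$date, "%Y"))
  for (v in vars) {
    ann <- tapply(v$air_temp, yr, mean)
    mk <- mann_kendall(ann)
    expect_gt(mk$p, 0.05)
  }
  ## trendless input: variants differ only in noise, trend stays ~0
  fac0 <- generate_forcing(forcing_config(1980, 2019,
                                          air_temp_trend = 0, seed = 3))
  v0 <- make_picontrol_variants(fac0, 1, seed = 50)[[1]]
  ann0 <- tapply(v0$air_temp, yr, mean)
  expect_lt(abs(sen_slope(ann0)), 0.02)
  expect_error(make_picontrol_variants(fac, 0), "n_variants")
})

test_that("bias correction recovers exact and noisy linear relations", {
  raw <- generate_forcing(forcing_config(1995, 1999, seed = 8))
  ## identity
  m_id <- fit_bias_correction(raw, raw)
  for (cf in m_id$coefficients) {
    expect_equal(cf$intercept, 0, tolerance = 1e-8)
    expect_equal(cf$slope, 1, tolerance = 1e-10)
  }
  expect_equal(apply_bias_correction(raw, m_id), raw, tolerance = 1e-9)

  ## exact affine relation: intercept 1, slope 2, residual sd 0
  ref <- raw
  ref$air_temp <- 2 * raw$air_temp + 1
  m <- fit_bias_correction(ref, raw, variables = "air_temp")
  expect_equal(m$coefficients$air_temp$intercept, 1, tolerance = 1e-8)
  expect_equal(m$coefficients$air_temp$slope, 2, tolerance = 1e-10)
  expect_equal(m$coefficients$air_temp$residual_sd, 0, tolerance = 1e-8)
  rt <- apply_bias_correction(raw, m, "air_temp")
  expect_equal(rt$air_temp, ref$air_temp, tolerance = 1e-9)

  ## noisy recovery of (a, b) = (0.5, 1.1) at n = 1000
  set.seed(21)
  n <- 1000
  base <- data.frame(date = as.Date("2000-01-01") + 0:(n - 1),
                     air_temp = rnorm(n, 10, 5))
  refn <- base
  refn$air_temp <- 0.5 + 1.1 * base$air_temp + rnorm(n, 0, 0.5)
  mn <- fit_bias_correction(refn, base, "air_temp")
  expect_lt(abs(mn$coefficients$air_temp$intercept - 0.5), 0.05)
  expect_lt(abs(mn$coefficients$air_temp$slope - 1.1), 0.05)

  ## chaining equals the composed affine map
  m1 <- list(coefficients = list(air_temp = list(intercept = 1, slope = 2)))
  m2 <- list(coefficients = list(air_temp = list(intercept = -3,
                                                 slope = 0.5)))
  class(m1) <- class(m2) <- "bias_model"
  once <- apply_bias_correction(
    apply_bias_correction(base, m1, "air_temp"), m2, "air_temp")
  expect_equal(once$air_temp, -3 + 0.5 * (1 + 2 * base$air_temp),
               tolerance = 1e-12)

  expect_error(fit_bias_correction(refn, transform(base, air_temp = 1),
                                   "air_temp"), "constant")
  expect_error(apply_bias_correction(base, m1, "wind_u"), "lacks")
})

test_that("cloud-cover estimation matches its documented mapping", {
  dates <- seq(as.Date("2005-06-01"), as.Date("2005-06-30"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  cs <- clear_sky_radiation(52.2, doy)
  ## half of clear-sky, neutral humidity -> c = (1 - 0.5)/0.75
  s <- data.frame(date = dates, shortwave = 0.5 * cs, rel_humidity = 70)
  cc <- estimate_cloud_cover(52.2, s)
  expect_equal(cc, rep(0.5 / 0.75, length(cc)), tolerance = 1e-10)
  ## clear-sky limit and overcast limit
  s$shortwave <- cs
  expect_equal(estimate_cloud_cover(52.2, s), rep(0, length(cc)))
  s$shortwave <- 0
  expect_equal(estimate_cloud_cover(52.2, s), rep(1, length(cc)))
  ## round trip through the generator's own attenuation
  m <- generate_forcing(forcing_config(2000, 2000, cloud_sd = 0.1,
                                       seed = 2))
  est <- estimate_cloud_cover(52.2, m)
  mid <- m$rel_humidity > 60 & m$rel_humidity < 80 & m$cloud < 0.9
  expect_lt(stats::median(abs(est[mid] - m$cloud[mid])), 0.08)
})

test_that("dew point follows the Magnus relation", {
  expect_equal(dewpoint_magnus(20, 100), 20, tolerance = 1e-6)
  expect_lt(dewpoint_magnus(20, 50), 20)
  ## consistency: saturation pressure at dew point = rh% of saturation
  td <- dewpoint_magnus(15, 60)
  expect_equal(relake:::sat_vapour_pressure(td),
               0.6 * relake:::sat_vapour_pressure(15), tolerance = 1e-3)
})

test_that("meteo CSV round-trips", {
  m <- generate_forcing(forcing_config(2001, 2001, seed = 4))
  path <- tempfile(fileext = ".csv")
  write_meteo_csv(m, path)
  m2 <- read_meteo_csv(path)
  expect_equal(as.data.frame(m)[, -1], as.data.frame(m2)[, -1],
               tolerance = 1e-6)
  expect_identical(m$date, m2$date)
})
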