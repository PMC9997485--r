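#' Assemble a complete lake-model configuration
#'
#' Bundles the forcing, grid, physical and biogeochemical parameters,
#' external loading, intervention events and initial state into one run
#' specification.
#'
#' @param forcing a `meteo_series` from [generate_forcing()] (daily).
#' @param grid a [build_grid()] object.
#' @param physics a [physics_params()] object.
#' @param eco an [eco_params()] object.
#' @param loading a [loading_spec()] object.
#' @param events list of [intervention_event()]s (may be empty).
#' @param bio_init initial [bio_state()] matrix.
#' @param sed_init initial [sed_state()].
#' @param spinup_years integer; the first forcing year is recycled this
#'   many times before the output window starts, and the spin-up output is
#'   discarded.
#' @param budget_tol relative mass-balance tolerance checked yearly at run
#'   time; a violation aborts with a per-element budget report.
#' @return list of class `"lake_config"`.
#' @export
lake_config <- function(forcing, grid = build_grid(),
                        physics = physics_params(), eco = eco_params(),
                        loading = loading_spec(),
                        events = historical_events(),
                        bio_init = bio_state(grid),
                        sed_init = sed_state(),
                        spinup_years = 2, budget_tol = 1e-6) {
  stopifnot(inherits(forcing, "meteo_series"))
  cfg <- list(forcing = forcing, grid = grid, physics = physics, eco = eco,
              loading = loading, events = events, bio_init = bio_init,
              sed_init = sed_init, spinup_years = spinup_years,
              budget_tol = budget_tol)
  class(cfg) <- "lake_config"
  cfg
}

#' The "barleber" experiment preset
#'
#' One canonical configuration encoding the study-lake morphometry
#' (103 ha, 11 m maximum / 6.7 m mean depth), groundwater inflow
#' (640,000 m^3 a^-1 into the bottom layer), external P budget
#' (42 + 26 + 10 kg P a^-1), sediment P release rate (7.2e-5 m^2 d^-1)
#' and the historical event sequence (P precipitation 1986, internal
#' loading onset 2016, P precipitation 2019), driven by the synthetic
#' factual forcing.
#'
#' @param forcing optional `meteo_series`; generated from
#'   [forcing_config()] defaults (warming trend on) when omitted.
#' @param seed forcing seed when `forcing` is omitted; the default, 1,
#'   defines the preset's canonical factual weather realisation.
#' @param start_year,end_year forcing period when generated here.
#' @param grid a [build_grid()] object.
#' @param bio_init initial biogeochemical state; defaults to the eutrophic
#'   1980 state of the study template.
#' @param ... passed on to [lake_config()].
#' @return a `"lake_config"`.
#' @export
barleber_preset <- function(forcing = NULL, seed = 1L,
                            start_year = 1980, end_year = 2021,
                            grid = build_grid(),
                            bio_init = bio_state(grid, srp = 0.10,
                                                 no3 = 1.0, si = 2.0,
                                                 diat = 3, green = 3,
                                                 cyano = 3),
                            ...) {
  if (is.null(forcing))
    forcing <- generate_forcing(forcing_config(
      start_year = start_year, end_year = end_year, seed = seed))
  lake_config(forcing = forcing, grid = grid, bio_init = bio_init, ...)
}

#' Run the coupled lake model
#'
#' Integrates the thermal and biogeochemical model day by day over the
#' forcing period, preceded by a spin-up in which the first forcing year
#' is recycled `spinup_years` times with outputs discarded. Each day the
#' model applies, in order: intervention events falling on that date;
#' surface heat fluxes and shortwave deposition; implicit vertical
#' diffusion of heat and all dissolved/particulate fields with the
#' stability-damped eddy diffusivity; convective adjustment; the
#' groundwater through-flow (bottom inflow, surface withdrawal); and the
#' biogeochemical process kernel with settling and external loads. A
#' yearly mass-balance audit compares the stored element totals with the
#' cumulative external exchanges and aborts on drift beyond
#' `budget_tol`.
#'
#' @param config a [lake_config()] (e.g. from [barleber_preset()]).
#' @param store character vector of per-layer fields to keep as
#'   days-by-layers matrices (default all state fields plus temperature).
#' @return An object of class `"lake_run"`: `dates`, `fields` (list of
#'   matrices), `sediment` (days x 4), `diag` (daily diagnostics data
#'   frame), `derived` (daily band means: surface 0-1 m cyanobacteria,
#'   epilimnion 0-2 m temperature, bottom 8-10 m TP, whole-lake
#'   volume-weighted temperature and oxygen), `annual` (calendar-year
#'   means plus the annual internal P load), the `grid` and the `config`.
#' @export
run_lake <- function(config,
                     store = c("temp", BIO_FIELDS)) {
  stopifnot(inherits(config, "lake_config"))
  grid <- config$grid
  pp <- config$physics
  ep <- config$eco
  n <- grid$n_layers
  forcing <- config$forcing
  check_meteo_series(forcing)
  dates <- forcing$date
  nd <- length(dates)
  yr <- as.integer(format(dates, "%Y"))

  ## forcing columns as plain vectors (fast row access)
  f_wu <- forcing$wind_u; f_wv <- forcing$wind_v
  f_ta <- forcing$air_temp; f_pr <- forcing$pressure
  f_dp <- forcing$dewpoint; f_sw <- forcing$shortwave
  f_cl <- forcing$cloud
  f_doy <- as.integer(format(dates, "%j"))
  wind10 <- sqrt(f_wu^2 + f_wv^2)

  ## day indices: spin-up recycles the first calendar year
  first_year_idx <- which(yr == yr[1])
  plan <- c(rep(first_year_idx, config$spinup_years), seq_len(nd))
  record <- c(rep(FALSE, length(first_year_idx) * config$spinup_years),
              rep(TRUE, nd))

  ## per-year daily surface loads (mg L^-1 d^-1 in the surface layer)
  ld <- config$loading
  v1 <- grid$volume[1]
  year_days <- table(yr)
  surf_load <- function(kg_per_day) kg_per_day * 1000 / v1   # mg L^-1 d^-1
  gw_cin <- numeric(length(BIO_FIELDS)); names(gw_cin) <- BIO_FIELDS
  gw_cin["srp"] <- ld$gw_conc[["srp"]]
  gw_cin["no3"] <- ld$gw_conc[["tn"]] * ld$gw_no3_frac
  gw_cin["nh4"] <- ld$gw_conc[["tn"]] * (1 - ld$gw_no3_frac)
  gw_cin["si"] <- ld$gw_conc[["si"]]
  gw_cin["do"] <- 6
  c_in <- c(pp$gw_temp, gw_cin)                      # temp first
  q_day <- ld$inflow * 86400                         # m^3 d^-1

  ## event schedule (main period only)
  evts <- config$events
  evt_idx <- if (length(evts))
    vapply(evts, function(e) {
      i <- match(e$date, dates)
      if (is.na(i)) -1L else i
    }, integer(1)) else integer(0)
  k_diff_ref <- ep$k_diff

  bio <- config$bio_init
  sed <- config$sed_init
  temp <- rep(mean(f_ta[first_year_idx]), n)
  temp <- pmax(4, temp)

  keep <- intersect(store, c("temp", BIO_FIELDS))
  out <- lapply(keep, function(x) matrix(NA_real_, nd, n))
  names(out) <- keep
  sed_out <- matrix(NA_real_, nd, 4,
                    dimnames = list(NULL, c("org_p", "p_exch", "org_n",
                                            "bio_si")))
  diag_out <- data.frame(p_flux_pos = rep(NA_real_, nd),
                         p_flux_net = NA_real_, thermocline = NA_real_,
                         k_diff = NA_real_)

  ## cumulative external exchanges for the mass audit (kg)
  ext <- c(P = 0, N = 0, Si = 0)
  removed <- c(P = 0, N = 0, Si = 0)
  budget0 <- element_budget(bio, sed, grid, ep)
  next_audit <- 365L
  steps_done <- 0L

  for (s in seq_along(plan)) {
    d <- plan[s]
    rec <- record[s]

    ## -- intervention events (main period only) --------------------------
    if (rec && length(evt_idx) && any(evt_idx == d)) {
      for (e in which(evt_idx == d)) {
        before <- element_budget(bio, sed, grid, ep)
        r <- apply_intervention(ep, bio, evts[[e]], k_diff_ref)
        ep <- r$params; bio <- r$bio
        after <- element_budget(bio, sed, grid, ep)
        removed <- removed + (before - after)
      }
    }

    ## -- physics ----------------------------------------------------------
    met <- list(wind_u = f_wu[d], wind_v = f_wv[d], air_temp = f_ta[d],
                pressure = f_pr[d], dewpoint = f_dp[d],
                shortwave = f_sw[d], cloud = f_cl[d])
    chl <- bio[, "diat"] + bio[, "green"] + bio[, "cyano"]
    hf <- surface_heat_flux(met, temp[1], pp)
    lp <- light_profile(hf$shortwave * (1 - pp$beta_sw), chl,
                        pp$kd_background, pp$kd_chl, grid$dz)
    ein <- lp$interface * grid$area
    sw_heat <- ein[-(n + 1)] - ein[-1]
    sw_heat[n] <- sw_heat[n] + ein[n + 1]
    sw_heat[1] <- sw_heat[1] + hf$shortwave * pp$beta_sw * grid$area[1]
    nonpen <- (hf$longwave + hf$sensible + hf$latent) * grid$area[1]
    temp <- temp + (sw_heat + c(nonpen, rep(0, n - 1))) * 86400 /
      (4.186e6 * grid$volume)

    kz <- eddy_diffusivity(temp, grid, wind10[d], pp)
    fields <- cbind(temp, bio)
    fields <- diffuse_implicit(fields, grid, kz, 1)
    fields <- convective_adjust(fields, grid)
    ext["P"] <- ext["P"] + q_day *
      (c_in[["srp"]] - fields[1, 1 + match("srp", BIO_FIELDS)] -
         fields[1, 1 + match("dop", BIO_FIELDS)] -
         (fields[1, 1 + match("detc", BIO_FIELDS)] +
            (fields[1, 1 + match("diat", BIO_FIELDS)] +
               fields[1, 1 + match("green", BIO_FIELDS)] +
               fields[1, 1 + match("cyano", BIO_FIELDS)]) * ep$c_per_chl +
            fields[1, 1 + match("daph", BIO_FIELDS)] +
            fields[1, 1 + match("meso", BIO_FIELDS)]) * ep$pc) / 1000
    ext["N"] <- ext["N"] + q_day *
      (c_in[["no3"]] + c_in[["nh4"]] -
         fields[1, 1 + match("nh4", BIO_FIELDS)] -
         fields[1, 1 + match("no3", BIO_FIELDS)] -
         (fields[1, 1 + match("detc", BIO_FIELDS)] +
            (fields[1, 1 + match("diat", BIO_FIELDS)] +
               fields[1, 1 + match("green", BIO_FIELDS)] +
               fields[1, 1 + match("cyano", BIO_FIELDS)]) * ep$c_per_chl +
            fields[1, 1 + match("daph", BIO_FIELDS)] +
            fields[1, 1 + match("meso", BIO_FIELDS)]) * ep$nc) / 1000
    ext["Si"] <- ext["Si"] + q_day *
      (c_in[["si"]] - fields[1, 1 + match("si", BIO_FIELDS)] -
         fields[1, 1 + match("detsi", BIO_FIELDS)] -
         fields[1, 1 + match("diat", BIO_FIELDS)] * ep$c_per_chl *
           ep$sic_diat) / 1000
    fields <- advect_throughflow(fields, grid, q_day, c_in, 1)
    temp <- pmax(0, fields[, 1])
    bio <- fields[, -1, drop = FALSE]
    bio[bio < 0 & bio > -1e-11] <- 0

    ## -- biogeochemistry --------------------------------------------------
    nd_year <- as.integer(year_days[[as.character(yr[d])]])
    loads <- list(
      srp = c(surf_load(ld$tp_diffusive / nd_year), rep(0, n - 1)),
      no3 = c(surf_load(ld$tn_deposition / nd_year), rep(0, n - 1)),
      detc = c(surf_load(ld$tp_atmospheric / nd_year) / ep$pc,
               rep(0, n - 1)))
    ext["P"] <- ext["P"] + (ld$tp_diffusive + ld$tp_atmospheric) / nd_year
    ext["N"] <- ext["N"] + ld$tn_deposition / nd_year +
      ld$tp_atmospheric / nd_year * ep$nc / ep$pc
    r <- step_ecosystem(bio, sed, list(temp = temp, par = lp$layer *
                                         pp$par_frac / (1 - pp$beta_sw)),
                        grid, loads = loads, dt = 1, params = ep,
                        wind = wind10[d], doy = f_doy[d])
    bio <- r$bio; sed <- r$sed
    ext["N"] <- ext["N"] - r$diag$denit_n

    if (rec) {
      for (f in keep) {
        out[[f]][d, ] <- if (f == "temp") temp else bio[, f]
      }
      sed_out[d, ] <- c(sed$org_p, sed$p_exch, sed$org_n, sed$bio_si)
      diag_out$p_flux_pos[d] <- r$diag$p_flux_pos
      diag_out$p_flux_net[d] <- r$diag$p_flux_net
      rho <- water_density(temp)
      diag_out$thermocline[d] <-
        grid$z_mid[which.max(c(0, diff(rho) / diff(grid$z_mid)))]
      diag_out$k_diff[d] <- ep$k_diff
    }

    ## -- yearly mass audit ------------------------------------------------
    steps_done <- steps_done + 1L
    if (steps_done >= next_audit) {
      next_audit <- next_audit + 365L
      now <- element_budget(bio, sed, grid, ep)
      drift <- abs(now - budget0 - ext + removed) / pmax(abs(now), 1)
      if (any(drift > config$budget_tol)) {
        stop(sprintf(
          "mass-balance violation: rel. drift P=%.2e N=%.2e Si=%.2e",
          drift[["P"]], drift[["N"]], drift[["Si"]]))
      }
    }
  }

  res <- structure(
    list(dates = dates, grid = grid, fields = out, sediment = sed_out,
         diag = diag_out, config = config),
    class = "lake_run")
  res$derived <- derive_bands(res)
  res$annual <- annual_summary(res)
  res
}

## Daily band means used throughout the scenario analysis.
derive_bands <- function(run) {
  grid <- run$grid
  ep <- run$config$eco
  tp <- run$fields$srp + run$fields$dop +
    (run$fields$detc +
       (run$fields$diat + run$fields$green + run$fields$cyano) *
         ep$c_per_chl + run$fields$daph + run$fields$meso) * ep$pc
  data.frame(
    date = run$dates,
    surface_cyano = extract_band(run$fields$cyano, grid, c(0, 1)),
    epi_temp = extract_band(run$fields$temp, grid, c(0, 2)),
    bottom_tp = extract_band(tp, grid, c(8, 10)),
    wl_temp = extract_band(run$fields$temp, grid),
    wl_do = extract_band(run$fields$do, grid),
    wl_tp = extract_band(tp, grid),
    surface_diat = extract_band(run$fields$diat, grid, c(0, 1)),
    surface_green = extract_band(run$fields$green, grid, c(0, 1)),
    p_flux_pos = run$diag$p_flux_pos
  )
}

## Calendar-year means of the derived bands plus the internal P load.
annual_summary <- function(run) {
  der <- run$derived
  yr <- as.integer(format(der$date, "%Y"))
  agg <- stats::aggregate(der[, setdiff(names(der), "date")],
                          by = list(year = yr), FUN = mean)
  load <- tryCatch(
    annual_internal_load(run$diag$p_flux_pos, run$dates, run$grid),
    error = function(e) NULL)
  agg$internal_p_load <- if (!is.null(load))
    load[match(agg$year, as.integer(names(load)))] else NA_real_
  agg
}

#' @export
print.lake_run <- function(x, ...) {
  cat(sprintf("Lake model run: %s to %s (%d days, %d layers)\n",
              format(min(x$dates)), format(max(x$dates)),
              length(x$dates), x$grid$n_layers))
  yrs <- range(x$annual$year)
  cat(sprintf("  whole-lake mean T %.2f degC, DO %.2f mg/L\n",
              mean(x$derived$wl_temp), mean(x$derived$wl_do)))
  cat(sprintf("  mean internal P load %.0f kg/a (years %d-%d)\n",
              mean(x$annual$internal_p_load, na.rm = TRUE), yrs[1], yrs[2]))
  invisible(x)
}

#' @export
summary.lake_run <- function(object, ...) {
  a <- object$annual
  cat("Annual summary (calendar-year means):\n")
  print(round(a, 3), row.names = FALSE)
  invisible(a)
}

#' @export
plot.lake_run <- function(x, variable = "surface_cyano", ...) {
  plot(x$derived$date, x$derived[[variable]], type = "l",
       xlab = "date", ylab = variable, ...)
  invisible(x)
}
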