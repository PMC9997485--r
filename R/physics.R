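#' Physical parameter set for the lake thermal model
#'
#' Constants of the surface heat budget, light attenuation and the
#' parametric vertical mixing scheme. The mixing scheme replaces a full
#' turbulence closure with a documented eddy diffusivity: a background
#' value plus a wind-driven surface enhancement decaying exponentially with
#' depth, damped by local stratification through the Brunt-Vaisala
#' frequency.
#'
#' @param albedo water surface shortwave albedo (default 0.07).
#' @param emissivity water longwave emissivity.
#' @param c_sensible,c_latent bulk transfer coefficients for sensible and
#'   latent heat.
#' @param u_min minimum effective wind speed (m s^-1); at zero wind the
#'   bulk fluxes equal their free-convection floor computed at `u_min`.
#' @param beta_sw fraction of penetrating shortwave absorbed in the top
#'   layer (near-infrared part).
#' @param kd_background background light attenuation (m^-1).
#' @param kd_chl chlorophyll-specific attenuation (m^-1 per mg chl m^-3),
#'   the phytoplankton self-shading / transparency-heating feedback.
#' @param par_frac photosynthetically active fraction of shortwave.
#' @param k_background background vertical diffusivity (m^2 d^-1).
#' @param k_wind wind-driven surface diffusivity per squared wind speed
#'   (m^2 d^-1 per (m s^-1)^2).
#' @param z_decay e-folding depth of the wind-driven mixing (m).
#' @param n2_damp stratification damping coefficient (s^2); diffusivity is
#'   divided by `(1 + n2_damp * N^2)^1.5`.
#' @param gw_temp groundwater inflow temperature (degC).
#' @return list of class `"physics_params"`.
#' @export
physics_params <- function(albedo = 0.07, emissivity = 0.97,
                           c_sensible = 1.4e-3, c_latent = 1.4e-3,
                           u_min = 0.5, beta_sw = 0.45,
                           kd_background = 0.45, kd_chl = 0.015,
                           par_frac = 0.46,
                           k_background = 0.06, k_wind = 0.3,
                           z_decay = 4, n2_damp = 3000,
                           gw_temp = 10) {
  p <- as.list(environment())
  class(p) <- "physics_params"
  p
}

## UNESCO freshwater density polynomial (kg m^-3); maximum near 4 degC,
## so winter inverse stratification is represented.
water_density <- function(temp) {
  999.842594 + 6.793952e-2 * temp - 9.095290e-3 * temp^2 +
    1.001685e-4 * temp^3
}

#' Surface heat-flux components from bulk formulas
#'
#' Standard bulk-aerodynamic surface energy budget for one meteorological
#' record. Sign convention: positive warms the lake. Longwave uses a
#' Brutsaert clear-sky atmospheric emissivity with a quadratic cloud
#' correction; sensible and latent fluxes use constant transfer
#' coefficients with an effective wind speed floored at `params$u_min`
#' (the free-convection floor).
#'
#' @param met one row of a `meteo_series` (list or single-row data frame).
#' @param t_surface surface water temperature (degC).
#' @param params a [physics_params()] object.
#' @return list with components `shortwave` (absorbed, `(1-albedo) * SW`),
#'   `longwave` (net), `sensible`, `latent`, and `net` (their sum), all in
#'   W m^-2.
#' @export
surface_heat_flux <- function(met, t_surface, params = physics_params()) {
  sigma <- 5.67e-8
  ta_k <- met$air_temp + 273.15
  ts_k <- t_surface + 273.15
  e_air <- sat_vapour_pressure(met$dewpoint)           # hPa
  cloud <- if (!is.null(met$cloud)) met$cloud else 0.5

  sw <- (1 - params$albedo) * met$shortwave

  eps_clear <- pmin(1, 1.24 * (e_air / ta_k)^(1 / 7))
  lw_in <- eps_clear * (1 + 0.22 * cloud^2) * sigma * ta_k^4
  lw_out <- params$emissivity * sigma * ts_k^4
  lw <- params$emissivity * lw_in - lw_out

  u_eff <- pmax(params$u_min, sqrt(met$wind_u^2 + met$wind_v^2))
  rho_air <- 1.2; cp_air <- 1005; l_vap <- 2.45e6
  sens <- rho_air * cp_air * params$c_sensible * u_eff *
    (met$air_temp - t_surface)
  q_air <- 0.622 * e_air / met$pressure
  q_surf <- 0.622 * sat_vapour_pressure(t_surface) / met$pressure
  lat <- rho_air * l_vap * params$c_latent * u_eff * (q_air - q_surf)

  list(shortwave = sw, longwave = lw, sensible = sens, latent = lat,
       net = sw + lw + sens + lat)
}

#' Underwater light profile with phytoplankton self-shading
#'
#' Beer-Lambert attenuation layer by layer with a chlorophyll-dependent
#' attenuation coefficient `k(z) = kd_background + kd_chl * chl(z)`. The
#' same profile scales the depth distribution of shortwave heating, which
#' creates the transparency-heating feedback: clearer water lets radiation
#' (and heat) reach deeper.
#'
#' @param sw_surface radiation just below the surface (W m^-2).
#' @param chl per-layer chlorophyll (mg m^-3).
#' @param kd_background background attenuation (m^-1).
#' @param kd_chl chlorophyll-specific attenuation (m^-1 per mg m^-3).
#' @param dz per-layer thickness (m), recycled if scalar.
#' @return list with `interface` (radiation at the `n+1` interfaces),
#'   `layer` (depth-averaged radiation within each layer) and
#'   `attenuation` (per-layer `k`).
#' @export
light_profile <- function(sw_surface, chl, kd_background, kd_chl,
                          dz = 0.5) {
  if (kd_background < 0 || kd_chl < 0) stop("negative attenuation")
  n <- length(chl)
  dz <- rep_len(dz, n)
  k <- kd_background + kd_chl * pmax(0, chl)
  interface <- c(1, exp(-cumsum(k * dz))) * sw_surface
  kdz <- k * dz
  ## depth-average of I0 * exp(-k z) over the layer
  layer <- ifelse(kdz > 1e-12,
                  interface[-(n + 1)] * (1 - exp(-kdz)) / kdz,
                  interface[-(n + 1)])
  list(interface = interface, layer = layer, attenuation = k)
}

## Parametric eddy diffusivity (m^2 d^-1) at the n-1 interior interfaces.
eddy_diffusivity <- function(temp, grid, wind_speed, params) {
  n <- grid$n_layers
  rho <- water_density(temp)
  dzc <- diff(grid$z_mid)
  n2 <- pmax(0, 9.81 / 1000 * (rho[-1] - rho[-n]) / dzc)  # s^-2
  z_int <- grid$z[2:n]
  k <- params$k_background +
    params$k_wind * wind_speed^2 * exp(-z_int / params$z_decay) /
      (1 + params$n2_damp * n2)^1.5
  pmax(k, params$k_background)
}

## Implicit (backward Euler) vertical diffusion of the columns of `fields`
## (n_layers x n_fields), conservative in volume-weighted totals.
## `k` is diffusivity at interior interfaces (length n-1), m^2 d^-1.
diffuse_implicit <- function(fields, grid, k, dt = 1) {
  n <- grid$n_layers
  dzc <- diff(grid$z_mid)
  cond <- grid$area[2:n] * k / dzc        # m^3 d^-1 interface conductance
  v <- grid$volume
  lower <- -dt * cond
  upper <- -dt * cond
  diag_main <- v + dt * c(cond, 0) + dt * c(0, cond)
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- upper
  m[cbind(2:n, 1:(n - 1))] <- lower
  sol <- solve(m, v * fields)
  if (anyNA(sol)) stop("diffusion scheme produced NaN; unstable input")
  sol
}

## Convective adjustment: mix adjacent layers while density-unstable
## (denser water above lighter). `fields` columns are mixed with the same
## volume weights; column 1 is temperature (used for density).
convective_adjust <- function(fields, grid) {
  v <- grid$volume
  n <- grid$n_layers
  repeat {
    rho <- water_density(fields[, 1])
    i <- which(rho[-n] > rho[-1] + 1e-12)
    if (!length(i)) break
    i <- i[1]
    ## grow the mixed patch downward while still unstable
    j <- i + 1
    repeat {
      w <- v[i:j]
      mixed <- colSums(fields[i:j, , drop = FALSE] * w) / sum(w)
      fields[i:j, ] <- matrix(mixed, j - i + 1, ncol(fields), byrow = TRUE)
      if (j < n &&
          water_density(mixed[1]) > water_density(fields[j + 1, 1]) + 1e-12) {
        j <- j + 1
      } else break
    }
  }
  fields
}

## Upwind advection of the groundwater through-flow: inflow (m^3 d^-1)
## enters the bottom layer with concentrations `c_in` (one per field),
## flows upward, and is withdrawn from the surface layer.
advect_throughflow <- function(fields, grid, q, c_in, dt = 1) {
  if (q <= 0) return(fields)
  n <- grid$n_layers
  qdt <- q * dt
  gain <- rbind(fields[-1, , drop = FALSE],
                matrix(c_in, 1, ncol(fields)))
  fields + qdt * (gain - fields) / grid$volume
}

#' Advance the lake's physical state by one step
#'
#' Applies, in order: surface heat fluxes to the top layer, shortwave
#' deposition through the light profile, implicit vertical diffusion with
#' the wind- and stability-dependent eddy diffusivity, convective
#' adjustment of density-unstable profiles, and the groundwater
#' through-flow (inflow into the bottom layer, balancing withdrawal at the
#' surface). Temperatures are clamped at 0 degC; ice is not modelled.
#'
#' @param state list with at least `temp` (per-layer degC). Optional
#'   element `chl` (per-layer mg m^-3) feeds the self-shading attenuation.
#' @param grid a [build_grid()] object.
#' @param met one meteorological record (row of a `meteo_series`).
#' @param inflow groundwater inflow (m^3 s^-1).
#' @param dt time step (d), at most 1.
#' @param params a [physics_params()] object.
#' @return the updated state, with fields `temp`, `k` (interface
#'   diffusivities), `par` (per-layer photosynthetically active radiation,
#'   W m^-2) and `thermocline` (depth of the largest density gradient, m).
#' @export
step_physics <- function(state, grid, met, inflow = 0, dt = 1,
                         params = physics_params()) {
  stopifnot(dt <= 1, length(state$temp) == grid$n_layers)
  temp <- state$temp
  n <- grid$n_layers
  chl <- if (!is.null(state$chl)) state$chl else rep(0, n)

  flux <- surface_heat_flux(met, temp[1], params)
  rho_cp <- 4.186e6                        # J m^-3 K^-1
  secs <- 86400 * dt

  ## penetrative shortwave: beta_sw absorbed in the top layer, remainder
  ## attenuated; light intercepted between interfaces (area-weighted) heats
  ## the layer, light reaching the bottom heats the bottom layer.
  lp <- light_profile(flux$shortwave * (1 - params$beta_sw), chl,
                      params$kd_background, params$kd_chl, grid$dz)
  ein <- lp$interface * grid$area          # W
  sw_heat <- ein[-(n + 1)] - ein[-1]
  sw_heat[n] <- sw_heat[n] + ein[n + 1]
  sw_heat[1] <- sw_heat[1] + flux$shortwave * params$beta_sw * grid$area[1]
  nonpen <- (flux$longwave + flux$sensible + flux$latent) * grid$area[1]
  temp <- temp + (sw_heat + c(nonpen, rep(0, n - 1))) * secs /
    (rho_cp * grid$volume)

  u10 <- sqrt(met$wind_u^2 + met$wind_v^2)
  k <- eddy_diffusivity(temp, grid, u10, params)
  fields <- diffuse_implicit(cbind(temp), grid, k, dt)
  fields <- convective_adjust(fields, grid)
  fields <- advect_throughflow(fields, grid, inflow * 86400, params$gw_temp,
                               dt)
  temp <- pmax(0, fields[, 1])
  if (anyNA(temp)) stop("physics step produced NaN temperature")

  rho <- water_density(temp)
  grad <- diff(rho) / diff(grid$z_mid)
  state$temp <- temp
  state$k <- k
  state$par <- params$par_frac / (1 - params$beta_sw) * lp$layer
  state$thermocline <- grid$z_mid[which.max(c(0, grad))]
  state
}
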