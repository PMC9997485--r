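## Column order of the biogeochemical state matrix (one row per layer).
BIO_FIELDS <- c("do", "nh4", "no3", "srp", "dop", "si", "detc", "detsi",
                "diat", "green", "cyano", "daph", "meso")
PHYTO <- c("diat", "green", "cyano")
ZOO <- c("daph", "meso")

#' Biogeochemical parameter set
#'
#' Rates and constants of the PCLake-style process model: Monod-Liebig
#' growth of three phytoplankton groups (diatoms, green algae and buoyant
#' cyanobacteria), two zooplankton grazers with a fish-predation closure,
#' detritus mineralisation, nitrification/denitrification, oxygen dynamics
#' and a single well-mixed sediment layer whose exchangeable phosphorus
#' pool feeds a temperature- and oxygen-dependent diffusive release flux.
#' Stoichiometry is fixed (Redfield C:N:P by mass, a constant
#' chlorophyll:carbon ratio), so element budgets close exactly.
#'
#' Units: rates in d^-1, half-saturations in mg L^-1 (light in W m^-2),
#' settling velocities in m d^-1 (negative = buoyant), areal sediment
#' rates per m^2 of sediment surface. Arrhenius temperature factors
#' `theta^(T - 20)` use a 20 degC reference.
#'
#' @param mu_max maximum growth rates of diatoms, greens, cyanobacteria.
#' @param theta_growth per-group Arrhenius theta; the cyanobacterial
#'   default 1.12 makes a +0.9 degC warming raise growth by about 10 %.
#' @param k_p,k_n per-group phosphorus and nitrogen half-saturations.
#' @param k_si diatom silicon half-saturation.
#' @param k_light per-group light half-saturation (W m^-2).
#' @param resp,mort per-group respiration and mortality rates.
#' @param theta_resp Arrhenius theta for respiration/mortality.
#' @param settle per-group settling velocities; cyanobacteria negative
#'   (buoyancy as a constant upward velocity).
#' @param cyano_active_doy day-of-year window (first, last) outside of
#'   which cyanobacteria lose buoyancy and sink: an optional
#'   photoperiod cue for the resting phase (the default window disables
#'   it).
#' @param cyano_sink_temp whole-column mean temperature (degC) below
#'   which cyanobacteria lose buoyancy and sink: the autumn collapse of
#'   the bloom into the overwintering resting phase (`NA` disables).
#' @param cyano_sink_w settling velocity of non-buoyant (resting-phase)
#'   cyanobacteria (m d^-1).
#' @param settle_det detritus settling velocity.
#' @param c_per_chl carbon per chlorophyll unit (mg C L^-1 per mg chl
#'   m^-3).
#' @param pc,nc phosphorus:carbon and nitrogen:carbon mass ratios.
#' @param sic_diat silicon:carbon mass ratio of diatoms.
#' @param o2c oxygen:carbon mass ratio of production/mineralisation.
#' @param g_max,k_food,assim grazing maxima, food half-saturation and
#'   assimilation efficiency of the Daphnia-like and meso-zooplankton
#'   groups.
#' @param theta_zoo Arrhenius theta for grazing.
#' @param pref 2 x 4 preference matrix (rows Daphnia/meso, columns
#'   diatoms/greens/cyanobacteria/detritus).
#' @param resp_zoo,closure_lin,closure_quad zooplankton respiration and
#'   the linear + quadratic (density-dependent, collapsed fish predation)
#'   closure mortality.
#' @param r_det,theta_min detritus mineralisation rate and theta.
#' @param f_srp_min fraction of mineralised P released as SRP (the rest as
#'   dissolved organic P).
#' @param r_dop dissolved-organic-P mineralisation rate.
#' @param r_detsi biogenic-silica dissolution rate.
#' @param k_min_o2 oxygen half-saturation of aerobic mineralisation.
#' @param anaer_frac relative rate of the anaerobic mineralisation pathway
#'   (active when oxygen is depleted; consumes no oxygen).
#' @param nitrif,k_nit,o2n nitrification rate, its oxygen half-saturation
#'   and the O2:N stoichiometry (4.57 g O2 per g N).
#' @param denitrif,k_den denitrification rate and the oxygen
#'   half-saturation of its inverse-Monod inhibition.
#' @param k_diff sediment P diffusion rate constant (m^2 d^-1); the
#'   "barleber" default 7.2e-5 is the calibrated eutrophic value, reduced
#'   by three orders of magnitude by a P-precipitation event.
#' @param delta diffusive boundary-layer thickness (m).
#' @param theta_sed Arrhenius theta of sediment P release.
#' @param a_oxic oxic fraction of the sediment release (the oxygen
#'   dependence interpolates between `a_oxic` under fully oxic bottom
#'   water and 1 under anoxia).
#' @param k_o2 oxygen half-saturation of sediment P retention (mg L^-1).
#' @param h_pore effective porewater depth converting the exchangeable
#'   areal pool (g m^-2) into a porewater concentration (g m^-3).
#' @param r_sed_min sediment organic matter mineralisation rate (feeds the
#'   exchangeable P pool and releases NH4 to the overlying water).
#' @param theta_sed_min its Arrhenius theta.
#' @param p_exch_max sorption saturation of the exchangeable P pool
#'   (g m^-2): mineralised P is retained in the organic pool as the
#'   porewater-equivalent pool approaches this ceiling, so a diffusion cap
#'   cannot accumulate unbounded porewater P.
#' @param f_sed_direct fraction of the sediment organic P mineralisation
#'   released directly to the overlying water (surface diagenesis of
#'   freshly settled material, analogous to the sediment NH4 release);
#'   the remainder feeds the exchangeable porewater pool whose escape is
#'   controlled by `k_diff`. Distinguishes fast recycling of current
#'   deposition from the legacy internal loading targeted by P capping.
#' @param r_sed_si sediment biogenic-silica dissolution rate.
#' @param sod,k_sod,theta_sod sediment oxygen demand (g O2 m^-2 d^-1) with
#'   Monod oxygen dependence and Arrhenius theta.
#' @param phyto_min resting-stage inoculum (mg chl m^-3): biomass below
#'   this floor is recruited back through the ordinary growth/uptake path
#'   (consuming nutrients, subject to the same flux limiting), emulating
#'   germination from sediment resting stages so no group can go
#'   permanently extinct.
#' @param gas_exchange logical; wind-dependent surface O2 exchange.
#' @param n_substeps explicit sub-steps per day for the process kernel.
#' @return list of class `"eco_params"`.
#' @export
eco_params <- function(
    mu_max = c(diat = 2.2, green = 2.1, cyano = 1.1),
    theta_growth = c(diat = 1.01, green = 1.06, cyano = 1.12),
    k_p = c(diat = 0.010, green = 0.008, cyano = 0.004),
    k_n = c(diat = 0.10, green = 0.08, cyano = 0.03),
    k_si = 0.12,
    k_light = c(diat = 12, green = 14, cyano = 10),
    resp = c(diat = 0.10, green = 0.10, cyano = 0.08),
    mort = c(diat = 0.05, green = 0.05, cyano = 0.05),
    theta_resp = 1.08,
    settle = c(diat = 0.25, green = 0.08, cyano = -0.10),
    cyano_active_doy = c(1, 366), cyano_sink_temp = NA,
    cyano_sink_w = 0.25,
    settle_det = 0.35,
    c_per_chl = 0.05, pc = 0.0244, nc = 0.176, sic_diat = 0.35,
    o2c = 2.67,
    g_max = c(daph = 0.9, meso = 0.5),
    k_food = 0.4, assim = 0.6, theta_zoo = 1.09,
    pref = rbind(daph = c(0.40, 0.25, 0.05, 0.30),
                 meso = c(0.30, 0.20, 0.10, 0.40)),
    resp_zoo = c(daph = 0.04, meso = 0.04),
    closure_lin = 0.02, closure_quad = 0.10,
    r_det = 0.05, theta_min = 1.07, f_srp_min = 0.7,
    r_dop = 0.05, r_detsi = 0.02,
    k_min_o2 = 0.5, anaer_frac = 0.4,
    nitrif = 0.08, k_nit = 1.0, o2n = 4.57,
    denitrif = 0.25, k_den = 0.3,
    k_diff = 7.2e-5, delta = 0.02, theta_sed = 1.20,
    a_oxic = 0.05, k_o2 = 0.5, h_pore = 0.05,
    r_sed_min = 2.75e-4, theta_sed_min = 1.05, p_exch_max = 0.8,
    f_sed_direct = 0.55, r_sed_si = 5e-5,
    sod = 0.40, k_sod = 0.7, theta_sod = 1.13,
    phyto_min = 0,
    gas_exchange = TRUE, n_substeps = 2) {
  p <- as.list(environment())
  if (any(c(p$theta_growth, p$theta_resp, p$theta_zoo, p$theta_min,
            p$theta_sed, p$theta_sed_min, p$theta_sod) < 1))
    stop("Arrhenius theta must be >= 1")
  if (any(c(p$k_p, p$k_n, p$k_si, p$k_light, p$k_food) <= 0))
    stop("half-saturations must be positive")
  class(p) <- "eco_params"
  p
}

#' Arrhenius temperature modifier
#'
#' Multiplicative rate factor `theta^(T - t_ref)` applied to
#' biogeochemical process rates.
#'
#' @param temp temperature (degC), vectorised.
#' @param theta dimensionless base, `>= 1`.
#' @param t_ref reference temperature (default 20 degC).
#' @return the multiplier; 1 at the reference temperature.
#' @examples
#' arrhenius(20.9, 1.12)  # ~ +10 % for a +0.9 degC warming
#' @export
arrhenius <- function(temp, theta, t_ref = 20) {
  if (any(theta < 1)) stop("theta must be >= 1")
  theta^(temp - t_ref)
}

#' Monod-Liebig growth limitation factor
#'
#' Minimum over the nutrient Monod terms (P and N, plus Si for diatoms)
#' times a saturating light term; zero whenever a required resource is
#' absent.
#'
#' @param srp soluble reactive phosphorus (mg P L^-1).
#' @param din dissolved inorganic nitrogen (mg N L^-1).
#' @param si dissolved silicon (mg Si L^-1); only diatoms require it.
#' @param par photosynthetically active radiation (W m^-2).
#' @param params an [eco_params()] object.
#' @param group one of `"diat"`, `"green"`, `"cyano"`.
#' @return limitation factor in `[0, 1]`, vectorised over the inputs.
#' @export
growth_limitation <- function(srp, din, si, par, params = eco_params(),
                              group = "cyano") {
  group <- match.arg(group, PHYTO)
  lim <- pmin(srp / (srp + params$k_p[[group]]),
              din / (din + params$k_n[[group]]))
  if (group == "diat") lim <- pmin(lim, si / (si + params$k_si))
  lim * par / (par + params$k_light[[group]])
}

#' Initial biogeochemical state
#'
#' @param grid a [build_grid()] object.
#' @param do,nh4,no3,srp,dop,si,detc,detsi,diat,green,cyano,daph,meso
#'   initial uniform concentrations (see [eco_params()] for units).
#' @return an `n_layers` x 13 matrix with columns named after the state
#'   variables.
#' @export
bio_state <- function(grid, do = 10, nh4 = 0.05, no3 = 1.0, srp = 0.10,
                      dop = 0.02, si = 2.0, detc = 0.5, detsi = 0.3,
                      diat = 2, green = 2, cyano = 2,
                      daph = 0.05, meso = 0.02) {
  vals <- c(do, nh4, no3, srp, dop, si, detc, detsi, diat, green, cyano,
            daph, meso)
  matrix(rep(vals, each = grid$n_layers), grid$n_layers, length(BIO_FIELDS),
         dimnames = list(NULL, BIO_FIELDS))
}

#' Initial sediment state
#'
#' Areal pools per m^2 of sediment surface, uniform over the lake bed.
#'
#' @param org_p,org_n organic P and N pools (g m^-2).
#' @param p_exch exchangeable (porewater-equivalent) P pool (g m^-2); the
#'   porewater concentration is `p_exch / h_pore` (g m^-3 = mg L^-1).
#' @param bio_si biogenic silica pool (g m^-2).
#' @return list of class `"sed_state"`.
#' @export
sed_state <- function(org_p = 30, p_exch = 0.30, org_n = 150,
                      bio_si = 200) {
  structure(list(org_p = org_p, p_exch = p_exch, org_n = org_n,
                 bio_si = bio_si), class = "sed_state")
}

#' Diffusive sediment phosphorus release flux
#'
#' `F = 1000 (k_diff/delta) (C_pore - C_bottom) theta_sed^(T-20)
#'  [a_oxic + (1 - a_oxic) K_O2/(K_O2 + DO)]`
#' in mg P m^-2 d^-1; negative when the overlying water is richer than the
#' porewater. Warmer and more oxygen-depleted bottom water both increase
#' the release.
#'
#' @param sed a [sed_state()] object (supplies the porewater
#'   concentration `p_exch / h_pore`).
#' @param c_bottom overlying-water SRP (mg L^-1).
#' @param t_bottom overlying-water temperature (degC).
#' @param do_bottom overlying-water dissolved oxygen (mg L^-1).
#' @param params an [eco_params()] object (uses `k_diff`, `delta`,
#'   `theta_sed`, `a_oxic`, `k_o2`, `h_pore`).
#' @return flux in mg P m^-2 d^-1, vectorised over the water-side inputs.
#' @export
sediment_p_flux <- function(sed, c_bottom, t_bottom, do_bottom,
                            params = eco_params()) {
  if (params$delta <= 0) stop("delta must be positive")
  c_pore <- sed$p_exch / params$h_pore
  oxy <- params$a_oxic + (1 - params$a_oxic) *
    params$k_o2 / (params$k_o2 + pmax(0, do_bottom))
  1000 * (params$k_diff / params$delta) * (c_pore - c_bottom) *
    arrhenius(t_bottom, params$theta_sed) * oxy
}

## Oxygen saturation (mg L^-1) vs temperature, freshwater at 1 atm.
do_saturation <- function(temp) {
  14.652 - 0.41022 * temp + 0.0079910 * temp^2 - 7.7774e-5 * temp^3
}

## -------------------------------------------------------------------------
## Process kernel: one explicit sub-step of all biogeochemical processes.
## Non-negativity is enforced by proportional flux limiting on each source
## pool (all outgoing fluxes of a depleted pool are scaled down together),
## never by discarding mass, so element budgets close exactly.
##
## Internal units: all dissolved and detrital pools in mg L^-1 (= g m^-3),
## phytoplankton in mg chl m^-3 with carbon density c_per_chl * chl in
## g C m^-3, sediment pools in g m^-2. Areal fluxes in g m^-2 d^-1 except
## the sediment P flux, which follows the field convention mg m^-2 d^-1.
## -------------------------------------------------------------------------
## Process kernel: one explicit sub-step of all biogeochemical processes.
## Non-negativity is enforced by proportional flux limiting on each source
## pool (all outgoing fluxes of a depleted pool are scaled down together),
## never by discarding mass, so element budgets close exactly.
##
## Internal units: all dissolved and detrital pools in mg L^-1 (= g m^-3),
## phytoplankton in mg chl m^-3 with carbon density c_per_chl * chl in
## g C m^-3, sediment pools in g m^-2. Areal fluxes in g m^-2 d^-1 except
## the sediment P flux, which follows the field convention mg m^-2 d^-1.
## Column indices follow BIO_FIELDS; the kernel is written index-based and
## with hoisted parameter locals because it dominates the run time.
eco_process_step <- function(bio, sed, temp, par, grid, params, dt,
                             wind = 3,
                             gas_exchange = params$gas_exchange) {
  n <- grid$n_layers
  b <- bio
  do_ <- b[, 1L]; nh4 <- b[, 2L]; no3 <- b[, 3L]
  srp <- b[, 4L]; dop <- b[, 5L]; si <- b[, 6L]
  detc <- b[, 7L]; detsi <- b[, 8L]
  ph <- b[, 9:11, drop = FALSE]
  zo <- b[, 12:13, drop = FALSE]
  din <- nh4 + no3

  ## hoisted parameters (hot loop)
  mu <- params$mu_max; thg <- params$theta_growth
  kp <- params$k_p; kn <- params$k_n; ksi <- params$k_si
  klight <- params$k_light
  rsp <- params$resp; mrt <- params$mort
  cchl <- params$c_per_chl; pc <- params$pc; nc <- params$nc
  sic <- params$sic_diat; o2c <- params$o2c
  gmax <- params$g_max; kfood <- params$k_food; assim <- params$assim
  prefm <- params$pref
  t20 <- temp - 20
  fr <- params$theta_resp^t20
  fm <- params$theta_min^t20
  fz <- params$theta_zoo^t20

  ## --- desired process rates (before flux limiting) ---------------------
  light1 <- par / (par + klight[[1L]])
  light2 <- par / (par + klight[[2L]])
  light3 <- par / (par + klight[[3L]])
  g1 <- mu[[1L]] * thg[[1L]]^t20 *
    pmin(srp / (srp + kp[[1L]]), din / (din + kn[[1L]]),
         si / (si + ksi)) * light1 * ph[, 1L]
  g2 <- mu[[2L]] * thg[[2L]]^t20 *
    pmin(srp / (srp + kp[[2L]]), din / (din + kn[[2L]])) * light2 *
    ph[, 2L]
  g3 <- mu[[3L]] * thg[[3L]]^t20 *
    pmin(srp / (srp + kp[[3L]]), din / (din + kn[[3L]])) * light3 *
    ph[, 3L]
  growth <- cbind(g1, g2, g3, deparse.level = 0)
  ## resting-stage recruitment: top biomass up to the inoculum floor via
  ## the regular uptake path (nutrient-consuming, flux-limited below)
  if (params$phyto_min > 0)
    growth <- growth + pmax(0, params$phyto_min - ph) / dt
  growth_c <- growth * cchl                          # g C m^-3 d^-1

  resp <- cbind(ph[, 1L] * rsp[[1L]], ph[, 2L] * rsp[[2L]],
                ph[, 3L] * rsp[[3L]], deparse.level = 0) * fr
  mort <- cbind(ph[, 1L] * mrt[[1L]], ph[, 2L] * mrt[[2L]],
                ph[, 3L] * mrt[[3L]], deparse.level = 0) * fr

  food <- cbind(ph * cchl, detc, deparse.level = 0)  # g C m^-3
  fw1 <- food * rep(prefm[1L, ], each = n)
  fw2 <- food * rep(prefm[2L, ], each = n)
  ft1 <- fw1[, 1L] + fw1[, 2L] + fw1[, 3L] + fw1[, 4L]
  ft2 <- fw2[, 1L] + fw2[, 2L] + fw2[, 3L] + fw2[, 4L]
  gz1 <- fw1 * (gmax[[1L]] * fz * zo[, 1L] / ((ft1 + kfood) *
                                                pmax(ft1, 1e-12)) * ft1)
  gz2 <- fw2 * (gmax[[2L]] * fz * zo[, 2L] / ((ft2 + kfood) *
                                                pmax(ft2, 1e-12)) * ft2)
  graze_prey <- gz1 + gz2
  zoo_resp <- cbind(zo[, 1L] * params$resp_zoo[[1L]],
                    zo[, 2L] * params$resp_zoo[[2L]],
                    deparse.level = 0) * fr
  closure <- (params$closure_lin + params$closure_quad * zo) * zo * fr

  aer <- do_ / (do_ + params$k_min_o2)
  anf <- params$anaer_frac
  min_det <- params$r_det * fm * detc * (aer + anf * (1 - aer))
  min_dop <- params$r_dop * fm * dop
  diss_si <- params$r_detsi * fm * detsi
  nit <- params$nitrif * fm * nh4 * do_ / (do_ + params$k_nit)
  den <- params$denitrif * fm * no3 * params$k_den / (params$k_den + do_)

  fsed_t <- params$theta_sed_min^t20
  p_flux <- sediment_p_flux(sed, srp, temp, do_, params)  # mg P m^-2 d^-1
  sat <- max(0, 1 - sed$p_exch / params$p_exch_max)
  fdir <- params$f_sed_direct
  sed_min_p_dir <- fdir * params$r_sed_min * fsed_t * sed$org_p
  sed_min_p <- (1 - fdir) * params$r_sed_min * fsed_t * sed$org_p * sat
  sed_min_n <- params$r_sed_min * fsed_t * sed$org_n
  sed_si <- params$r_sed_si * fsed_t * sed$bio_si
  sod <- params$sod * params$theta_sod^t20 *
    do_ / (do_ + params$k_sod)                            # g O2 m^-2 d^-1
  a_over_v <- grid$sed_area / grid$volume                 # m^-1

  ## surface O2 exchange is applied after the state update as an exact
  ## exponential relaxation towards saturation (unconditionally stable
  ## even at storm winds where k A/V dt would exceed the explicit limit)

  ## --- flux limiting -----------------------------------------------------
  ## scale factor so that dt * demand never exceeds the pool; a depleted
  ## pool throttles all its outgoing fluxes proportionally
  lim <- function(pool, demand) {
    pmin(1, pool / pmax(pmax(demand, 0) * dt, 1e-300))
  }
  grow_tot_c0 <- growth_c[, 1L] + growth_c[, 2L] + growth_c[, 3L]
  p_demand <- grow_tot_c0 * pc
  n_demand <- grow_tot_c0 * nc
  f_nh4 <- 2 * nh4 / pmax(2 * nh4 + no3, 1e-12)      # NH4-preferent uptake
  s_srp <- lim(srp, p_demand)
  s_nh4 <- lim(nh4, n_demand * f_nh4 + nit)
  s_no3 <- lim(no3, n_demand * (1 - f_nh4) + den)
  s_si <- lim(si, growth_c[, 1L] * sic)
  s_nut <- pmin(s_srp, s_nh4, s_no3)
  growth[, 1L] <- growth[, 1L] * pmin(s_nut, s_si)
  growth[, 2L] <- growth[, 2L] * s_nut
  growth[, 3L] <- growth[, 3L] * s_nut
  growth_c <- growth * cchl
  nit <- nit * s_nh4
  den <- den * s_no3

  s_ph <- cbind(lim(ph[, 1L], resp[, 1L] + mort[, 1L] +
                      graze_prey[, 1L] / cchl),
                lim(ph[, 2L], resp[, 2L] + mort[, 2L] +
                      graze_prey[, 2L] / cchl),
                lim(ph[, 3L], resp[, 3L] + mort[, 3L] +
                      graze_prey[, 3L] / cchl), deparse.level = 0)
  resp <- resp * s_ph
  mort <- mort * s_ph
  s_det <- lim(detc, min_det + graze_prey[, 4L])
  min_det <- min_det * s_det
  scale4 <- cbind(s_ph, s_det, deparse.level = 0)
  gz1 <- gz1 * scale4
  gz2 <- gz2 * scale4
  in1 <- gz1[, 1L] + gz1[, 2L] + gz1[, 3L] + gz1[, 4L]
  in2 <- gz2[, 1L] + gz2[, 2L] + gz2[, 3L] + gz2[, 4L]

  s_zoo <- cbind(lim(zo[, 1L], zoo_resp[, 1L] + closure[, 1L]),
                 lim(zo[, 2L], zoo_resp[, 2L] + closure[, 2L]),
                 deparse.level = 0)
  zoo_resp <- zoo_resp * s_zoo
  closure <- closure * s_zoo
  min_dop <- min_dop * lim(dop, min_dop)
  diss_si <- diss_si * lim(detsi, diss_si)

  resp_c <- (resp[, 1L] + resp[, 2L] + resp[, 3L]) * cchl
  zoo_resp_c <- zoo_resp[, 1L] + zoo_resp[, 2L]
  min_det_o2 <- min_det * aer / pmax(aer + anf * (1 - aer), 1e-12) * o2c
  o2_sink <- (resp_c + zoo_resp_c) * o2c + min_det_o2 +
    nit * params$o2n + sod * a_over_v
  s_do <- lim(do_, o2_sink)
  resp_o2 <- resp_c * o2c * s_do
  zoo_resp_o2 <- zoo_resp_c * o2c * s_do
  min_det_o2 <- min_det_o2 * s_do
  nit_o2 <- nit * params$o2n * s_do
  sod_eff <- sod * s_do

  ## sediment source pools (areal; demand is the area-weighted mean draw)
  pos_draw <- sum(pmax(p_flux, 0) * grid$sed_area) / grid$surface_area / 1000
  s_sed_p <- lim(sed$p_exch, pos_draw)
  p_flux <- ifelse(p_flux > 0, p_flux * s_sed_p, p_flux)
  mean_sed_dir <- sum(sed_min_p_dir * grid$sed_area) / grid$surface_area
  mean_sed_min_p <- sum(sed_min_p * grid$sed_area) / grid$surface_area
  s_op <- lim(sed$org_p, mean_sed_dir + mean_sed_min_p)
  sed_min_p_dir <- sed_min_p_dir * s_op
  mean_sed_dir <- mean_sed_dir * s_op
  mean_sed_min_p <- mean_sed_min_p * s_op
  s_on <- lim(sed$org_n, sum(sed_min_n * grid$sed_area) / grid$surface_area)
  sed_min_n <- sed_min_n * s_on
  s_bsi <- lim(sed$bio_si, sum(sed_si * grid$sed_area) / grid$surface_area)
  sed_si <- sed_si * s_bsi

  ## --- assemble derivatives (mg L^-1 d^-1 for water pools) ---------------
  grow_tot_c <- growth_c[, 1L] + growth_c[, 2L] + growth_c[, 3L]
  egest <- (in1 + in2) * (1 - assim)
  si_grazed <- (gz1[, 1L] + gz2[, 1L]) * sic

  d_do <- grow_tot_c * o2c - resp_o2 - zoo_resp_o2 - min_det_o2 -
    nit_o2 - sod_eff * a_over_v
  d_nh4 <- -grow_tot_c * nc * f_nh4 - nit +
    (resp_c + zoo_resp_c + min_det) * nc + sed_min_n * a_over_v
  d_no3 <- -grow_tot_c * nc * (1 - f_nh4) + nit - den
  d_srp <- -grow_tot_c * pc +
    (resp_c + zoo_resp_c) * pc +
    params$f_srp_min * min_det * pc + min_dop +
    p_flux * a_over_v / 1000 + sed_min_p_dir * a_over_v
  d_dop <- (1 - params$f_srp_min) * min_det * pc - min_dop
  d_si <- -growth_c[, 1L] * sic + diss_si + sed_si * a_over_v
  closure_tot <- closure[, 1L] + closure[, 2L]
  d_detc <- (mort[, 1L] + mort[, 2L] + mort[, 3L]) * cchl + egest +
    closure_tot - min_det - (gz1[, 4L] + gz2[, 4L])
  d_detsi <- (mort[, 1L] + resp[, 1L]) * cchl * sic + si_grazed - diss_si
  d_ph <- growth - resp - mort - (gz1[, 1:3] + gz2[, 1:3]) / cchl
  d_zoo <- cbind(in1, in2, deparse.level = 0) * assim - zoo_resp - closure

  b[, 1L] <- do_ + dt * d_do
  b[, 2L] <- nh4 + dt * d_nh4
  b[, 3L] <- no3 + dt * d_no3
  b[, 4L] <- srp + dt * d_srp
  b[, 5L] <- dop + dt * d_dop
  b[, 6L] <- si + dt * d_si
  b[, 7L] <- detc + dt * d_detc
  b[, 8L] <- detsi + dt * d_detsi
  b[, 9:11] <- ph + dt * d_ph
  b[, 12:13] <- zo + dt * d_zoo
  b[b < 0 & b > -1e-10] <- 0   # round-off snap only; limiter prevents more

  gas <- 0
  if (gas_exchange) {
    k_gas <- 0.24 * (2.07 + 0.215 * wind^1.7)             # m d^-1
    sat_do <- do_saturation(temp[1L])
    relax <- exp(-k_gas * grid$area[1L] / grid$volume[1L] * dt)
    new_do <- sat_do + (b[1L, 1L] - sat_do) * relax
    gas <- (new_do - b[1L, 1L]) / dt
    b[1L, 1L] <- new_do
  }

  net_draw <- sum(p_flux * grid$sed_area) / grid$surface_area / 1000
  sed$p_exch <- sed$p_exch + dt * (mean_sed_min_p - net_draw)
  sed$org_p <- sed$org_p - dt * (mean_sed_min_p + mean_sed_dir)
  sed$org_n <- sed$org_n -
    dt * sum(sed_min_n * grid$sed_area) / grid$surface_area
  sed$bio_si <- sed$bio_si -
    dt * sum(sed_si * grid$sed_area) / grid$surface_area

  list(bio = b, sed = sed,
       diag = list(
         p_flux_pos = sum(pmax(p_flux, 0) * grid$sed_area) /
           grid$surface_area,                        # mg m^-2 d^-1
         p_flux_net = net_draw * 1000,
         denit_n = sum(den * grid$volume) / 1000,    # kg N d^-1
         gas_o2 = gas * grid$volume[1L] / 1000))     # kg O2 d^-1
}
## Settling / buoyancy advection of particulate fields (upwind, explicit);
## material settling onto the sediment annuli feeds the areal pools.
## Buoyant fields (w < 0) rise and accumulate in the surface layer.
settle_step <- function(bio, sed, grid, params, dt, doy = NULL,
                        temp = NULL) {
  n <- grid$n_layers
  dep_p <- 0; dep_n <- 0; dep_si <- 0
  w_set <- params$settle
  resting <- (!is.null(doy) && (doy < params$cyano_active_doy[1] ||
                                doy > params$cyano_active_doy[2])) ||
    (!is.null(temp) && !is.na(params$cyano_sink_temp) &&
       sum(temp * grid$volume) / sum(grid$volume) <
         params$cyano_sink_temp)
  if (resting) w_set[["cyano"]] <- params$cyano_sink_w
  move <- function(conc, w) {
    if (w == 0) return(list(conc = conc, dep_mean = 0))
    if (w > 0) {
      gain <- w * c(0, conc[-n]) * grid$area[1:n]
      loss <- w * conc * grid$area[1:n]
      dep <- sum(w * conc * grid$sed_area) / grid$surface_area
      list(conc = conc + dt * (gain - loss) / grid$volume, dep_mean = dep)
    } else {
      wu <- -w
      gain <- wu * c(conc[-1], 0) * grid$area[2:(n + 1)]
      loss <- wu * conc * c(0, grid$area[2:n])
      list(conc = conc + dt * (gain - loss) / grid$volume, dep_mean = 0)
    }
  }
  for (g in PHYTO) {
    r <- move(bio[, g], w_set[[g]])
    bio[, g] <- r$conc
    dep_c <- r$dep_mean * params$c_per_chl       # g C m^-2 d^-1
    dep_p <- dep_p + dep_c * params$pc
    dep_n <- dep_n + dep_c * params$nc
    if (g == "diat") dep_si <- dep_si + dep_c * params$sic_diat
  }
  r <- move(bio[, "detc"], params$settle_det)    # conc g m^-3
  bio[, "detc"] <- r$conc
  dep_p <- dep_p + r$dep_mean * params$pc
  dep_n <- dep_n + r$dep_mean * params$nc
  r <- move(bio[, "detsi"], params$settle_det)
  bio[, "detsi"] <- r$conc
  dep_si <- dep_si + r$dep_mean
  sed$org_p <- sed$org_p + dt * dep_p            # g m^-2
  sed$org_n <- sed$org_n + dt * dep_n
  sed$bio_si <- sed$bio_si + dt * dep_si
  list(bio = bio, sed = sed)
}

#' Advance the biogeochemical state by one day
#'
#' Applies the full process kernel (growth, grazing, mineralisation,
#' nitrogen transformations, oxygen dynamics, sediment exchange), the
#' settling/buoyancy advection, and external loads, in `params$n_substeps`
#' explicit sub-steps. Transport by turbulent diffusion and the
#' groundwater through-flow belong to the physical step and are not
#' applied here, so a call with zero loads, zero sediment diffusion and
#' gas exchange off is a closed system whose element totals are conserved.
#'
#' @param bio a [bio_state()] matrix.
#' @param sed a [sed_state()] object.
#' @param phys list with per-layer `temp` (degC) and `par` (W m^-2).
#' @param grid a [build_grid()] object.
#' @param loads optional list of per-layer concentration additions
#'   (mg L^-1 d^-1) named by state variable.
#' @param dt time step in days (default 1).
#' @param params an [eco_params()] object.
#' @param wind 10-m wind speed (m s^-1) for surface gas exchange.
#' @param doy day of year of the step; controls the photoperiod-cued
#'   cyanobacterial buoyancy. `NULL` keeps cyanobacteria buoyant.
#' @return list with updated `bio`, `sed` and a `diag` list of daily
#'   diagnostics: `p_flux_pos` (area-weighted positive sediment P release,
#'   mg m^-2 d^-1), `p_flux_net`, `denit_n` (kg N removed), `gas_o2`
#'   (kg O2 exchanged).
#' @export
step_ecosystem <- function(bio, sed, phys, grid, loads = NULL, dt = 1,
                           params = eco_params(), wind = 3, doy = NULL) {
  stopifnot(dt <= 1)
  nsub <- params$n_substeps
  h <- dt / nsub
  dg <- c(p_flux_pos = 0, p_flux_net = 0, denit_n = 0, gas_o2 = 0)
  for (s in seq_len(nsub)) {
    r <- eco_process_step(bio, sed, phys$temp, phys$par, grid, params, h,
                          wind = wind)
    bio <- r$bio; sed <- r$sed
    dg <- dg + unlist(r$diag) * h
    r <- settle_step(bio, sed, grid, params, h, doy = doy,
                     temp = phys$temp)
    bio <- r$bio; sed <- r$sed
    if (!is.null(loads)) {
      for (f in names(loads)) bio[, f] <- bio[, f] + h * loads[[f]]
    }
  }
  dg[c("p_flux_pos", "p_flux_net")] <- dg[c("p_flux_pos", "p_flux_net")] / dt
  list(bio = bio, sed = sed, diag = as.list(dg))
}

#' Whole-system element budgets
#'
#' Total phosphorus, nitrogen and silicon in water, biota and sediment, in
#' kilograms; used by the conservation tests and the runtime mass-balance
#' check.
#'
#' @param bio a [bio_state()] matrix.
#' @param sed a [sed_state()] object.
#' @param grid a [build_grid()] object.
#' @param params an [eco_params()] object (stoichiometry).
#' @return named numeric vector with elements `P`, `N`, `Si` (kg).
#' @export
element_budget <- function(bio, sed, grid, params = eco_params()) {
  v_l <- grid$volume * 1000                     # litres
  biota_c <- (bio[, "diat"] + bio[, "green"] + bio[, "cyano"]) *
    params$c_per_chl + bio[, "daph"] + bio[, "meso"]
  p_water <- sum(v_l * (bio[, "srp"] + bio[, "dop"] +
                          (bio[, "detc"] + biota_c) * params$pc))
  n_water <- sum(v_l * (bio[, "nh4"] + bio[, "no3"] +
                          (bio[, "detc"] + biota_c) * params$nc))
  si_water <- sum(v_l * (bio[, "si"] + bio[, "detsi"] +
                           bio[, "diat"] * params$c_per_chl *
                             params$sic_diat))
  a <- grid$surface_area
  c(P = p_water / 1e6 + (sed$org_p + sed$p_exch) * a / 1000,
    N = n_water / 1e6 + sed$org_n * a / 1000,
    Si = si_water / 1e6 + sed$bio_si * a / 1000)
}

#' Total phosphorus profile of a biogeochemical state
#'
#' TP = SRP + dissolved organic P + particulate P (detritus, phytoplankton
#' and zooplankton at fixed stoichiometry), per layer in mg P L^-1.
#'
#' @param bio a [bio_state()] matrix (or a days-by-fields slice with the
#'   same columns).
#' @param params an [eco_params()] object.
#' @return numeric vector (mg P L^-1).
#' @export
total_p <- function(bio, params = eco_params()) {
  biota_c <- (bio[, "diat"] + bio[, "green"] + bio[, "cyano"]) *
    params$c_per_chl + bio[, "daph"] + bio[, "meso"]
  bio[, "srp"] + bio[, "dop"] + (bio[, "detc"] + biota_c) * params$pc
}

#' Annual internal phosphorus load
#'
#' Area-weighted annual sum of the positive-direction sediment P release,
#' reported per complete calendar year in kg P a^-1.
#'
#' @param flux daily area-weighted positive sediment P flux
#'   (mg m^-2 d^-1), as in the `p_flux_pos` diagnostic of a run.
#' @param dates `Date` vector matching `flux`.
#' @param grid a [build_grid()] object (supplies the sediment area).
#' @return named numeric vector, one value per complete calendar year.
#' @export
annual_internal_load <- function(flux, dates, grid) {
  stopifnot(length(flux) == length(dates))
  yr <- as.integer(format(dates, "%Y"))
  full <- table(yr)
  keep <- as.integer(names(full)[full >= 365])
  if (!length(keep)) stop("no complete calendar year of fluxes")
  out <- vapply(keep, function(y)
    sum(flux[yr == y]) * grid$surface_area * 1e-6, numeric(1))
  names(out) <- keep
  out
}
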