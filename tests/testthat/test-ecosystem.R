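test_that("Arrhenius modifier matches hand values", {
  expect_equal(arrhenius(20, 1.08), 1)
  expect_equal(arrhenius(20, 1.001), 1)
  expect_equal(arrhenius(20.9, 1.08), 1.08^0.9, tolerance = 1e-12)
  expect_equal(arrhenius(20.9, 1.08), 1.0717, tolerance = 1e-4)
  ## +0.9 degC at theta = 1.12 (cyanobacteria default) is ~ +10 %
  expect_equal(arrhenius(20.9, 1.12), 1.107, tolerance = 1e-3)
  expect_error(arrhenius(20, 0.9), "theta")
})

test_that("growth limitation follows Monod-Liebig kinetics", {
  p <- eco_params()
  ## saturation limit
  expect_gt(growth_limitation(10, 10, 10, 1e4, p, "cyano"), 0.99)
  ## Liebig: a missing resource blocks growth entirely
  expect_equal(growth_limitation(0, 10, 10, 1e4, p, "cyano"), 0)
  expect_equal(growth_limitation(10, 0, 10, 1e4, p, "green"), 0)
  expect_equal(growth_limitation(10, 10, 0, 1e4, p, "diat"), 0)
  ## silicon only constrains diatoms
  expect_gt(growth_limitation(10, 10, 0, 1e4, p, "cyano"), 0.99)
  ## half-saturation: srp = K_P with everything else saturating
  expect_equal(growth_limitation(p$k_p[["cyano"]], 1e3, 1e3, 1e6, p,
                                 "cyano"), 0.5, tolerance = 1e-3)
})

test_that("sediment P flux matches the diffusive hand computation", {
  p <- eco_params(k_diff = 7.2e-5, delta = 0.02, a_oxic = 1,
                  h_pore = 0.1)
  sed <- sed_state(p_exch = 0.5)          # porewater 5 mg L^-1
  f <- sediment_p_flux(sed, c_bottom = 0.5, t_bottom = 20,
                       do_bottom = 10, p)
  expect_equal(f, 1000 * (7.2e-5 / 0.02) * 4.5, tolerance = 1e-9)
  expect_equal(f, 16.2, tolerance = 1e-9)
  ## no gradient, no flux; reversed gradient, negative flux
  expect_equal(sediment_p_flux(sed, 5, 20, 10, p), 0)
  expect_lt(sediment_p_flux(sed, 8, 20, 10, p), 0)
  ## anoxic flux is 5x the fully oxic flux at a_oxic = 0.2
  p2 <- eco_params(a_oxic = 0.2, h_pore = 0.1)
  f_anox <- sediment_p_flux(sed, 0.5, 20, 0, p2)
  f_oxic <- sediment_p_flux(sed, 0.5, 20, 1e9, p2)
  expect_equal(f_anox / f_oxic, 5, tolerance = 1e-6)
  expect_error(sediment_p_flux(sed, 1, 20, 5, eco_params(delta = 0)),
               "delta")
})

test_that("sediment P flux is monotone in temperature and oxygen depletion", {
  p <- eco_params()
  sed <- sed_state(p_exch = 0.3)
  temps <- seq(4, 28, by = 2)
  f_t <- sediment_p_flux(sed, 0.05, temps, 5, p)
  expect_true(all(diff(f_t) > 0))
  oxy <- seq(0, 12, by = 1)
  f_o <- sediment_p_flux(sed, 0.05, 15, oxy, p)
  expect_true(all(diff(f_o) < 0))
})

test_that("annual internal load integrates area-weighted fluxes", {
  g <- build_grid()
  dates <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  ## constant 1.60 mg m^-2 d^-1 over 1.03e6 m^2 -> ~601 kg a^-1
  load <- annual_internal_load(rep(1.60, 365), dates, g)
  expect_equal(unname(load), 1.60e-6 * 1.03e6 * 365, tolerance = 1e-9)
  expect_equal(unname(load), 601, tolerance = 1e-2)
  expect_equal(unname(annual_internal_load(rep(0, 365), dates, g)), 0)
  ## linearity
  expect_equal(unname(annual_internal_load(rep(3.2, 365), dates, g)),
               2 * unname(load), tolerance = 1e-9)
  expect_error(annual_internal_load(rep(1, 100), dates[1:100], g),
               "complete")
})

test_that("closed-system element totals are conserved", {
  g <- toy_grid()
  p <- closed_params()
  phys <- quiet_phys(g)
  bio <- bio_state(g, srp = 0.05, no3 = 0.8, si = 1.5, diat = 5,
                   green = 4, cyano = 6, daph = 0.1, meso = 0.05)
  sed <- sed_state()
  b0 <- element_budget(bio, sed, g, p)
  denit <- 0
  for (i in 1:1000) {
    r <- step_ecosystem(bio, sed, phys, g, loads = NULL, dt = 1,
                        params = p)
    bio <- r$bio; sed <- r$sed
    denit <- denit + r$diag$denit_n
  }
  b1 <- element_budget(bio, sed, g, p)
  expect_lt(abs(b1[["P"]] - b0[["P"]]) / b0[["P"]], 1e-8)
  expect_lt(abs(b1[["N"]] + denit - b0[["N"]]) / b0[["N"]], 1e-8)
  expect_lt(abs(b1[["Si"]] - b0[["Si"]]) / b0[["Si"]], 1e-8)
  expect_true(all(bio >= 0))
})

test_that("conservation holds for random parameter draws", {
  set.seed(7)
  g <- toy_grid()
  for (k in 1:5) {
    p <- closed_params(
      mu_max = c(diat = runif(1, 1, 3), green = runif(1, 1, 3),
                 cyano = runif(1, 0.5, 2)),
      r_det = runif(1, 0.01, 0.1),
      nitrif = runif(1, 0.01, 0.2),
      denitrif = runif(1, 0.05, 0.5),
      settle = c(diat = runif(1, 0, 0.5), green = runif(1, 0, 0.3),
                 cyano = -runif(1, 0, 0.3)),
      g_max = c(daph = runif(1, 0.3, 1.2), meso = runif(1, 0.2, 0.8)))
    phys <- quiet_phys(g, temp = runif(1, 4, 26))
    bio <- bio_state(g, srp = runif(1, 0.01, 0.2),
                     diat = runif(1, 1, 10), cyano = runif(1, 1, 10))
    sed <- sed_state()
    b0 <- element_budget(bio, sed, g, p)
    denit <- 0
    for (i in 1:120) {
      r <- step_ecosystem(bio, sed, phys, g, params = p)
      bio <- r$bio; sed <- r$sed
      denit <- denit + r$diag$denit_n
    }
    b1 <- element_budget(bio, sed, g, p)
    expect_lt(abs(b1[["P"]] - b0[["P"]]) / b0[["P"]], 1e-8)
    expect_lt(abs(b1[["N"]] + denit - b0[["N"]]) / b0[["N"]], 1e-8)
    expect_lt(abs(b1[["Si"]] - b0[["Si"]]) / b0[["Si"]], 1e-8)
    expect_true(all(bio > -1e-12))
  }
})

test_that("dark abiotic mineralisation consumes oxygen stoichiometrically", {
  g <- toy_grid()
  p <- closed_params(nitrif = 0, denitrif = 0, sod = 0, r_dop = 0,
                     anaer_frac = 0, n_substeps = 10, settle_det = 0,
                     settle = c(diat = 0, green = 0, cyano = 0))
  phys <- quiet_phys(g, temp = 20, par0 = 0)
  bio <- bio_state(g, do = 10, nh4 = 0, no3 = 0, srp = 0, dop = 0,
                   si = 0, detc = 2, detsi = 0, diat = 0, green = 0,
                   cyano = 0, daph = 0, meso = 0)
  sed <- sed_state(org_p = 0, p_exch = 0, org_n = 0, bio_si = 0)
  do0 <- bio[1, "do"]; det0 <- bio[1, "detc"]
  prev_do <- do0
  for (i in 1:30) {
    r <- step_ecosystem(bio, sed, phys, g, params = p)
    bio <- r$bio; sed <- r$sed
    expect_lte(bio[1, "do"], prev_do + 1e-12)
    prev_do <- bio[1, "do"]
  }
  ## closed-form check: aerobic first-order decay at DO >> K is
  ## approximately exponential; O2:N bookkeeping ties NH4 to DO loss
  det_loss <- unname(det0 - mean(bio[, "detc"]))
  nh4_gain <- unname(mean(bio[, "nh4"]))
  expect_equal(nh4_gain, det_loss * p$nc, tolerance = 0.02 * nh4_gain)
  do_loss <- unname(do0 - mean(bio[, "do"]))
  ## oxygen consumed only by carbon mineralisation here
  expect_equal(do_loss, det_loss * p$o2c,
               tolerance = 0.05 * do_loss)
})

test_that("buoyant cyanobacteria accumulate at the surface conservatively", {
  g <- toy_grid()
  p <- closed_params(mu_max = c(diat = 0, green = 0, cyano = 0),
                     resp = c(diat = 0, green = 0, cyano = 0),
                     mort = c(diat = 0, green = 0, cyano = 0),
                     g_max = c(daph = 0, meso = 0),
                     r_det = 0, nitrif = 0, denitrif = 0, sod = 0,
                     settle = c(diat = 0, green = 0, cyano = -0.1))
  phys <- quiet_phys(g)
  bio <- bio_state(g, cyano = 5, diat = 0, green = 0, daph = 0, meso = 0)
  tot0 <- sum(bio[, "cyano"] * g$volume)
  for (i in 1:200) {
    r <- step_ecosystem(bio, sed_state(), phys, g, params = p)
    bio <- r$bio
  }
  expect_equal(sum(bio[, "cyano"] * g$volume), tot0,
               tolerance = 1e-9 * tot0)
  ## top layer enriched, deep layers drained
  expect_gt(bio[1, "cyano"], 5)
  expect_lt(bio[g$n_layers, "cyano"], 0.5)
})

test_that("summer cyanobacterial dominance and Daphnia dominance emerge", {
  run <- eutrophic_run()
  d <- run$derived
  m <- as.integer(format(d$date, "%m"))
  yr <- as.integer(format(d$date, "%Y"))
  ## summer surface community dominated by cyanobacteria
  summer <- m %in% 7:8 & yr > min(yr)
  expect_gt(mean(d$surface_cyano[summer]),
            mean(d$surface_diat[summer] + d$surface_green[summer]))
  ## Daphnia-group biomass exceeds meso-zooplankton in the annual mean
  daph <- extract_band(run$fields$daph, run$grid)
  meso <- extract_band(run$fields$meso, run$grid)
  expect_gt(mean(daph), mean(meso))
  ## all state fields stay non-negative
  for (f in names(run$fields)) expect_true(all(run$fields[[f]] >= 0))
})
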