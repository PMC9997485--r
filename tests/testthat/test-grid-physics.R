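test_that("hypsographic grid reproduces the lake morphometry", {
  g <- build_grid(1.03e6, 11, 6.7, 22)
  expect_equal(g$p, 11 / 6.7 - 1, tolerance = 1e-12)
  expect_equal(sum(g$volume), 1.03e6 * 6.7, tolerance = 1e-6)
  expect_equal(sum(g$volume) / g$surface_area, 6.7, tolerance = 1e-9)
  expect_equal(sum(g$volume), 6.90e6, tolerance = 1e-3)
  expect_true(all(diff(g$area) <= 0))
  expect_equal(sum(g$sed_area), g$surface_area, tolerance = 1e-9)
  ## telescoping: refinement preserves total volume exactly
  g2 <- build_grid(1.03e6, 11, 6.7, 11)
  expect_equal(sum(g$volume), sum(g2$volume), tolerance = 1e-12)
  expect_error(build_grid(mean_depth = 11, max_depth = 11), "mean_depth")
  expect_error(build_grid(n_layers = 3), "n_layers")
})

test_that("band extraction is an exact volume-weighted mean", {
  g <- build_grid()
  expect_equal(extract_band(rep(3.3, g$n_layers), g, c(0, 5)), 3.3)
  x <- runif(g$n_layers)
  expect_equal(extract_band(x, g, c(0, 11)),
               sum(x * g$volume) / sum(g$volume), tolerance = 1e-12)
  ## two-layer toy: volumes 2 and 1, values 1 and 4 -> 2.0
  gt <- build_grid(surface_area = 1, max_depth = 2, mean_depth = 1.5,
                   n_layers = 5)
  expect_equal(extract_band(c(1, 1, 4, 4, 4), gt,
                            c(0, 2)),
               sum(c(1, 1, 4, 4, 4) * gt$volume) / sum(gt$volume))
  ## matrix input gives one value per row
  m <- rbind(x, x)
  expect_equal(extract_band(m, g, c(2, 6)),
               rep(extract_band(x, g, c(2, 6)), 2))
  expect_error(extract_band(x, g, c(5, 5)), "empty")
})

test_that("surface heat flux components behave as bulk formulas", {
  met <- list(air_temp = 15, dewpoint = 10, pressure = 1013,
              wind_u = 3, wind_v = 0, shortwave = 200, cloud = 0.5)
  pp <- physics_params()
  f <- surface_heat_flux(met, 15, pp)
  expect_equal(f$shortwave, (1 - pp$albedo) * 200)
  expect_equal(f$net, f$shortwave + f$longwave + f$sensible + f$latent)
  ## doubling shortwave raises net by exactly (1 - albedo) * dSW
  met2 <- met; met2$shortwave <- 400
  f2 <- surface_heat_flux(met2, 15, pp)
  expect_equal(f2$net - f$net, (1 - pp$albedo) * 200, tolerance = 1e-9)
  ## zero wind: fluxes at the free-convection floor (u_min)
  met0 <- met; met0$wind_u <- 0; met0$wind_v <- 0
  metf <- met; metf$wind_u <- pp$u_min; metf$wind_v <- 0
  f0 <- surface_heat_flux(met0, 15, pp)
  ff <- surface_heat_flux(metf, 15, pp)
  expect_equal(f0$sensible, ff$sensible)
  expect_equal(f0$latent, ff$latent)
  ## warmer water than equilibrium loses heat, colder gains
  eq <- uniroot(function(ts) surface_heat_flux(met, ts, pp)$net,
                c(-5, 40))$root
  expect_lt(surface_heat_flux(met, eq + 1, pp)$net, 0)
  expect_gt(surface_heat_flux(met, eq - 1, pp)$net, 0)
})

test_that("light profile follows layered Beer-Lambert attenuation", {
  lp <- light_profile(100, chl = c(0, 0), kd_background = 0.5,
                      kd_chl = 0.02, dz = c(2, 2))
  expect_equal(lp$interface, 100 * exp(-0.5 * c(0, 2, 4)))
  ## no attenuation at all: constant with depth
  lp0 <- light_profile(100, c(0, 0, 0), 0, 0, 1)
  expect_equal(lp0$interface, rep(100, 4))
  expect_equal(lp0$layer, rep(100, 3))
  ## two-layer toy with k1 = 0.5 over 2 m, k2 = 1.0 over 2 m
  lp2 <- light_profile(100, chl = c(0, 25), kd_background = 0.5,
                       kd_chl = 0.02, dz = c(2, 2))
  expect_equal(lp2$interface[3], 100 * exp(-1) * exp(-2),
               tolerance = 1e-12)
  ## self-shading: more chlorophyll, darker at depth
  dark <- light_profile(100, c(50, 50), 0.5, 0.02, c(2, 2))
  expect_lt(dark$interface[3], lp2$interface[3])
  expect_error(light_profile(100, c(0), -0.1, 0.02), "negative")
})

test_that("diffusion conserves heat and relaxes gradients", {
  g <- build_grid(n_layers = 12)
  x <- seq(20, 6, length.out = 12)
  k <- rep(0.5, 11)
  f <- cbind(x)
  for (i in 1:200) f <- relake:::diffuse_implicit(f, g, k, 1)
  expect_equal(sum(f[, 1] * g$volume), sum(x * g$volume),
               tolerance = 1e-10)
  expect_lt(max(f) - min(f), max(x) - min(x))
  ## long-run limit is the volume-weighted mean
  for (i in 1:5000) f <- relake:::diffuse_implicit(f, g, k, 1)
  expect_equal(unname(f[, 1]),
               rep(sum(x * g$volume) / sum(g$volume), 12),
               tolerance = 1e-6)
})

test_that("convective adjustment matches a brute-force pairwise oracle", {
  ## oracle: repeatedly volume-average any single adjacent unstable pair
  oracle <- function(temp, vol) {
    repeat {
      rho <- relake:::water_density(temp)
      i <- which(rho[-length(rho)] > rho[-1] + 1e-12)
      if (!length(i)) return(temp)
      i <- i[1]
      m <- sum(temp[i:(i + 1)] * vol[i:(i + 1)]) / sum(vol[i:(i + 1)])
      temp[i:(i + 1)] <- m
    }
  }
  set.seed(42)
  g <- build_grid(n_layers = 6)
  for (rep in 1:25) {
    t0 <- runif(6, 2, 25)
    ours <- relake:::convective_adjust(cbind(t0), g)[, 1]
    ref <- oracle(t0, g$volume)
    expect_equal(ours, ref, tolerance = 1e-9)
    rho <- relake:::water_density(ours)
    expect_true(all(diff(rho) >= -1e-9))
    ## heat conserved
    expect_equal(sum(ours * g$volume), sum(t0 * g$volume),
                 tolerance = 1e-8)
  }
  ## cold-over-warm inversion mixes fully monotone in density
  inv <- seq(2, 24, length.out = 6)
  out <- relake:::convective_adjust(cbind(inv), g)[, 1]
  expect_true(all(diff(relake:::water_density(out)) >= -1e-9))
})

test_that("physics step is conservative without forcing and stable", {
  g <- build_grid()
  pp <- physics_params()
  ## a met record whose fluxes nearly vanish: no sun, equilibrium temp
  met <- list(air_temp = 10, dewpoint = 10, pressure = 1013,
              wind_u = 2, wind_v = 0, shortwave = 0, cloud = 0.5)
  eq <- uniroot(function(ts) surface_heat_flux(met, ts, pp)$net,
                c(-5, 40))$root
  st <- list(temp = rep(eq, g$n_layers))
  out <- step_physics(st, g, met, inflow = 0, dt = 1, pp)
  expect_equal(out$temp, rep(eq, g$n_layers), tolerance = 1e-6)
  ## pure internal redistribution conserves the heat content
  st2 <- list(temp = seq(18, 6, length.out = g$n_layers))
  h0 <- sum(st2$temp * g$volume)
  ## switch off all surface exchange by balancing at equilibrium is not
  ## possible for an arbitrary profile; instead check the transport core
  f <- cbind(st2$temp)
  k <- relake:::eddy_diffusivity(st2$temp, g, 4, pp)
  f <- relake:::diffuse_implicit(f, g, k, 1)
  f <- relake:::convective_adjust(f, g)
  expect_equal(sum(f[, 1] * g$volume), h0, tolerance = 1e-8 * h0)
})

test_that("groundwater through-flow keeps volume and moves mass upward", {
  g <- build_grid()
  n <- g$n_layers
  conc <- matrix(0, n, 1)
  ## steady inflow of tracer at the bottom accumulates and exits on top
  q <- 1728   # m^3 d^-1
  for (i in 1:2000) conc <- relake:::advect_throughflow(conc, g, q, 1, 1)
  expect_true(all(diff(conc[, 1]) >= -1e-9))   # increasing with depth
  expect_true(conc[n, 1] <= 1 + 1e-9)
  ## without inflow nothing changes
  expect_equal(relake:::advect_throughflow(conc, g, 0, 1, 1), conc)
})
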