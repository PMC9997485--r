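## Shared, lazily built fixtures. Heavy simulations are run once per test
## session and reused across test files.
.relake_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.relake_cache[[name]])) .relake_cache[[name]] <- builder()
  .relake_cache[[name]]
}

## Six-year eutrophic run (no interventions), used for seasonal-pattern
## and dominance checks.
eutrophic_run <- function() {
  cached("eutrophic", function() {
    met <- generate_forcing(forcing_config(1980, 1985, seed = 11))
    cfg <- barleber_preset(forcing = met, spinup_years = 2)
    cfg$events <- list()
    run_lake(cfg)
  })
}

## The full historical factorial (1980-2021, 4 detrended variants); this
## is the expensive fixture behind the scenario-attribution checks.
factorial_cached <- function() {
  cached("factorial", function() {
    cfg <- barleber_preset(seed = 1, spinup_years = 2)
    run_factorial(cfg)
  })
}

## Small grid + quiescent physical state for ecosystem unit tests.
toy_grid <- function(n_layers = 8) build_grid(n_layers = n_layers)

quiet_phys <- function(grid, temp = 15, par0 = 60) {
  list(temp = rep(temp, grid$n_layers),
       par = par0 * exp(-0.5 * grid$z_mid))
}

## Closed-system ecosystem parameters: no sediment diffusion, no gas
## exchange (loads are simply not passed).
closed_params <- function(...) {
  eco_params(k_diff = 0, gas_exchange = FALSE, ...)
}
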