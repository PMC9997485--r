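#' Save / load an experiment preset as YAML
#'
#' Serialises the reproducible part of a configuration — the forcing
#' generator settings, scalar physical and biogeochemical parameters,
#' loading spec scalars and the event list — to a human-readable YAML
#' file. Matrices and derived tables are rebuilt from these on load.
#'
#' @param config a [lake_config()].
#' @param path file path.
#' @return `write_preset_yaml` returns `path` invisibly;
#'   `read_preset_yaml` returns a rebuilt `"lake_config"`.
#' @export
write_preset_yaml <- function(config, path) {
  fc <- attr(config$forcing, "config")
  as_plain <- function(x) lapply(unclass(x), function(v)
    if (is.matrix(v)) as.list(as.data.frame(v)) else v)
  obj <- list(
    forcing = unclass(fc),
    physics = unclass(config$physics),
    eco = as_plain(config$eco),
    loading = list(
      tp_atmospheric = config$loading$tp_atmospheric,
      tp_groundwater = config$loading$tp_groundwater,
      tp_diffusive = config$loading$tp_diffusive,
      landuse = as.list(config$loading$landuse),
      tn_deposition_rate = config$loading$tn_deposition_rate,
      tn_deposition_area = config$loading$tn_deposition_area,
      annual_inflow_volume = config$loading$annual_inflow_volume,
      gw_no3_frac = config$loading$gw_no3_frac),
    grid = list(surface_area = config$grid$surface_area,
                max_depth = config$grid$max_depth,
                mean_depth = config$grid$mean_depth,
                n_layers = config$grid$n_layers),
    events = lapply(config$events, function(e)
      list(date = format(e$date), kind = e$kind, factor = e$factor,
           post_srp = e$post_srp, post_dop = e$post_dop,
           post_part_p = e$post_part_p)),
    spinup_years = config$spinup_years
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @export
read_preset_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  fc <- do.call(forcing_config, obj$forcing[names(obj$forcing) %in%
                                              names(formals(forcing_config))])
  grid <- do.call(build_grid, obj$grid)
  physics <- do.call(physics_params,
                     obj$physics[names(obj$physics) %in%
                                   names(formals(physics_params))])
  eco_args <- obj$eco[names(obj$eco) %in% names(formals(eco_params))]
  eco_args <- lapply(eco_args, function(v)
    if (is.list(v)) do.call(cbind, v) else unlist(v))
  ## named vectors round-trip as lists; restore names where needed
  for (nm in c("mu_max", "theta_growth", "k_p", "k_n", "k_light",
               "resp", "mort", "settle", "g_max", "resp_zoo")) {
    if (!is.null(eco_args[[nm]]) && is.null(names(eco_args[[nm]])))
      names(eco_args[[nm]]) <- if (nm %in% c("g_max", "resp_zoo"))
        ZOO else PHYTO
  }
  eco <- do.call(eco_params, eco_args)
  loading <- loading_spec(
    tp_atmospheric = obj$loading$tp_atmospheric,
    tp_groundwater = obj$loading$tp_groundwater,
    tp_diffusive = obj$loading$tp_diffusive,
    landuse = as.data.frame(obj$loading$landuse),
    tn_deposition_rate = obj$loading$tn_deposition_rate,
    tn_deposition_area = obj$loading$tn_deposition_area,
    annual_inflow_volume = obj$loading$annual_inflow_volume,
    gw_no3_frac = obj$loading$gw_no3_frac)
  events <- lapply(obj$events, function(e)
    intervention_event(e$date, e$kind, e$factor, e$post_srp, e$post_dop,
                       e$post_part_p))
  lake_config(forcing = generate_forcing(fc), grid = grid,
              physics = physics, eco = eco, loading = loading,
              events = events, bio_init = bio_state(grid),
              spinup_years = obj$spinup_years)
}

#' Write daily profile output as long-format CSV
#'
#' One row per (date, depth, variable): the standard interchange format
#' for profile output.
#'
#' @param run a [run_lake()] result.
#' @param path file path.
#' @param variables field names to export (default temperature and
#'   oxygen).
#' @param thin keep every `thin`-th day (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(run, path, variables = c("temp", "do"),
                               thin = 1) {
  sel <- seq(1, length(run$dates), by = thin)
  out <- do.call(rbind, lapply(variables, function(v) {
    fld <- run$fields[[v]][sel, , drop = FALSE]
    data.frame(date = rep(run$dates[sel], times = run$grid$n_layers),
               depth = rep(run$grid$z_mid, each = length(sel)),
               variable = v, value = as.vector(fld))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
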