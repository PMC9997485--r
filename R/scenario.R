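#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test: `S` is the sum over all pairs of
#' the sign of the later-minus-earlier difference; its variance is
#' tie-corrected; `Z` applies a continuity correction; the two-sided p
#' comes from the normal approximation. The accompanying Sen's slope is
#' the median of all pairwise slopes.
#'
#' @param x numeric series (annual values), `n >= 4`.
#' @return object of class `"trend_result"`: `S`, `var_s`, `Z`, `p`,
#'   `sen_slope`, `n`.
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  s <- 0
  for (i in seq_len(n - 1))
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
  else if (s < 0) (s + 1) / sqrt(var_s)
  else 0
  p <- if (var_s > 0) 2 * (1 - stats::pnorm(abs(z))) else 1
  structure(list(S = s, var_s = var_s, Z = z, p = p,
                 sen_slope = sen_slope(x), n = n),
            class = "trend_result")
}

#' Sen's slope
#'
#' Median of all pairwise slopes `(x_j - x_i)/(j - i)`, in units per
#' index step (per year for annual series).
#'
#' @param x numeric series, `n >= 2`.
#' @return the slope.
#' @export
sen_slope <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  slopes <- unlist(lapply(seq_len(n - 1), function(i)
    (x[(i + 1):n] - x[i]) / (seq_len(n - i))))
  stats::median(slopes)
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall: S = %d, Z = %.3f, p = %.4g; Sen's slope = %.5g /a (n = %d)\n",
    x$S, x$Z, x$p, x$sen_slope, x$n))
  invisible(x)
}

#' Run the warming-by-internal-loading factorial
#'
#' Runs the 2 x 2 scenario design: `clim+` uses the factual (warming)
#' forcing, `clim-` the detrended counterfactual variants from
#' [make_picontrol_variants()]; `intP+` follows the historical event
#' sequence (internal loading active outside the capped 1986-2016
#' window), `intP-` keeps the sediment P diffusion rate at its
#' post-capping value throughout (no internal-loading onset; the
#' water-column P resets of the precipitation events are retained so the
#' two arms differ only in the diffusion-rate trajectory). All other
#' settings are identical across cells.
#'
#' @param config a [lake_config()] for the factual historical run (the
#'   `clim+`/`intP+` cell).
#' @param n_clim_minus_variants number of detrended forcing variants
#'   (default 4).
#' @param cap_factor diffusion scaling defining "no internal loading".
#' @param variant_seed seed offset for the counterfactual noise.
#' @return object of class `"lake_factorial"`: `runs` (named list of
#'   [run_lake()] outputs), `design` (data frame with `clim`, `intp`,
#'   `variant`, `key`).
#' @export
run_factorial <- function(config, n_clim_minus_variants = 4,
                          cap_factor = 1e-3, variant_seed = 100L) {
  stopifnot(inherits(config, "lake_config"))
  variants <- make_picontrol_variants(config$forcing,
                                      n_clim_minus_variants,
                                      seed = variant_seed)
  intp_minus <- function(cfg) {
    cfg$eco$k_diff <- cfg$eco$k_diff * cap_factor
    cfg$events <- lapply(
      Filter(function(e) e$kind == "p_precipitation", cfg$events),
      function(e) { e$factor <- 1; e })
    cfg
  }
  with_forcing <- function(cfg, f) { cfg$forcing <- f; cfg }

  design <- list()
  runs <- list()
  add <- function(clim, intp, variant, cfg) {
    key <- sprintf("%s/%s%s", clim, intp,
                   if (clim == "clim-") paste0("/v", variant) else "")
    runs[[key]] <<- run_lake(cfg)
    design[[key]] <<- data.frame(clim = clim, intp = intp,
                                 variant = variant, key = key)
  }
  add("clim+", "intP+", 0, config)
  add("clim+", "intP-", 0, intp_minus(config))
  for (v in seq_along(variants)) {
    add("clim-", "intP+", v, with_forcing(config, variants[[v]]))
    add("clim-", "intP-", v, intp_minus(with_forcing(config,
                                                     variants[[v]])))
  }
  structure(list(runs = runs, design = do.call(rbind, design)),
            class = "lake_factorial")
}

## Annual means of one derived response for every factorial cell;
## clim- cells are averaged over the variants (ensemble mean), giving a
## balanced 2x2 table with years as replicates.
factorial_response <- function(fact, response = "surface_cyano",
                               years = 2016:2018) {
  des <- fact$design
  rows <- lapply(seq_len(nrow(des)), function(i) {
    a <- fact$runs[[des$key[i]]]$annual
    a <- a[a$year %in% years, c("year", response)]
    data.frame(clim = des$clim[i], intp = des$intp[i],
               variant = des$variant[i], year = a$year,
               value = a[[response]])
  })
  tab <- do.call(rbind, rows)
  stats::aggregate(value ~ clim + intp + year, data = tab, FUN = mean)
}

#' Two-way ANOVA attribution of the factorial response
#'
#' Decomposes the variance of the (variant-averaged) annual-mean response
#' across the four factorial cells into internal-loading, warming and
#' interaction sums of squares, with years as replicates. Contributions
#' are normalised over the three effect sums of squares (excluding the
#' residual) so they add to 100 %. Also reports the percentage increase
#' of the factual cell over the no-warming/no-internal-loading cell.
#'
#' @param fact a [run_factorial()] result.
#' @param response derived-series column (default `"surface_cyano"`, the
#'   0-1 m cyanobacterial biomass).
#' @param years replicate years (default 2016-2018).
#' @return object of class `"attribution_result"`: `cell_means`, the
#'   ANOVA table `ss` (`intp`, `clim`, `interaction`, `residual`,
#'   `total`), `contributions` (% of effect SS), `increase_pct`.
#' @export
attribute_factorial <- function(fact, response = "surface_cyano",
                                years = 2016:2018) {
  tab <- factorial_response(fact, response, years)
  tab$clim <- factor(tab$clim, levels = c("clim-", "clim+"))
  tab$intp <- factor(tab$intp, levels = c("intP-", "intP+"))
  if (nrow(tab) < 8 || length(unique(tab$year)) < 2)
    stop("need all four cells with at least two replicate years")
  fit <- stats::aov(value ~ intp * clim, data = tab)
  an <- stats::anova(fit)
  ss <- c(intp = an["intp", "Sum Sq"],
          clim = an["clim", "Sum Sq"],
          interaction = an["intp:clim", "Sum Sq"],
          residual = an["Residuals", "Sum Sq"])
  ss["total"] <- sum(ss)
  eff <- ss[c("intp", "clim", "interaction")]
  contributions <- 100 * eff / sum(eff)
  cm <- stats::aggregate(value ~ clim + intp, data = tab, FUN = mean)
  m_factual <- cm$value[cm$clim == "clim+" & cm$intp == "intP+"]
  m_base <- cm$value[cm$clim == "clim-" & cm$intp == "intP-"]
  structure(list(cell_means = cm, ss = ss,
                 contributions = contributions,
                 increase_pct = 100 * (m_factual - m_base) / m_base,
                 response = response, years = years),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Factorial attribution of %s (%d-%d)\n", x$response,
              min(x$years), max(x$years)))
  cat(sprintf("  factual vs base increase: %.1f %%\n", x$increase_pct))
  cat(sprintf(
    "  contributions: internal P %.1f %%, warming %.1f %%, interaction %.1f %%\n",
    x$contributions[["intp"]], x$contributions[["clim"]],
    x$contributions[["interaction"]]))
  invisible(x)
}

#' Warming effect within the active-internal-loading arm
#'
#' Percentage by which the factual (warming) climate raises an annual-mean
#' response relative to the counterfactual climate (variant-averaged),
#' within the `intP+` arm of the factorial.
#'
#' @param fact a [run_factorial()] result.
#' @param response derived-series column, e.g. `"bottom_tp"` or
#'   `"surface_cyano"`.
#' @param years year(s) to average (default 2016).
#' @return percentage excess of `clim+` over `clim-`.
#' @export
warming_effect <- function(fact, response = "bottom_tp", years = 2016) {
  tab <- factorial_response(fact, response, years)
  tab <- tab[tab$intp == "intP+", ]
  m <- tapply(tab$value, tab$clim, mean)
  100 * (m[["clim+"]] - m[["clim-"]]) / m[["clim-"]]
}

#' Trend report over annual band means
#'
#' Mann-Kendall test and Sen's slope for the annual means of the
#' requested derived series of a run.
#'
#' @param run a [run_lake()] result.
#' @param variables derived-series columns (defaults: whole-lake and
#'   epilimnion temperature, whole-lake oxygen).
#' @return data frame with one row per variable: Sen's slope (units per
#'   year), Mann-Kendall S, Z and p.
#' @export
trend_report <- function(run, variables = c("wl_temp", "epi_temp",
                                            "wl_do")) {
  a <- run$annual
  if (nrow(a) < 10) stop("need at least 10 annual values")
  rows <- lapply(variables, function(v) {
    mk <- mann_kendall(a[[v]])
    data.frame(variable = v, sen_slope = mk$sen_slope, S = mk$S,
               Z = mk$Z, p = mk$p, n = mk$n)
  })
  do.call(rbind, rows)
}
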