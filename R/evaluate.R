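#' Relative error of a simulation against observations
#'
#' `RE = sum(|sim_i - obs_i|) / sum(obs_i)`; lower is better, 0 is a
#' perfect fit, and doubling every value gives RE = 1. Scale-invariant
#' under a common positive rescaling of both series.
#'
#' @param obs,sim matched numeric vectors; `sum(obs)` must be positive.
#' @return the relative error.
#' @export
relative_error <- function(obs, sim) {
  stopifnot(length(obs) == length(sim), length(obs) >= 1)
  if (sum(obs) <= 0) stop("sum of observations must be positive")
  sum(abs(sim - obs)) / sum(obs)
}

#' Pearson correlation of a simulation against observations
#'
#' @param obs,sim matched numeric vectors, at least 3 pairs, both
#'   non-constant.
#' @return the product-moment correlation coefficient.
#' @export
pearson_r <- function(obs, sim) {
  stopifnot(length(obs) == length(sim), length(obs) >= 3)
  if (stats::sd(obs) == 0 || stats::sd(sim) == 0)
    stop("correlation undefined for constant series")
  stats::cor(obs, sim)
}

#' Default performance-classification thresholds
#'
#' Per-variable cut points at the 20th/50th/80th percentile positions of a
#' reference population of published aquatic-ecosystem model performances.
#' R cut points are increasing (higher is better), RE cut points
#' decreasing (lower is better). The exact reference percentiles are not
#' public, so this table is an editable default and every report carries
#' the raw R/RE values alongside the categories.
#'
#' @return data frame with columns `variable`, `r20`, `r50`, `r80`,
#'   `re20`, `re50`, `re80`.
#' @export
default_thresholds <- function() {
  vars <- c("temp", "do", "tn", "no3", "nh4", "tp", "srp", "si",
            "chl", "cyano", "diat")
  data.frame(
    variable = vars,
    r20 = c(0.90, 0.60, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45, 0.40, 0.40,
            0.40),
    r50 = c(0.95, 0.75, 0.60, 0.60, 0.60, 0.60, 0.60, 0.60, 0.55, 0.55,
            0.55),
    r80 = c(0.98, 0.85, 0.75, 0.75, 0.75, 0.75, 0.75, 0.75, 0.70, 0.70,
            0.70),
    re20 = c(0.15, 0.50, 0.70, 0.70, 0.70, 0.70, 0.70, 0.70, 0.80, 0.80,
             0.80),
    re50 = c(0.10, 0.35, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.60, 0.60,
             0.60),
    re80 = c(0.05, 0.20, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.40, 0.40,
             0.40)
  )
}

#' Classify a performance metric into the four-category scheme
#'
#' Maps an R or RE value onto the percentile bands of the reference model
#' population: fair (level 1, below the 20th percentile), satisfactory
#' (20-50), good (50-80), excellent (above the 80th). R uses >=
#' comparisons, RE uses <=; boundary values belong to the higher
#' category.
#'
#' @param value the metric value.
#' @param variable variable id matching a row of `thresholds`.
#' @param metric `"R"` or `"RE"`.
#' @param thresholds a [default_thresholds()]-style data frame.
#' @return integer level 1-4.
#' @export
classify_metric <- function(value, variable, metric = c("R", "RE"),
                            thresholds = default_thresholds()) {
  metric <- match.arg(metric)
  row <- thresholds[thresholds$variable == variable, ]
  if (nrow(row) != 1) stop("no thresholds for variable: ", variable)
  if (metric == "R") {
    cuts <- c(row$r20, row$r50, row$r80)
    1L + sum(value >= cuts)
  } else {
    cuts <- c(row$re20, row$re50, row$re80)
    1L + sum(value <= cuts)
  }
}

#' Combine the R and RE category levels
#'
#' The combined category is the median-or-lower of the two levels,
#' formalised as `floor((level_R + level_RE)/2)`: satisfactory + good
#' gives satisfactory, satisfactory + excellent gives good, and equal
#' levels map to themselves.
#'
#' @param level_r,level_re integer levels 1-4.
#' @return integer combined level 1-4.
#' @export
combine_categories <- function(level_r, level_re) {
  stopifnot(level_r %in% 1:4, level_re %in% 1:4)
  as.integer(floor((level_r + level_re) / 2))
}

CATEGORY_NAMES <- c("fair", "satisfactory", "good", "excellent")

## Per-layer matrix of a simulated (possibly derived) variable.
sim_field <- function(run, v) {
  ep <- run$config$eco
  biota_c <- function()
    (run$fields$diat + run$fields$green + run$fields$cyano) *
      ep$c_per_chl + run$fields$daph + run$fields$meso
  switch(v,
         chl = run$fields$diat + run$fields$green + run$fields$cyano,
         tp = run$fields$srp + run$fields$dop +
           (run$fields$detc + biota_c()) * ep$pc,
         tn = run$fields$nh4 + run$fields$no3 +
           (run$fields$detc + biota_c()) * ep$nc,
         if (!is.null(run$fields[[v]])) run$fields[[v]]
         else stop("unknown variable: ", v))
}

#' Evaluate a model run against an observation set
#'
#' Matches simulated fields to observations by variable, date and depth
#' (volume-weighted band means when `depth` is `NA`), computes R and RE
#' per variable and classifies them.
#'
#' @param run a [run_lake()] result.
#' @param obs data frame with columns `variable`, `date`, `depth`
#'   (m; `NA` for whole-column volume-weighted values) and `value`, as
#'   produced by [synthetic_observations()].
#' @param thresholds classification table, see [default_thresholds()].
#' @return data frame of class `"eval_result"`: per variable R, RE, the
#'   two levels and the combined category.
#' @export
evaluate_run <- function(run, obs, thresholds = default_thresholds()) {
  res <- lapply(unique(obs$variable), function(v) {
    ob <- obs[obs$variable == v, ]
    fld <- sim_field(run, v)
    it <- match(ob$date, run$dates)
    ok <- !is.na(it)
    ob <- ob[ok, ]; it <- it[ok]
    sim <- vapply(seq_len(nrow(ob)), function(i) {
      if (is.na(ob$depth[i])) {
        extract_band(fld[it[i], ], run$grid)
      } else {
        il <- findInterval(ob$depth[i], run$grid$z, all.inside = TRUE)
        fld[it[i], il]
      }
    }, numeric(1))
    r <- pearson_r(ob$value, sim)
    re <- relative_error(ob$value, sim)
    lr <- classify_metric(r, v, "R", thresholds)
    lre <- classify_metric(re, v, "RE", thresholds)
    data.frame(variable = v, n = nrow(ob), R = r, RE = re,
               level_R = lr, level_RE = lre,
               category = CATEGORY_NAMES[combine_categories(lr, lre)])
  })
  out <- do.call(rbind, res)
  class(out) <- c("eval_result", "data.frame")
  out
}

#' Synthetic observation set
#'
#' Samples a model run at five depths (0.5, 2.5, 5.0, 7.0, 9.0 m) at
#' biweekly intervals and perturbs the values with multiplicative
#' lognormal noise, emulating a field monitoring campaign for
#' calibration/evaluation experiments. This is a synthetic stand-in for a
#' real monitoring data set.
#'
#' @param run a [run_lake()] result.
#' @param variables variables to sample (default temperature, oxygen,
#'   nutrients and the phytoplankton groups).
#' @param depths sampling depths (m).
#' @param interval days between sampling dates (default 14).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param seed RNG seed.
#' @return data frame with columns `variable`, `date`, `depth`, `value`,
#'   `unit`.
#' @export
synthetic_observations <- function(run,
                                   variables = c("temp", "do", "srp",
                                                 "no3", "si", "cyano",
                                                 "diat"),
                                   depths = c(0.5, 2.5, 5.0, 7.0, 9.0),
                                   interval = 14, noise_cv = 0.05,
                                   seed = 7L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  units <- c(temp = "degC", do = "mg/L", srp = "mgP/L", no3 = "mgN/L",
             nh4 = "mgN/L", si = "mgSi/L", cyano = "mg chl/m3",
             diat = "mg chl/m3", chl = "mg chl/m3", tp = "mgP/L",
             tn = "mgN/L")
  sel <- seq(1, length(run$dates), by = interval)
  out <- do.call(rbind, lapply(variables, function(v) {
    fld <- sim_field(run, v)
    do.call(rbind, lapply(depths, function(dp) {
      il <- findInterval(dp, run$grid$z, all.inside = TRUE)
      val <- fld[sel, il]
      noise <- exp(stats::rnorm(length(val), sd = noise_cv))
      data.frame(variable = v, date = run$dates[sel], depth = dp,
                 value = val * noise,
                 unit = unname(units[v]))
    }))
  }))
  rownames(out) <- NULL
  out
}
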