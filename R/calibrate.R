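#' Staged ("bottom-up") parameter calibration
#'
#' Optimises model parameters against an observation set in ordered
#' stages, mirroring the bottom-up practice of calibrating the physics
#' first, then oxygen and nutrients, then the plankton. Within a stage a
#' seeded Latin-hypercube sample of the bounded parameter box is
#' evaluated, the best point is refined by a Nelder-Mead simplex search
#' (box-clamped), and the stage's result is frozen before the next stage
#' starts. The objective is the unweighted mean relative error over the
#' stage's target variables.
#'
#' @param simulate_fn function taking a named parameter vector (the union
#'   of all stage parameters seen so far) and returning a [run_lake()]
#'   result.
#' @param obs observation data frame (see [evaluate_run()]).
#' @param stages list of stages; each a list with `params` (data frame
#'   with columns `name`, `lower`, `upper`), `targets` (character vector
#'   of observed variables), `budget` (Latin-hypercube sample size) and
#'   `refine` (maximum simplex iterations).
#' @param seed RNG seed for the space-filling sample.
#' @param thresholds classification table for the per-stage evaluation
#'   report.
#' @return object of class `"lake_calib"`: `par` (named best parameter
#'   vector), `objective`, `trace` (one row per evaluation: stage,
#'   parameters, objective, best-so-far), and `stage_eval` (per-stage
#'   [evaluate_run()] tables at the stage optimum).
#' @export
calibrate <- function(simulate_fn, obs, stages, seed = 1L,
                      thresholds = default_thresholds()) {
  stopifnot(length(stages) >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  frozen <- numeric(0)
  trace <- list()
  stage_eval <- list()

  for (si in seq_along(stages)) {
    st <- stages[[si]]
    pnames <- st$params$name
    lower <- st$params$lower; upper <- st$params$upper
    if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
        any(lower >= upper) && any(lower > upper))
      stop("stage ", si, ": bounds must be finite with lower <= upper")
    k <- length(pnames)

    obs_stage <- obs[obs$variable %in% st$targets, ]
    if (nrow(obs_stage) == 0)
      stop("stage ", si, ": no observations for targets ",
           paste(st$targets, collapse = ", "))

    objective <- function(x) {
      x <- pmin(upper, pmax(lower, x))
      par <- c(frozen, stats::setNames(x, pnames))
      run <- simulate_fn(par)
      ev <- evaluate_run(run, obs_stage, thresholds)
      mean(ev$RE)
    }

    if (all(upper == lower)) {
      cand <- matrix(lower, 1, k)
    } else {
      u <- lhs::randomLHS(max(1, st$budget), k)
      cand <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
    }
    vals <- apply(cand, 1, objective)
    best_i <- which.min(vals)
    best_x <- cand[best_i, ]
    best_v <- vals[best_i]
    tr <- data.frame(stage = si, eval = seq_along(vals),
                     objective = vals,
                     best = cummin(vals))

    if (!is.null(st$refine) && st$refine > 0 && any(upper > lower)) {
      opt <- stats::optim(best_x, objective, method = "Nelder-Mead",
                          control = list(maxit = st$refine))
      if (opt$value <= best_v) {
        best_x <- pmin(upper, pmax(lower, opt$par))
        best_v <- opt$value
      }
      tr2 <- data.frame(stage = si,
                        eval = nrow(tr) + seq_len(1),
                        objective = opt$value,
                        best = min(tr$best[nrow(tr)], opt$value))
      tr <- rbind(tr, tr2)
    }

    frozen <- c(frozen, stats::setNames(best_x, pnames))
    trace[[si]] <- tr
    run_best <- simulate_fn(frozen)
    stage_eval[[si]] <- evaluate_run(run_best, obs_stage, thresholds)
  }

  structure(list(par = frozen, objective = best_v,
                 trace = do.call(rbind, trace),
                 stage_eval = stage_eval),
            class = "lake_calib")
}

#' @export
print.lake_calib <- function(x, ...) {
  cat("Staged lake-model calibration\n")
  cat("  best parameters:\n")
  print(round(x$par, 6))
  cat(sprintf("  final objective (mean RE): %.4f\n", x$objective))
  invisible(x)
}

#' @export
coef.lake_calib <- function(object, ...) object$par
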