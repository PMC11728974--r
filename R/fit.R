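#' Fitting configuration
#'
#' Collects the knobs of the two-stage estimation. Bounds default to the
#' network's [param_registry()] boxes; any subset can be overridden through
#' `lower`/`upper` named vectors. The optimizer budget defaults are sized for
#' desk-scale runs.
#'
#' @param budget Stage-1 pattern-search evaluation budget.
#' @param maxit Stage-2 quasi-Newton iteration cap.
#' @param tol Stage-2 relative convergence tolerance.
#' @param step Stage-1 initial mesh step (fraction of each box width).
#' @param lower,upper Optional named numeric vectors overriding registry
#'   bounds for some or all parameters.
#' @param start Optional named start vector (default: box midpoints).
#' @param penalty_weight Weight of the intermediate-bound penalty.
#' @param bound Intermediate concentration bound (pmol/ug DNA).
#' @param dense_step Internal grid step (minutes) for the penalty maxima.
#' @param weights Optional named per-species cost weights (0 excludes).
#' @param replicates `"mean"` or `"all"` (see [scaled_fit_error()]).
#' @return List of class `fit_config`.
#' @export
fit_config <- function(budget = 2000, maxit = 100, tol = 1e-8, step = 0.25,
                       lower = NULL, upper = NULL, start = NULL,
                       penalty_weight = 1000, bound = 10, dense_step = 0.1,
                       weights = NULL, replicates = "mean") {
  structure(list(budget = budget, maxit = maxit, tol = tol, step = step,
                 lower = lower, upper = upper, start = start,
                 penalty_weight = penalty_weight, bound = bound,
                 dense_step = dense_step, weights = weights,
                 replicates = replicates),
            class = "fit_config")
}

# Resolve bounds and start vectors against the registry.
fit_bounds <- function(network, config) {
  reg <- param_registry(network)
  lower <- stats::setNames(reg$lower, reg$name)
  upper <- stats::setNames(reg$upper, reg$name)
  if (!is.null(config$lower)) lower[names(config$lower)] <- config$lower
  if (!is.null(config$upper)) upper[names(config$upper)] <- config$upper
  if (any(upper < lower)) stop("inconsistent parameter bounds")
  start <- (lower + upper) / 2
  if (!is.null(config$start)) start[names(config$start)] <- config$start
  start <- pmin(pmax(start, lower), upper)
  list(lower = lower, upper = upper, start = start)
}

#' Fit the model to multi-condition data
#'
#' Two-stage hybrid estimation of all free parameters (kinetic constants and
#' initial enzyme levels, shared across conditions) against one or more
#' condition datasets: a seeded mesh pattern search ([direct_search()])
#' explores the bounded box, then a bounded quasi-Newton refinement
#' ([local_refine()]) polishes the result. The objective is the penalized
#' scaled fit-error ([penalized_cost()]). Conditions are fitted jointly.
#'
#' @param datasets Tidy measurement data frame (see [read_timeseries()])
#'   covering one or more conditions.
#' @param network A `cyber_network`.
#' @param profiles Named list of [input_profiles()], one per condition.
#' @param config A [fit_config()].
#' @param seed Integer seed (poll ordering of stage 1); fits are reproducible
#'   bit-for-bit given seed, config and data.
#' @return Object of class `fit_result`: estimated `params`, `cost`,
#'   `penalty`, stage costs (`cost_start`, `cost_stage1`, `cost_stage2`),
#'   `intermediate_max`, fitted `trajectories` (tidy data frame over the
#'   measurement grid), `evals`, `seed` and `config`.
#' @export
fit_model <- function(datasets, network, profiles, config = fit_config(),
                      seed = 1) {
  if (is.null(datasets) || nrow(datasets) == 0L) stop("empty dataset")
  prep <- prep_fit_data(datasets, network, config$weights, config$replicates)
  missing_prof <- setdiff(names(prep), names(profiles))
  if (length(missing_prof)) {
    stop("no input profiles for condition(s): ",
         paste(missing_prof, collapse = ", "))
  }
  b <- fit_bounds(network, config)
  nm <- names(b$start)
  width <- b$upper - b$lower
  width[width == 0] <- 1
  # Optimize on the unit box so mesh steps and finite-difference gradient
  # steps are commensurate across parameters of very different magnitudes.
  to_unit <- function(theta) (theta - b$lower) / width
  from_unit <- function(z) b$lower + z * width
  objective <- function(z) {
    theta <- stats::setNames(from_unit(z), nm)
    out <- tryCatch(
      penalized_cost(theta, datasets, network, profiles,
                     penalty_weight = config$penalty_weight,
                     bound = config$bound, dense_step = config$dense_step,
                     prep = prep),
      error = function(e) NULL)
    if (is.null(out) || !is.finite(out$total)) 1e12 else out$total
  }
  z0 <- to_unit(b$start)
  zeros <- rep(0, length(z0))
  ones <- rep(1, length(z0))
  f_start <- objective(z0)
  s1 <- direct_search(objective, zeros, ones, z0, seed = seed,
                      budget = config$budget, step = config$step)
  s2 <- local_refine(objective, s1$par, zeros, ones,
                     maxit = config$maxit, tol = config$tol)
  params <- stats::setNames(from_unit(s2$par), nm)
  final <- penalized_cost(params, datasets, network, profiles,
                          penalty_weight = config$penalty_weight,
                          bound = config$bound,
                          dense_step = config$dense_step, prep = prep)
  trajs <- lapply(prep, function(pc) {
    traj <- simulate_model(network, params, profiles[[pc$condition]],
                           times = pc$times,
                           y0 = initial_state(network, params, pc$y0))
    as.data.frame(traj)
  })
  structure(list(params = params, cost = final$cost, penalty = final$penalty,
                 total = final$total,
                 intermediate_max = final$intermediate_max,
                 cost_start = f_start, cost_stage1 = s1$value,
                 cost_stage2 = s2$value,
                 trajectories = do.call(rbind, c(trajs,
                                                 make.row.names = FALSE)),
                 evals = c(stage1 = s1$evals, stage2 = s2$evals),
                 seed = seed, config = config, variant = network$variant),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Cybernetic model fit (", x$variant, " variant)\n", sep = "")
  cat(sprintf("  cost %.5g (+ penalty %.3g); stages: start %.5g -> %.5g -> %.5g\n",
              x$cost, x$penalty, x$cost_start, x$cost_stage1, x$cost_stage2))
  cat("  evaluations: stage1 ", x$evals[["stage1"]], ", stage2 ",
      x$evals[["stage2"]], "; seed ", x$seed, "\n", sep = "")
  r <- tryCatch(switch_ratio(x$params[["kPGH2"]],
                             x$params[[if (x$variant == "EPA") "kPGH3" else
                                       "kPD"]]),
                error = function(e) NA_real_)
  cat(sprintf("  switch ratio kPGH3/kPGH2 = %.3g\n", r))
  invisible(x)
}
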