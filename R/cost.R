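# Precompute everything about the data that the cost function needs, so the
# optimization loop only integrates and sums.
prep_fit_data <- function(datasets, network, weights = NULL,
                          replicates = c("mean", "all")) {
  replicates <- match.arg(replicates)
  check_timeseries(datasets)
  unknown <- setdiff(unique(datasets$species), network$metabolites)
  if (length(unknown)) {
    stop("measured species not in the network: ",
         paste(unknown, collapse = ", "))
  }
  conds <- unique(datasets$condition)
  prep <- list()
  for (cond in conds) {
    sub <- datasets[datasets$condition == cond, , drop = FALSE]
    times <- sort(unique(sub$time_min))
    species <- sort(unique(sub$species))
    means <- tapply(sub$value, list(sub$time_min, sub$species), mean)
    means <- means[as.character(times), species, drop = FALSE]
    if (anyNA(means)) stop("incomplete species x time grid for ", cond)
    if (replicates == "mean") {
      maxima <- apply(means, 2, max)
    } else {
      maxima <- vapply(species, function(s)
        max(sub$value[sub$species == s]), numeric(1))
    }
    w <- stats::setNames(rep(1, length(species)), species)
    if (!is.null(weights)) {
      known <- intersect(names(weights), species)
      w[known] <- weights[known]
    }
    zero <- maxima <= 0
    if (any(zero)) {
      warning("species with all-zero measurements excluded from the cost (",
              cond, "): ", paste(species[zero], collapse = ", "))
      w[zero] <- 0
      maxima[zero] <- 1  # never used: weight 0
    }
    y0 <- means[1, , drop = TRUE]
    names(y0) <- species
    prep[[cond]] <- list(condition = cond, times = times, species = species,
                         means = means, maxima = maxima, weights = w,
                         y0 = y0, replicates = replicates, raw = sub)
  }
  prep
}

# Scaled squared error of one condition's simulated trajectory against its
# prepared data; traj must contain the data times.
condition_cost <- function(pc, traj, per_species = FALSE) {
  rows <- match(pc$times, traj$time)
  out <- stats::setNames(numeric(length(pc$species)), pc$species)
  for (s in pc$species) {
    if (pc$weights[[s]] == 0 && !per_species) next
    ypred <- traj$state[rows, s]
    if (pc$replicates == "mean") {
      sse <- sum((pc$means[, s] - ypred)^2)
    } else {
      sub <- pc$raw[pc$raw$species == s, , drop = FALSE]
      sse <- sum((sub$value - ypred[match(sub$time_min, pc$times)])^2)
    }
    out[s] <- sse / pc$maxima[[s]]
  }
  if (per_species) out else sum(out * pc$weights[pc$species])
}

#' Scaled fit-error cost
#'
#' The cost minimized during parameter estimation: for every measured species
#' and condition, the sum over time of squared deviations between the
#' replicate-mean measurement and the simulated value, scaled by the species'
#' maximum measured level (so abundant and scarce metabolites contribute
#' comparably), summed over species and conditions. Species weights allow
#' exclusion (weight 0) of a metabolite, as used by leave-one-out
#' cross-validation. Species whose measurements are identically zero are
#' excluded with a warning (their scale is undefined).
#'
#' @param params Named parameter vector covering the full registry
#'   (including the initial enzyme levels `x0*`).
#' @param datasets Tidy measurement data frame (columns `condition`,
#'   `time_min`, `species`, `replicate`, `value`), one or more conditions.
#' @param network A `cyber_network`.
#' @param profiles Named list of [input_profiles()], one per condition in
#'   `datasets`.
#' @param weights Optional named per-species weights (default 1 each).
#' @param replicates `"mean"` (default) fits the replicate means; `"all"`
#'   sums squared deviations over individual replicates.
#' @return Nonnegative scalar cost.
#' @export
scaled_fit_error <- function(params, datasets, network, profiles,
                             weights = NULL,
                             replicates = c("mean", "all")) {
  prep <- prep_fit_data(datasets, network, weights, replicates)
  tot <- 0
  for (pc in prep) {
    traj <- simulate_model(network, params, profiles[[pc$condition]],
                           times = pc$times,
                           y0 = initial_state(network, params, pc$y0))
    tot <- tot + condition_cost(pc, traj)
  }
  tot
}

#' Scaled fit-error with intermediate-concentration penalty
#'
#' Adds to [scaled_fit_error()] a smooth quadratic hinge penalty keeping the
#' unmeasured intermediates (PGH2/PGH3, or PD) below their assumed bound:
#' `penalty_weight * sum_i max(0, max_t [I_i](t) - bound)^2`, with the
#' trajectory maximum taken over a dense internal grid. A smooth penalty
#' (rather than hard rejection) keeps the surface usable by the local
#' refinement stage.
#'
#' @inheritParams scaled_fit_error
#' @param penalty_weight Penalty weight (default 1000).
#' @param bound Intermediate bound in pmol/ug DNA (default 10).
#' @param dense_step Internal grid step in minutes for the trajectory maxima
#'   (default 0.1).
#' @param prep Precomputed data summary (internal use by [fit_model()]).
#' @return List with elements `cost`, `penalty`, `total`, and
#'   `intermediate_max` (named maxima of the unmeasured intermediates).
#' @export
penalized_cost <- function(params, datasets, network, profiles,
                           weights = NULL, penalty_weight = 1000, bound = 10,
                           replicates = c("mean", "all"), dense_step = 0.1,
                           prep = NULL) {
  if (is.null(prep)) prep <- prep_fit_data(datasets, network, weights,
                                           replicates)
  inter <- setdiff(network$metabolites, unique(unlist(lapply(prep, `[[`,
                                                             "species"))))
  cost <- 0
  imax <- stats::setNames(rep(0, length(inter)), inter)
  for (pc in prep) {
    tmax <- max(pc$times)
    times <- sort(unique(c(pc$times, seq(0, tmax, by = dense_step))))
    traj <- simulate_model(network, params, profiles[[pc$condition]],
                           times = times,
                           y0 = initial_state(network, params, pc$y0))
    cost <- cost + condition_cost(pc, traj)
    for (s in inter) imax[s] <- max(imax[s], max(traj$state[, s]))
  }
  pen <- penalty_weight * sum(pmax(0, imax - bound)^2)
  list(cost = cost, penalty = pen, total = cost + pen,
       intermediate_max = imax)
}
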