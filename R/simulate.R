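#' Default initial state
#'
#' Metabolites start at 0 (the pre-stimulus baseline) unless overridden;
#' enzymes start at their estimated initial levels `x0*` from `params`. When
#' fitting, the measured metabolites are initialized at their time-zero
#' replicate means via `metabolite_init`.
#'
#' @param network A `cyber_network`.
#' @param params Named parameter vector (supplies `x0eCOX`, `x0ePtgds`, ...).
#' @param metabolite_init Optional named numeric vector of initial metabolite
#'   concentrations (unnamed metabolites default to 0).
#' @return Named numeric state vector over `network$state_names`.
#' @export
initial_state <- function(network, params, metabolite_init = NULL) {
  y0 <- stats::setNames(numeric(length(network$state_names)),
                        network$state_names)
  if (!is.null(metabolite_init)) {
    bad <- setdiff(names(metabolite_init), network$metabolites)
    if (length(bad)) stop("unknown metabolites in initial state: ",
                          paste(bad, collapse = ", "))
    y0[names(metabolite_init)] <- metabolite_init
  }
  for (e in names(network$enzyme_specs)) {
    y0[e] <- getp(params, paste0("x0", e))
  }
  y0
}

#' Integrate the model over the experimental time window
#'
#' Solves the coupled metabolite/enzyme ODE system with `deSolve`'s `lsoda`
#' (stiff-capable, automatic method switching) at relative tolerance `1e-6`
#' and absolute tolerance `1e-9`, driven by the interpolated input profiles.
#'
#' @param network A `cyber_network`.
#' @param params Named numeric parameter vector covering the full registry.
#' @param profiles An [input_profiles()] object for the condition simulated.
#' @param times Output grid in minutes (default: the measurement times
#'   0, 2.5, 5, 10, 15, 30, 60).
#' @param y0 Initial state (default: [initial_state()]).
#' @param cybernetic If `FALSE`, integrate the unregulated reduction
#'   (`u = 1/n`, `v = 1`).
#' @param rtol,atol Solver tolerances.
#' @param engine `"compiled"` (default) integrates the C right-hand side;
#'   `"R"` integrates [assemble_rhs()] directly (reference engine, identical
#'   mathematics, used for cross-checking).
#' @return Object of class `trajectory`: list with `time`, `state` (matrix,
#'   time x species), and `condition`.
#' @export
simulate_model <- function(network, params, profiles,
                           times = default_times(), y0 = NULL,
                           cybernetic = TRUE, rtol = 1e-6, atol = 1e-9,
                           engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (is.null(y0)) y0 <- initial_state(network, params)
  y0 <- y0[network$state_names]
  sol <- if (engine == "compiled") {
    deSolve::ode(y = y0, times = times, func = "cyberlipid_derivs",
                 parms = pack_parms(network, params, profiles, cybernetic),
                 dllname = "cyberlipid", initfunc = "cyberlipid_init",
                 method = "lsoda", rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times,
                 func = make_rhs(network, params, profiles, cybernetic),
                 parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else times[1]
    stop("integration failed at t = ", t_fail, " min")
  }
  state <- unclass(sol)[, -1, drop = FALSE]
  rownames(state) <- NULL
  structure(list(time = times, state = state,
                 condition = profiles$condition),
            class = "trajectory")
}

#' Measurement time grid
#'
#' The sampling times of the experimental design: 0, 2.5, 5, 10, 15, 30 and
#' 60 minutes post ATP stimulation.
#' @return Numeric vector of times in minutes.
#' @export
default_times <- function() c(0, 2.5, 5, 10, 15, 30, 60)

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory [", x$condition, "]: ", ncol(x$state), " states at ",
      length(x$time), " times (", x$time[1], "..", x$time[length(x$time)],
      " min)\n", sep = "")
  invisible(x)
}

#' Convert a trajectory to a tidy data frame
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `condition`, `time_min`, `species`,
#'   `value`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(condition = x$condition,
             time_min = rep(x$time, times = ncol(x$state)),
             species = rep(colnames(x$state), each = length(x$time)),
             value = as.vector(x$state),
             stringsAsFactors = FALSE)
}

#' Check the bound on unmeasured intermediates
#'
#' The endoperoxide intermediates (PGH2 and PGH3, or PD) are too unstable to
#' measure; their simulated concentrations are assumed to stay below a bound
#' (10 pmol/ug DNA by default).
#'
#' @param traj A `trajectory` (use a dense grid for a tight maximum).
#' @param bound Concentration bound in pmol/ug DNA.
#' @param species Which species to check (default: the unmeasured
#'   metabolites present in the trajectory).
#' @return Data frame with columns `species`, `max`, `pass`.
#' @export
check_intermediate_bound <- function(traj, bound = 10, species = NULL) {
  if (is.null(species)) {
    species <- intersect(c("PGH2", "PGH3", "PD"), colnames(traj$state))
  }
  mx <- vapply(species, function(s) max(traj$state[, s]), numeric(1))
  data.frame(species = species, max = unname(mx),
             pass = unname(mx) <= bound, stringsAsFactors = FALSE)
}
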