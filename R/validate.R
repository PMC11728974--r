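#' Lack-of-fit F statistic for one metabolite
#'
#' Ratio of the model lack-of-fit mean square to the replicate (pure-error)
#' mean square, pooled over the experimental conditions:
#' numerator `sum_cond sum_t (Y - Xbar)^2 / (ne*nt)` with `Y` the fitted and
#' `Xbar` the replicate-mean value, denominator
#' `sum_cond sum_t sum_r (X - Xbar)^2 / (ne*nt*(nr-1))`. A small F means the
#' fit error is below the experimental scatter.
#'
#' @param fitted Named list, one numeric vector per condition with the fitted
#'   values at that condition's sorted measurement times.
#' @param data Tidy data frame for one species (columns `condition`,
#'   `time_min`, `replicate`, `value`) covering the same conditions.
#' @return The F value (nonnegative scalar) with attributes `df1` and `df2`.
#' @export
f_statistic <- function(fitted, data) {
  conds <- names(fitted)
  if (length(conds) < 1L) stop("no conditions supplied")
  ne <- length(conds)
  num <- 0
  den <- 0
  nt <- NULL
  nr <- NULL
  for (cond in conds) {
    sub <- data[data$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no data for condition ", cond)
    times <- sort(unique(sub$time_min))
    if (is.null(nt)) nt <- length(times)
    if (length(times) != nt) stop("unequal time grids across conditions")
    reps <- table(sub$time_min)
    if (length(unique(as.integer(reps))) != 1L) {
      stop("replicate count is not uniform across time points")
    }
    nr_c <- as.integer(reps[1])
    if (is.null(nr)) nr <- nr_c
    if (nr_c != nr) stop("unequal replicate counts across conditions")
    xbar <- tapply(sub$value, sub$time_min, mean)[as.character(times)]
    y <- fitted[[cond]]
    if (length(y) != nt) stop("fitted values do not match the time grid")
    num <- num + sum((y - xbar)^2)
    den <- den + sum((sub$value - xbar[as.character(sub$time_min)])^2)
  }
  if (nr < 2L) stop("at least 2 replicates are required (zero pure-error df)")
  df1 <- ne * nt
  df2 <- ne * nt * (nr - 1L)
  f <- (num / df1) / (den / df2)
  attr(f, "df1") <- df1
  attr(f, "df2") <- df2
  f
}

#' Lower-tail critical value of the F distribution
#'
#' The fit passes the lack-of-fit test when its F value is below the
#' lower-tail `alpha` quantile (the fit error is then significantly smaller
#' than the replicate error).
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return The quantile `qf(alpha, df1, df2)`; e.g.
#'   `f_critical(0.05, 16, 32)` is 0.46 to two decimals.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  stats::qf(alpha, df1, df2)
}

#' Lack-of-fit F-test report over all measured metabolites
#'
#' Computes the per-metabolite F statistic of a fit against the replicate
#' data and compares each against the lower-tail critical value with
#' `df1 = ne*nt`, `df2 = ne*nt*(nr-1)` computed from the data at hand.
#'
#' @param fit A `fit_result` (its `trajectories` supply the fitted values).
#' @param datasets The tidy measurement data the fit used.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `validation_report`: data frame with columns
#'   `species`, `F`, `df1`, `df2`, `critical`, `pass`; attributes `alpha`,
#'   `ne`, `nt`, `nr`.
#' @export
f_test_report <- function(fit, datasets, alpha = 0.05) {
  check_timeseries(datasets)
  conds <- unique(datasets$condition)
  traj <- fit$trajectories
  rows <- list()
  for (s in sort(unique(datasets$species))) {
    sub <- datasets[datasets$species == s, , drop = FALSE]
    if (!all(conds %in% unique(sub$condition))) {
      warning("metabolite ", s, " missing in some condition; skipped")
      next
    }
    fitted <- lapply(stats::setNames(conds, conds), function(cond) {
      tc <- traj[traj$condition == cond & traj$species == s, , drop = FALSE]
      tc$value[order(tc$time_min)]
    })
    f <- f_statistic(fitted, sub)
    rows[[s]] <- data.frame(species = s, F = as.numeric(f),
                            df1 = attr(f, "df1"), df2 = attr(f, "df2"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$critical <- f_critical(alpha, out$df1, out$df2)
  out$pass <- out$F < out$critical
  attr(out, "alpha") <- alpha
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Leave-one-out-metabolite cross-validation
#'
#' Refits the model with one measured metabolite's weight in the cost set to
#' zero (the metabolite stays in the reaction kinetics and flux balances) and
#' scores the scaled error of its predicted trajectory against its held-out
#' measurements.
#'
#' @param datasets Tidy measurement data frame.
#' @param network A `cyber_network`.
#' @param profiles Named list of [input_profiles()] per condition.
#' @param metabolite The measured metabolite to hold out (e.g. `"PGD2"`).
#' @param config A [fit_config()].
#' @param seed Integer seed for the refit.
#' @return List with the refit (`fit`), `heldout_error` (scaled error of the
#'   held-out prediction, summed over conditions), and `fitted_errors`
#'   (per-species scaled errors of the species that were fitted).
#' @export
loo_metabolite_cv <- function(datasets, network, profiles, metabolite,
                              config = fit_config(), seed = 1) {
  if (!(metabolite %in% unique(datasets$species)) ||
      !(metabolite %in% network$metabolites)) {
    stop("unknown or unmeasured metabolite: ", metabolite)
  }
  w <- config$weights
  if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
  w[metabolite] <- 0
  config$weights <- w
  fit <- fit_model(datasets, network, profiles, config = config, seed = seed)
  prep <- prep_fit_data(datasets, network, NULL, config$replicates)
  errs <- stats::setNames(numeric(0), character(0))
  for (pc in prep) {
    tc <- fit$trajectories[fit$trajectories$condition == pc$condition, ,
                           drop = FALSE]
    traj <- list(time = pc$times,
                 state = vapply(pc$species, function(s) {
                   v <- tc[tc$species == s, , drop = FALSE]
                   v$value[order(v$time_min)]
                 }, numeric(length(pc$times))))
    e <- condition_cost(pc, traj, per_species = TRUE)
    for (nm in names(e)) {
      errs[nm] <- (if (nm %in% names(errs)) errs[[nm]] else 0) + e[[nm]]
    }
  }
  list(fit = fit, heldout_error = unname(errs[[metabolite]]),
       fitted_errors = errs[setdiff(names(errs), metabolite)],
       metabolite = metabolite)
}

#' Activity-control switch surface
#'
#' Evaluates the simplified activity-control variables on an AA x EPA grid
#' and records the substrate ratio at which dominance switches between the
#' proinflammatory and antiinflammatory branches.
#'
#' @param AA,EPA Nonnegative concentration grids.
#' @param kPGH2,kPGH3 Positive rate constants.
#' @return Object of class `switch_analysis`: list with the grids, matrices
#'   `vPGH2` and `vPGH3` (rows index AA, columns EPA, values in `[0, 1]`),
#'   and `ratio` (`[AA]switch/[EPA]switch = kPGH3/kPGH2`).
#' @export
switch_surface <- function(AA, EPA, kPGH2, kPGH3) {
  if (length(AA) == 0L || length(EPA) == 0L) stop("empty concentration grid")
  if (any(AA < 0) || any(EPA < 0)) stop("grids must be nonnegative")
  if (kPGH2 <= 0 || kPGH3 <= 0) stop("rate constants must be positive")
  v2 <- matrix(NA_real_, length(AA), length(EPA))
  v3 <- v2
  for (i in seq_along(AA)) {
    for (j in seq_along(EPA)) {
      v <- simplified_v(AA[i], EPA[j], kPGH2, kPGH3)
      v2[i, j] <- v[["vPGH2"]]
      v3[i, j] <- v[["vPGH3"]]
    }
  }
  structure(list(AA = AA, EPA = EPA, vPGH2 = v2, vPGH3 = v3,
                 ratio = switch_ratio(kPGH2, kPGH3)),
            class = "switch_analysis")
}

#' @export
print.switch_analysis <- function(x, ...) {
  cat("Activity-control switch surface: ", length(x$AA), " x ",
      length(x$EPA), " grid; [AA]switch/[EPA]switch = ",
      format(x$ratio, digits = 4), "\n", sep = "")
  invisible(x)
}
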