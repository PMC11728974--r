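#' Measured input profiles for one experimental condition
#'
#' The fatty-acid substrates (AA and EPA or DHA) and the ATP stimulus are
#' inputs to the model, not states: their measured time courses drive the ODE
#' system. Profiles are interpolated piecewise-linearly between the tabulated
#' times (linear rather than cubic so interpolation can never overshoot into
#' negative concentrations) and extrapolated as constants beyond the last
#' point. The ATP stimulus is summarized by its initial level `ATP0`; its
#' decay rate is a model parameter (`dATP`).
#'
#' @param condition Condition label, e.g. `"ctrl"`, `"EPA"`, `"DHA"`.
#' @param time Strictly increasing numeric grid in minutes, starting at 0.
#' @param values Named list of numeric vectors (one per input substrate,
#'   e.g. `AA` and `EPA`), each the same length as `time`, all values >= 0.
#' @param ATP0 Initial ATP level (> 0 under stimulation).
#' @param mode Interpolation mode; only `"linear"` is provided.
#' @return Object of class `input_profiles`.
#' @export
input_profiles <- function(condition, time, values, ATP0, mode = "linear") {
  if (length(time) < 1L) stop("empty input profile")
  if (time[1] != 0 || is.unsorted(time, strictly = TRUE)) {
    stop("time grid must be strictly increasing and start at 0")
  }
  mode <- match.arg(mode, "linear")
  for (nm in names(values)) {
    v <- values[[nm]]
    if (length(v) != length(time)) {
      stop("profile for ", nm, " does not match the time grid")
    }
    if (any(v < 0)) stop("negative values in profile for ", nm)
  }
  if (ATP0 < 0) stop("ATP0 must be nonnegative")
  structure(list(condition = condition, time = time, values = values,
                 ATP0 = ATP0, mode = mode),
            class = "input_profiles")
}

#' @export
print.input_profiles <- function(x, ...) {
  cat("Input profiles [", x$condition, "]: ",
      paste(names(x$values), collapse = ", "),
      " on t = ", x$time[1], "..", x$time[length(x$time)], " min, ATP0 = ",
      x$ATP0, "\n", sep = "")
  invisible(x)
}

# One approxfun per substrate (constant extrapolation at both ends).
input_interpolators <- function(profiles) {
  lapply(profiles$values, function(v) {
    if (length(profiles$time) == 1L) {
      local({ v0 <- v[1]; function(t) rep(v0, length(t)) })
    } else {
      stats::approxfun(profiles$time, v, method = "linear", rule = 2)
    }
  })
}

#' Interpolate input-substrate concentrations at a time point
#'
#' Piecewise-linear interpolation on the profile grid with constant
#' extrapolation beyond the last tabulated time; results are clipped at 0.
#'
#' @param profiles An [input_profiles()] object.
#' @param t Time (minutes), `t >= 0`; may be a vector.
#' @return For scalar `t`, a named numeric vector of substrate
#'   concentrations; for vector `t`, a matrix (time in rows).
#' @export
interpolate_inputs <- function(profiles, t) {
  if (!inherits(profiles, "input_profiles")) stop("not an input_profiles object")
  if (any(t < 0)) stop("t must be nonnegative")
  fs <- input_interpolators(profiles)
  out <- vapply(fs, function(f) pmax(0, f(t)), numeric(length(t)))
  if (length(t) == 1L) {
    stats::setNames(as.numeric(out), names(fs))
  } else {
    out
  }
}
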