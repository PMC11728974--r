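# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Stage-1 mesh pattern search
#'
#' Bounded derivative-free direct search: coordinates are scaled to the unit
#' box, the current point is polled along each coordinate direction at the
#' current mesh step (in seeded random order, opportunistically accepting the
#' first improvement), and the mesh is contracted by half after an
#' unsuccessful full poll. Deterministic given `seed` and `start`.
#'
#' @param fn Cost function over the parameter vector (must be finite at
#'   `start`).
#' @param lower,upper Finite bound vectors.
#' @param start Start vector within the bounds.
#' @param seed Integer seed for the poll ordering.
#' @param budget Maximum number of cost evaluations (0 returns `start`).
#' @param step Initial mesh step as a fraction of each box width.
#' @param min_step Mesh step below which the search stops.
#' @return List with `par`, `value`, `evals`.
#' @export
direct_search <- function(fn, lower, upper, start, seed = 1, budget = 2000,
                          step = 0.25, min_step = 1e-6) {
  n <- length(start)
  stopifnot(length(lower) == n, length(upper) == n,
            all(is.finite(lower)), all(is.finite(upper)),
            all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  width <- upper - lower
  width[width == 0] <- 1
  x <- pmin(pmax(start, lower), upper)
  f0 <- fn(x)
  if (!is.finite(f0)) stop("cost is non-finite at the start point")
  if (budget <= 0) return(list(par = x, value = f0, evals = 1L))

  evals <- 1L
  fbest <- f0
  with_local_seed(seed, {
    while (evals < budget && step >= min_step) {
      improved <- FALSE
      dirs <- sample(rep(seq_len(n), each = 2))
      sgn <- integer(n)
      for (j in dirs) {
        sgn[j] <- sgn[j] + 1L
        s <- if (sgn[j] == 1L) 1 else -1
        cand <- x
        cand[j] <- min(upper[j], max(lower[j], x[j] + s * step * width[j]))
        if (cand[j] == x[j]) next
        fc <- fn(cand)
        evals <- evals + 1L
        if (is.finite(fc) && fc < fbest) {
          x <- cand
          fbest <- fc
          improved <- TRUE
          break
        }
        if (evals >= budget) break
      }
      if (!improved) step <- step / 2
    }
  })
  list(par = x, value = fbest, evals = evals)
}

#' Stage-2 bounded local refinement
#'
#' Numerical-gradient quasi-Newton refinement (`L-BFGS-B`) within the bounds,
#' started from the stage-1 solution. The returned cost never exceeds the
#' starting cost (the start is kept if the line search cannot improve it).
#'
#' @param fn Cost function (finite at `start`).
#' @param start Start vector within the bounds.
#' @param lower,upper Bound vectors.
#' @param maxit Maximum number of quasi-Newton iterations.
#' @param tol Relative convergence tolerance on the cost.
#' @return List with `par`, `value`, `convergence`, `evals`.
#' @export
local_refine <- function(fn, start, lower, upper, maxit = 100, tol = 1e-8) {
  f0 <- fn(start)
  if (!is.finite(f0)) stop("cost is non-finite at the start point")
  safe_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  res <- tryCatch(
    stats::optim(start, safe_fn, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = maxit,
                                factr = tol / .Machine$double.eps)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value > f0) {
    return(list(par = start, value = f0, convergence = 1L, evals = 1L))
  }
  list(par = res$par, value = res$value, convergence = res$convergence,
       evals = unname(res$counts[1]))
}
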