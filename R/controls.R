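#' Fluxes of the controlled conversions
#'
#' The cybernetic goal is to maximize the combined consumption rate of the two
#' competing fatty-acid substrates, i.e. the combined production flux of their
#' COX products. The flux of each controlled conversion is bilinear in enzyme
#' and substrate: `rho_i = k_i * [eCOX] * [S_i]` (the ATP modulation factor is
#' common to both conversions and cancels from the control ratios, so it is
#' not part of the flux used to compute them).
#'
#' @param state Named numeric state vector (must contain `eCOX`).
#' @param params Named numeric parameter vector.
#' @param substrates Named numeric vector of input-substrate concentrations at
#'   the evaluation time (must contain `AA` and `EPA` or `DHA`).
#' @param network A `cyber_network`.
#' @return Named numeric vector of fluxes, one per controlled reaction, named
#'   by product (`PGH2` and `PGH3`, or `PGH2` and `PD`), in pmol/ug DNA per
#'   minute.
#' @export
compute_fluxes <- function(state, params, substrates, network) {
  ctrl <- network$controlled
  ecox <- state[["eCOX"]]
  s <- substrates[ctrl$substrate]
  if (any(s < 0) || ecox < 0) {
    stop("negative concentration in flux computation")
  }
  k <- vapply(ctrl$rate, function(nm) getp(params, nm), numeric(1))
  rho <- unname(k) * ecox * unname(s)
  names(rho) <- ctrl$product
  rho
}

#' Cybernetic control variables from fluxes
#'
#' Applies the matching and proportion laws: the activity variable
#' `v_i = rho_i / max_j rho_j` and the synthesis-allocation variable
#' `u_i = rho_i / sum_j rho_j`. When every flux is zero (e.g. before any
#' enzyme or substrate is present) the degenerate convention `u_i = 1/n`,
#' `v_i = 1` is returned, so the model reduces to unregulated mass action.
#'
#' @param fluxes Nonnegative numeric vector of fluxes (named by product).
#' @return List with numeric vectors `u` and `v` (same names as `fluxes`);
#'   `sum(u) == 1` and `max(v) == 1` always hold.
#' @examples
#' cybernetic_controls(c(PGH2 = 2, PGH3 = 6))  # u = (0.25, 0.75), v = (1/3, 1)
#' @export
cybernetic_controls <- function(fluxes) {
  if (any(fluxes < 0)) stop("fluxes must be nonnegative")
  tot <- sum(fluxes)
  if (tot <= 0) {
    n <- length(fluxes)
    u <- rep(1 / n, n)
    v <- rep(1, n)
  } else {
    u <- fluxes / tot
    v <- fluxes / max(fluxes)
  }
  names(u) <- names(v) <- names(fluxes)
  list(u = u, v = v)
}

#' Simplified activity-control variables
#'
#' Because both controlled conversions share the same COX pool, the enzyme
#' level cancels from the activity-control ratio, which therefore depends only
#' on the substrate concentrations and rate constants:
#' `vPGH2_simp = kPGH2*[AA] / max(kPGH2*[AA], kPGH3*[EPA])` and analogously
#' for the 3-series branch. Identical to the `v` component of
#' [cybernetic_controls()] for any positive COX level.
#'
#' @param AA,EPA Nonnegative substrate concentrations (for the DHA variant
#'   pass the DHA concentration as `EPA` and `kPD` as `kPGH3`).
#' @param kPGH2,kPGH3 Nonnegative rate constants.
#' @return Numeric vector `c(vPGH2 = ..., vPGH3 = ...)` in `[0, 1]`; `(1, 1)`
#'   in the degenerate all-zero case.
#' @export
simplified_v <- function(AA, EPA, kPGH2, kPGH3) {
  if (AA < 0 || EPA < 0 || kPGH2 < 0 || kPGH3 < 0) {
    stop("simplified_v requires nonnegative inputs")
  }
  p <- c(vPGH2 = kPGH2 * AA, vPGH3 = kPGH3 * EPA)
  m <- max(p)
  if (m <= 0) return(c(vPGH2 = 1, vPGH3 = 1))
  p / m
}

#' Substrate ratio at the activity switch
#'
#' The AA:EPA concentration ratio at which the activity-control dominance
#' transfers between the proinflammatory (2-series) and antiinflammatory
#' (3-series) branches, i.e. at which both simplified activity variables
#' equal 1: `[AA]switch / [EPA]switch = kPGH3 / kPGH2`.
#'
#' @param kPGH2 Positive rate constant of the AA -> PGH2 conversion.
#' @param kPGH3 Nonnegative rate constant of the competing conversion.
#' @return The ratio `kPGH3 / kPGH2`.
#' @export
switch_ratio <- function(kPGH2, kPGH3) {
  if (!is.finite(kPGH2) || kPGH2 <= 0) stop("kPGH2 must be positive")
  if (kPGH3 < 0) stop("kPGH3 must be nonnegative")
  kPGH3 / kPGH2
}
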