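#' Metabolite balance derivatives
#'
#' Evaluates the production-minus-degradation-minus-downstream balance for
#' every metabolite state. The two COX conversions carry the activity-control
#' variable `v` and the ATP modulation factor `(1 + kATP*[ATP])` (basal plus
#' stimulus-induced COX activity); downstream enzymatic conversions are
#' bilinear in substrate and enzyme without control variables; the PGD2
#' dehydrations to PGJ2 and 15-deoxy-PGD2 are first-order non-enzymatic; and
#' every metabolite degrades first-order with its own rate `g*`.
#'
#' @param state Named numeric vector over `network$state_names`.
#' @param params Named numeric parameter vector.
#' @param substrates Named numeric vector with the input concentrations
#'   (`AA`, `EPA` or `DHA`, `ATP`) at the evaluation time.
#' @param controls List with `u` and `v` as returned by
#'   [cybernetic_controls()], named by controlled product.
#' @param network A `cyber_network`.
#' @return Named numeric vector of derivatives, one per metabolite.
#' @export
metabolite_rhs <- function(state, params, substrates, controls, network) {
  d <- stats::setNames(numeric(length(network$metabolites)),
                       network$metabolites)
  for (i in seq_len(nrow(network$degradations))) {
    m <- network$degradations$species[i]
    d[m] <- d[m] - getp(params, network$degradations$rate[i]) * state[[m]]
  }
  kATP <- getp(params, "kATP")
  rx <- network$reactions
  for (i in seq_len(nrow(rx))) {
    sub_name <- rx$substrate[i]
    sub <- if (sub_name %in% names(state)) state[[sub_name]] else
      substrates[[sub_name]]
    rate <- getp(params, rx$rate[i]) * sub
    if (!is.na(rx$enzyme[i])) rate <- rate * state[[rx$enzyme[i]]]
    if (rx$atp[i]) rate <- rate * (1 + kATP * substrates[["ATP"]])
    if (rx$controlled[i]) rate <- rate * controls$v[[rx$product[i]]]
    d[rx$product[i]] <- d[rx$product[i]] + rate
    if (sub_name %in% names(d)) d[sub_name] <- d[sub_name] - rate
  }
  d
}

#' Enzyme balance derivatives
#'
#' Each enzyme follows constitutive synthesis plus Michaelis-Menten induction
#' by the substrate(s) it acts on, minus first-order degradation:
#' `d[e]/dt = alpha + sum_j f_j * ke_j * S_j / (Km_j + S_j) - beta * [e]`.
#' For the shared COX pool the induction terms are weighted by the cybernetic
#' synthesis-allocation variables `u` (resource allocation between the
#' competing conversions); the downstream enzymes carry a single un-weighted
#' lumped induction term (driver `[PGH2] + [PGH3]` for `ePtgds`/`ePtges`,
#' `[PGD2]` for `edhkPGD2`), and `edhkPGD2` has no constitutive term.
#'
#' @inheritParams metabolite_rhs
#' @return Named numeric vector of derivatives, one per enzyme.
#' @export
enzyme_rhs <- function(state, params, substrates, controls, network) {
  d <- stats::setNames(numeric(length(network$enzymes)), network$enzymes)
  for (es in network$enzyme_specs) {
    dd <- if (is.null(es$alpha)) 0 else getp(params, es$alpha)
    dd <- dd - getp(params, es$beta) * state[[es$enzyme]]
    for (tm in es$terms) {
      S <- sum(vapply(tm$driver, function(id) {
        if (id %in% names(state)) state[[id]] else substrates[[id]]
      }, numeric(1)))
      den <- getp(params, tm$Km) + S
      if (den <= 0) {
        stop("zero Michaelis-Menten denominator for enzyme ", es$enzyme)
      }
      fac <- if (isTRUE(es$u_controlled)) controls$u[[tm$u]] else 1
      dd <- dd + fac * getp(params, tm$k) * S / den
    }
    d[es$enzyme] <- dd
  }
  d
}

#' Full ODE right-hand side
#'
#' Evaluates the complete derivative vector at time `t`: interpolates the
#' input profiles, computes the controlled fluxes and the cybernetic control
#' variables from them, and assembles the metabolite and enzyme balances.
#' The ATP input follows `[ATP](t) = ATP0 * exp(-dATP * t)` with `ATP0` fixed
#' by the condition's profiles and `dATP` a model parameter.
#'
#' @param t Time in minutes.
#' @param state Named numeric vector over `network$state_names`; small
#'   negative excursions from the integrator are clipped to zero for rate
#'   evaluation.
#' @param params Named numeric parameter vector.
#' @param network A `cyber_network`.
#' @param inputs An [input_profiles()] object for the condition.
#' @param cybernetic If `FALSE`, the control variables are frozen at the
#'   neutral values `u = 1/n`, `v = 1` (unregulated mass-action reduction).
#' @return Named numeric derivative vector over `network$state_names`
#'   (length 13 for the EPA variant).
#' @export
assemble_rhs <- function(t, state, params, network, inputs,
                         cybernetic = TRUE) {
  if (any(!is.finite(state))) stop("non-finite state at t = ", t)
  state <- pmax(state, 0)
  if (is.null(names(state))) names(state) <- network$state_names
  subs <- interpolate_inputs(inputs, t)
  subs[["ATP"]] <- inputs$ATP0 * exp(-getp(params, "dATP") * t)
  controls <- if (cybernetic) {
    cybernetic_controls(compute_fluxes(state, params, subs, network))
  } else {
    n <- nrow(network$controlled)
    list(u = stats::setNames(rep(1 / n, n), network$controlled$product),
         v = stats::setNames(rep(1, n), network$controlled$product))
  }
  c(metabolite_rhs(state, params, subs, controls, network),
    enzyme_rhs(state, params, subs, controls, network))
}

# Pack variant id, control switch, kinetic constants and tabulated input
# profiles into the fixed-layout parameter vector consumed by the compiled
# right-hand side (src/rhs.c). Mathematics identical to assemble_rhs(),
# asserted by an engine-consistency test.
pack_parms <- function(network, params, profiles, cybernetic = TRUE) {
  const_names <- if (network$variant == "EPA") {
    c("kPGH2", "kPGH3", "kPGD2", "kPGD3", "kPGE2", "kPGE3", "kdhkPGD2",
      "kPGJ2", "kdPGD2",
      "gPGH2", "gPGH3", "gPGD2", "gPGD3", "gPGE2", "gPGE3", "gPGJ2",
      "gdPGD2", "gdhkPGD2",
      "aCOX", "bCOX", "kePGH2", "KmAA", "kePGH3", "KmEPA",
      "aPtgds", "bPtgds", "kePtgds", "KmPtgds",
      "aPtges", "bPtges", "kePtges", "KmPtges",
      "bdhk", "kedhk", "Kmdhk")
  } else {
    c("kPGH2", "kPD", "kPGD2", "kPGE2", "kdhkPGD2", "kPGJ2", "kdPGD2",
      "gPGH2", "gPD", "gPGD2", "gPGE2", "gPGJ2", "gdPGD2", "gdhkPGD2",
      "aCOX", "bCOX", "kePGH2", "KmAA", "kePD", "KmDHA",
      "aPtgds", "bPtgds", "kePtgds", "KmPtgds",
      "aPtges", "bPtges", "kePtges", "KmPtges",
      "bdhk", "kedhk", "Kmdhk")
  }
  konst <- vapply(const_names, function(nm) getp(params, nm), numeric(1))
  konst <- c(unname(konst), numeric(35 - length(konst)))
  omega3 <- setdiff(network$inputs, c("AA", "ATP"))
  tg <- profiles$time
  ng <- length(tg)
  if (41 + 3 * ng > 512) stop("input profile grid too long for the solver")
  aa <- profiles$values[["AA"]]
  o3 <- profiles$values[[omega3]]
  if (is.null(aa) || is.null(o3)) {
    stop("profiles must tabulate AA and ", omega3)
  }
  p <- c(if (network$variant == "EPA") 1 else 2,
         as.numeric(cybernetic),
         getp(params, "kATP"), getp(params, "dATP"), profiles$ATP0,
         konst, ng, tg, aa, o3)
  c(p, numeric(512 - length(p)))
}

# R-level right-hand side closure over assemble_rhs() (reference engine).
make_rhs <- function(network, params, profiles, cybernetic = TRUE) {
  reg <- param_registry(network)$name
  for (nm in reg) getp(params, nm)  # fail fast, naming any missing parameter
  function(t, y, parms) {
    names(y) <- network$state_names
    list(unname(assemble_rhs(t, y, params, network, profiles,
                             cybernetic = cybernetic)))
  }
}
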