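neutral <- function(net) {
  n <- nrow(net$controlled)
  list(u = stats::setNames(rep(1 / n, n), net$controlled$product),
       v = stats::setNames(rep(1, n), net$controlled$product))
}

test_that("metabolite balances reduce to their analytic limits", {
  net <- build_network("EPA")
  zero_state <- stats::setNames(numeric(13), net$state_names)
  subs <- c(AA = 0, EPA = 0, ATP = 0)
  p <- make_params(net)
  expect_equal(max(abs(metabolite_rhs(zero_state, p, subs, neutral(net),
                                      net))), 0)

  # production-only limit of the PGH2 balance
  p2 <- make_params(net, kPGH2 = 0.7, gPGH2 = 0, kPGD2 = 0, kPGE2 = 0,
                    kATP = 0)
  st <- zero_state; st["eCOX"] <- 1.3
  d <- metabolite_rhs(st, p2, c(AA = 2, EPA = 0, ATP = 5), neutral(net), net)
  expect_equal(d[["PGH2"]], 0.7 * 2 * 1.3)

  # full hand evaluation of the PGH2 balance with v = 0.5
  p3 <- make_params(net, kPGH2 = 1, kATP = 1, gPGH2 = 0.1, kPGD2 = 0,
                    kPGE2 = 0)
  st3 <- zero_state; st3["eCOX"] <- 1; st3["PGH2"] <- 10
  ctl <- neutral(net); ctl$v["PGH2"] <- 0.5
  d3 <- metabolite_rhs(st3, p3, c(AA = 2, EPA = 0, ATP = 1), ctl, net)
  expect_equal(d3[["PGH2"]], 0.5 * 1 * 2 * 1 * 2 - 0.1 * 10)

  expect_error(metabolite_rhs(st3, p3[-1], c(AA = 2, EPA = 0, ATP = 1),
                              ctl, net),
               "missing parameter: kPGH2")
})

test_that("downstream flux out of PGH2 equals its conversion terms", {
  net <- build_network("EPA")
  p <- make_params(net, kPGD2 = 0.21, kPGE2 = 0.13, gPGH2 = 0.4,
                   kPGH2 = 0.05, kATP = 0.1)
  st <- stats::setNames(runif(13, 0.1, 3), net$state_names)
  subs <- c(AA = 8, EPA = 3, ATP = 2)
  ctl <- cybernetic_controls(compute_fluxes(st, p, subs, net))
  d <- metabolite_rhs(st, p, subs, ctl, net)
  production <- ctl$v[["PGH2"]] * 0.05 * 8 * st[["eCOX"]] * (1 + 0.1 * 2)
  downstream <- 0.21 * st[["PGH2"]] * st[["ePtgds"]] +
    0.13 * st[["PGH2"]] * st[["ePtges"]]
  expect_equal(d[["PGH2"]],
               production - 0.4 * st[["PGH2"]] - downstream)
})

test_that("enzyme balances follow constitutive + induction - degradation", {
  net <- build_network("EPA")
  zero_state <- stats::setNames(numeric(13), net$state_names)
  subs0 <- c(AA = 0, EPA = 0, ATP = 0)
  p <- make_params(net, aCOX = 0.2, aPtgds = 0.2, aPtges = 0.2)
  d <- enzyme_rhs(zero_state, p, subs0, neutral(net), net)
  expect_equal(d[["eCOX"]], 0.2)
  expect_equal(d[["ePtgds"]], 0.2)
  expect_equal(d[["ePtges"]], 0.2)
  expect_equal(d[["edhkPGD2"]], 0)  # no constitutive synthesis

  # Michaelis-Menten saturation of the induction term
  p2 <- make_params(net, aCOX = 0, bCOX = 0, kePGH2 = 2, KmAA = 1,
                    kePGH3 = 0)
  ctl <- neutral(net); ctl$u[] <- c(1, 0)
  d2 <- enzyme_rhs(zero_state, p2, c(AA = 1e9, EPA = 0, ATP = 0), ctl, net)
  expect_equal(d2[["eCOX"]], 2, tolerance = 1e-8)

  # hand evaluation with u = 0.5 and degradation
  p3 <- make_params(net, aCOX = 0, bCOX = 0.1, kePGH2 = 2, KmAA = 1,
                    kePGH3 = 0)
  st3 <- zero_state; st3["eCOX"] <- 10
  ctl3 <- neutral(net)  # uPGH2 = 0.5
  d3 <- enzyme_rhs(st3, p3, c(AA = 1, EPA = 0, ATP = 0), ctl3, net)
  expect_equal(d3[["eCOX"]], 0.5 * 2 * 0.5 - 0.1 * 10)

  # 0/0 guard
  p4 <- make_params(net, KmAA = 0)
  expect_error(enzyme_rhs(zero_state, p4, subs0, neutral(net), net),
               "Michaelis-Menten denominator")
})

test_that("assembled right-hand side composes fluxes, controls and balances", {
  net <- build_network("EPA")
  p <- make_params(net, aCOX = 0.11, aPtgds = 0.12, aPtges = 0.13)
  prof <- flat_profiles()
  d <- assemble_rhs(0, stats::setNames(numeric(13), net$state_names), p, net,
                    prof)
  expect_length(d, 13L)
  expect_equal(unname(d[net$metabolites]), numeric(9))
  expect_equal(d[["eCOX"]], 0.11)
  expect_equal(d[["edhkPGD2"]], 0)
  expect_error(assemble_rhs(0, c(NaN, numeric(12)), p, net, prof),
               "non-finite state")
})

test_that("derivative matches a finite-difference of the trajectory", {
  w <- get_world()
  h <- 1e-3
  for (t0 in c(3, 20)) {
    tr <- simulate_model(w$net, w$truth, w$profiles$EPA,
                         times = c(0, t0, t0 + h), rtol = 1e-10,
                         atol = 1e-12)
    x <- stats::setNames(tr$state[2, ], w$net$state_names)
    fd <- (tr$state[3, ] - tr$state[2, ]) / h
    d <- assemble_rhs(t0, x, w$truth, w$net, w$profiles$EPA)
    expect_equal(unname(d), unname(fd), tolerance = 1e-2)
  }
})

test_that("compiled and reference ODE engines agree", {
  w <- get_world()
  times <- seq(0, 30, by = 3)
  for (cond in c("ctrl", "EPA")) {
    trC <- simulate_model(w$net, w$truth, w$profiles[[cond]], times = times)
    trR <- simulate_model(w$net, w$truth, w$profiles[[cond]], times = times,
                          engine = "R")
    expect_equal(trC$state, trR$state, tolerance = 1e-6)
  }
  # and for the DHA variant
  netD <- build_network("DHA")
  specD <- synthetic_spec(seed = 2, conditions = c("ctrl", "DHA"))
  pD <- gen_true_params(specD, netD)
  prD <- gen_substrate_profiles("DHA", specD)
  trC <- simulate_model(netD, pD, prD, times = times)
  trR <- simulate_model(netD, pD, prD, times = times, engine = "R")
  expect_equal(trC$state, trR$state, tolerance = 1e-6)
})
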