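test_that("input interpolation is linear with constant extrapolation", {
  pr <- input_profiles("ctrl", c(0, 10), list(AA = c(0, 10),
                                              EPA = c(3, 1)), ATP0 = 5)
  expect_equal(interpolate_inputs(pr, 5)[["AA"]], 5)
  expect_equal(interpolate_inputs(pr, 25)[["AA"]], 10)   # beyond the grid
  expect_equal(interpolate_inputs(pr, 10)[["EPA"]], 1)   # on a grid point
  expect_equal(interpolate_inputs(pr, 0)[["EPA"]], 3)
  expect_error(input_profiles("ctrl", numeric(0), list(AA = numeric(0)),
                              ATP0 = 0), "empty")
  expect_error(input_profiles("ctrl", c(0, 5), list(AA = c(1, -2)),
                              ATP0 = 0), "negative")
  expect_error(interpolate_inputs(pr, -1), "nonnegative")
})

test_that("zero world is a fixed point of the integration", {
  net <- build_network("EPA")
  p <- make_params(net, value = 0.1)
  p[grep("^a|^x0", names(p))] <- 0   # no synthesis, no initial enzyme
  tr <- simulate_model(net, p, flat_profiles(), times = seq(0, 60, 10))
  expect_equal(max(abs(tr$state)), 0)
})

test_that("an isolated first-order decay matches the closed form", {
  net <- build_network("EPA")
  p <- make_params(net, value = 0)
  p[grep("^Km", names(p))] <- 1
  p["gPGD2"] <- 0.07
  y0 <- initial_state(net, p, c(PGD2 = 4))
  times <- seq(0, 60, 5)
  tr <- simulate_model(net, p, flat_profiles(), times = times, y0 = y0,
                       rtol = 1e-8, atol = 1e-12)
  expect_equal(tr$state[, "PGD2"], 4 * exp(-0.07 * times),
               tolerance = 1e-6)
  other <- setdiff(colnames(tr$state), "PGD2")
  expect_equal(max(abs(tr$state[, other])), 0)
})

test_that("solutions are stable under tolerance and grid refinement", {
  w <- get_world()
  t7 <- default_times()
  tr1 <- simulate_model(w$net, w$truth, w$profiles$EPA, times = t7)
  tr2 <- simulate_model(w$net, w$truth, w$profiles$EPA, times = t7,
                        rtol = 5e-7, atol = 5e-10)
  expect_equal(tr1$state, tr2$state, tolerance = 1e-5)
  dense <- sort(unique(c(t7, seq(0, 60, 0.5))))
  tr3 <- simulate_model(w$net, w$truth, w$profiles$EPA, times = dense)
  expect_equal(tr3$state[match(t7, dense), ], tr1$state, tolerance = 1e-5)
})

test_that("trajectories from nonnegative initial states stay nonnegative", {
  for (seed in 1:3) {
    w <- get_world(seed)
    for (cond in names(w$profiles)) {
      tr <- simulate_model(w$net, w$truth, w$profiles[[cond]],
                           times = seq(0, 60, 0.5))
      expect_gte(min(tr$state), -1e-8)
    }
  }
})

test_that("disabling the controls reduces the model to plain mass action", {
  # independent implementation of the reduced (uncontrolled) EPA model
  w <- get_world()
  p <- w$truth
  prof <- w$profiles$EPA
  fAA <- approxfun(prof$time, prof$values$AA, rule = 2)
  fEPA <- approxfun(prof$time, prof$values$EPA, rule = 2)
  reduced <- function(t, y, parms) {
    AA <- max(0, fAA(t)); EPA <- max(0, fEPA(t))
    ATP <- prof$ATP0 * exp(-p[["dATP"]] * t)
    atpf <- 1 + p[["kATP"]] * ATP
    y <- pmax(y, 0)
    S <- y[1] + y[7]
    with(as.list(p), {
      d <- numeric(13)
      d[1] <- kPGH2 * AA * y[10] * atpf - gPGH2 * y[1] -
        kPGD2 * y[1] * y[11] - kPGE2 * y[1] * y[12]
      d[7] <- kPGH3 * EPA * y[10] * atpf - gPGH3 * y[7] -
        kPGD3 * y[7] * y[11] - kPGE3 * y[7] * y[12]
      d[2] <- kPGD2 * y[1] * y[11] - gPGD2 * y[2] -
        kdhkPGD2 * y[2] * y[13] - kPGJ2 * y[2] - kdPGD2 * y[2]
      d[3] <- kPGE2 * y[1] * y[12] - gPGE2 * y[3]
      d[4] <- kPGJ2 * y[2] - gPGJ2 * y[4]
      d[5] <- kdPGD2 * y[2] - gdPGD2 * y[5]
      d[6] <- kdhkPGD2 * y[2] * y[13] - gdhkPGD2 * y[6]
      d[8] <- kPGD3 * y[7] * y[11] - gPGD3 * y[8]
      d[9] <- kPGE3 * y[7] * y[12] - gPGE3 * y[9]
      d[10] <- aCOX + 0.5 * kePGH2 * AA / (KmAA + AA) +
        0.5 * kePGH3 * EPA / (KmEPA + EPA) - bCOX * y[10]
      d[11] <- aPtgds + kePtgds * S / (KmPtgds + S) - bPtgds * y[11]
      d[12] <- aPtges + kePtges * S / (KmPtges + S) - bPtges * y[12]
      d[13] <- kedhk * y[2] / (Kmdhk + y[2]) - bdhk * y[13]
      list(d)
    })
  }
  # state order: PGH2 PGD2 PGE2 PGJ2 dPGD2 dhkPGD2 PGH3 PGD3 PGE3
  #              eCOX ePtgds ePtges edhkPGD2
  y0 <- c(numeric(9), p[["x0eCOX"]], p[["x0ePtgds"]], p[["x0ePtges"]],
          p[["x0edhkPGD2"]])
  times <- default_times()
  ref <- deSolve::ode(y0, times, reduced, NULL, method = "lsoda",
                      rtol = 1e-6, atol = 1e-9)
  tr <- simulate_model(w$net, p, prof, times = times, cybernetic = FALSE)
  expect_equal(unname(tr$state), unname(unclass(ref)[, -1]),
               tolerance = 1e-5)
})

test_that("intermediate bound report matches a brute-force grid scan", {
  w <- get_world()
  tr <- simulate_model(w$net, w$truth, w$profiles$EPA,
                       times = seq(0, 60, 0.1))
  rep <- check_intermediate_bound(tr, bound = 10)
  expect_setequal(rep$species, c("PGH2", "PGH3"))
  for (i in seq_len(nrow(rep))) {
    expect_equal(rep$max[i], max(tr$state[, rep$species[i]]))
  }
  # fabricated trajectories around the bound
  fake <- structure(list(time = 0:5,
                         state = cbind(PGH2 = rep(0, 6), PGH3 = rep(0, 6)),
                         condition = "ctrl"), class = "trajectory")
  expect_true(all(check_intermediate_bound(fake, 10)$pass))
  fake$state[, "PGH2"] <- 11
  out <- check_intermediate_bound(fake, 10)
  expect_false(out$pass[out$species == "PGH2"])
  expect_equal(out$max[out$species == "PGH2"], 11)
})
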