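lam_yb177 <- decay_constant("yb177")
lam_lu177 <- decay_constant("lu177g")

test_that("the indirect + direct chains reproduce the published 5-day yield", {
  t5 <- 5 * 86400
  indirect <- bateman_during(c(lam_yb177, lam_lu177), table5_rates[["dp_yb177"]], t5)
  direct <- bateman_during(lam_lu177, table5_rates[["dn_lu177g"]], t5)
  n_lu <- indirect[2] + direct[1]
  expect_equal(n_lu, 3.65e18, tolerance = 0.01)
  expect_equal(lam_lu177 * n_lu / 1e9, 4406, tolerance = 0.01)
  # the direct route carries a few percent of the combined atoms
  expect_equal(direct[1] / n_lu, 0.0355, tolerance = 0.01)
})

test_that("inventories start at zero and saturate at source/lambda", {
  expect_identical(bateman_during(c(lam_yb177, lam_lu177), 1e13, 0), c(0, 0))
  lam <- log(2) / 3600
  expect_equal(bateman_during(lam, 1e10, 1e9), 1e10 / lam, tolerance = 1e-9)
})

test_that("post-irradiation decay reproduces the published 48 h state", {
  t5 <- 5 * 86400
  n0 <- bateman_during(c(lam_yb177, lam_lu177), table5_rates[["dp_yb177"]], t5)
  n0[2] <- n0[2] + bateman_during(lam_lu177, table5_rates[["dn_lu177g"]], t5)
  n48 <- bateman_decay(n0, c(lam_yb177, lam_lu177), 48 * 3600)
  expect_equal(n48[2], 3.05e18, tolerance = 0.01)
  expect_equal(lam_lu177 * n48[2] / 1e9, 3682, tolerance = 0.01)
  # tau = 0 is the identity
  expect_identical(bateman_decay(n0, c(lam_yb177, lam_lu177), 0), n0)
  # an orphan nuclide decays as a bare exponential
  lam <- log(2) / 5000
  expect_equal(bateman_decay(1e15, lam, 1234), 1e15 * exp(-lam * 1234))
})

test_that("a 12-day irradiation reaches the published activity", {
  t12 <- 12 * 86400
  n <- bateman_during(c(lam_yb177, lam_lu177), table5_rates[["dp_yb177"]], t12)
  n_lu <- n[2] + bateman_during(lam_lu177, table5_rates[["dn_lu177g"]], t12)
  expect_equal(lam_lu177 * n_lu / 1e9, 7840, tolerance = 0.01)
})

test_that("closed form agrees with the ODE oracle on the reference chains", {
  for (t_d in c(5, 12)) {
    t_s <- t_d * 86400
    cf <- bateman_during(c(lam_yb177, lam_lu177), 1.065e13, t_s)
    ode <- ode_oracle(c(lam_yb177, lam_lu177), 1.065e13, t_s)
    expect_equal(cf, ode, tolerance = 1e-8)
  }
})

test_that("closed form matches the ODE oracle on randomized chains", {
  set.seed(7)
  for (i in seq_len(100)) {
    n <- sample(1:4, 1)
    repeat {  # decay constants spread over <= 6 decades, well separated
      lam <- 10^runif(n, -8, -2)
      if (n == 1 || min(diff(sort(lam)) / sort(lam)[-1]) > 1e-4) break
    }
    src <- 10^runif(1, 8, 14)
    t_s <- 10^runif(1, 2, 7)
    cf <- bateman_during(lam, src, t_s)
    ode <- ode_oracle(lam, src, t_s)
    expect_chain_close(cf, ode)
    # and the decay phase, starting from the irradiated state; the horizon
    # is capped at 10 e-folds of the fastest component, beyond which the
    # inventory is numerically extinct and the ODE oracle cannot resolve it
    tau <- min(10^runif(1, 2, 6), 10 / max(lam))
    cf2 <- bateman_decay(cf, lam, tau)
    ode2 <- ode_oracle(lam, 0, tau, n_init = cf, rtol = 1e-12)
    expect_chain_close(cf2, ode2)
  }
})

test_that("near-degenerate decay constants are handled without NaN", {
  lam <- c(1e-5, 1e-5 * (1 + 1e-12), 2e-5)
  n <- bateman_during(lam, 1e12, 1e5)
  expect_false(anyNA(n))
  expect_true(all(is.finite(n)))
  expect_equal(n, ode_oracle(lam, 1e12, 1e5), tolerance = 1e-6)
})

test_that("atoms are conserved through a chain with a terminal sink", {
  # append the stable decay sink: source * t must equal the chain total
  lam <- c(lam_yb177, lam_lu177, 0)
  for (t_s in c(3600, 86400, 5 * 86400, 50 * 86400)) {
    n <- bateman_during(lam, 1e13, t_s)
    expect_equal(sum(n), 1e13 * t_s, tolerance = 1e-9)
  }
  # and through a decay phase
  n0 <- bateman_during(lam, 1e13, 5 * 86400)
  n1 <- bateman_decay(n0, lam, 7 * 86400)
  expect_equal(sum(n1), sum(n0), tolerance = 1e-12)
})

test_that("inventories grow monotonically during irradiation", {
  routes <- lu177_routes(table5_rates)
  times <- c(0.2, 0.5, 1, 2, 5, 9, 14) * 86400
  atoms <- sapply(times, function(t) {
    inv <- inventory_during_irradiation(routes, t)
    setNames(inv$atoms, inv$nuclide)[c("lu177g", "lu177m", "lu176m", "yb177")]
  })
  for (r in seq_len(nrow(atoms))) expect_true(all(diff(atoms[r, ]) > -1e-6))
})

test_that("route combination is additive and empty sets give zero inventory", {
  t5 <- 5 * 86400
  r_ind <- decay_route(c("yb177", "lu177g"), table5_rates[["dp_yb177"]])
  r_dir <- decay_route("lu177g", table5_rates[["dn_lu177g"]])
  both <- inventory_during_irradiation(list(r_ind, r_dir), t5)
  ind <- inventory_during_irradiation(r_ind, t5)
  n_both <- both$atoms[both$nuclide == "lu177g"]
  n_ind <- ind$atoms[ind$nuclide == "lu177g"]
  expect_equal(n_both - n_ind,
               bateman_during(decay_constant("lu177g"),
                              table5_rates[["dn_lu177g"]], t5))
  empty <- combine_routes(list())
  expect_identical(nrow(as.data.frame(empty)), 0L)
})

test_that("end-of-irradiation continuity holds across the phase boundary", {
  routes <- lu177_routes(table5_rates)
  eoi <- inventory_during_irradiation(routes, 5, unit = "d")
  same <- inventory_post_irradiation(eoi, 0)
  expect_equal(same$atoms, eoi$atoms)
})

test_that("target depletion follows the exponential law", {
  n0 <- 3.148e21
  k <- 6.07e13 / n0
  expect_identical(target_depletion(n0, k, 0), n0)
  t10 <- log(10 / 9) / k
  expect_equal(target_depletion(n0, k, t10) / n0, 0.9, tolerance = 1e-12)
  # 100-day depletion of the reference target sits between 10 and 20 percent
  f100 <- 1 - target_depletion(1, k, 100 * 86400)
  expect_gt(f100, 0.10); expect_lt(f100, 0.20)
})

test_that("yield reports normalise radiopurity and compute masses", {
  routes <- lu177_routes(table5_rates)
  inv <- inventory_post_irradiation(
    inventory_during_irradiation(routes, 5, unit = "d"), 48, unit = "h")
  rep <- yield_report(inv, c("lu177m", "lu177g", "lu176m", "lu174m", "lu174g"))
  expect_equal(sum(rep$radiopurity_pct), 100, tolerance = 1e-9)
  expect_equal(rep$radiopurity_pct[rep$nuclide == "lu177g"], 99.81,
               tolerance = 0.001)
  # mass = N M / N_A
  i <- match("lu177g", rep$nuclide)
  expect_equal(rep$mass_mg[i],
               rep$atoms[i] * 176.943764 / 6.02214076e23 * 1e3)
  # a single-nuclide set is 100 percent pure by construction
  solo <- yield_report(inv, "lu177g")
  expect_equal(solo$radiopurity_pct, 100)
  # stable nuclides report zero activity, with a note
  expect_message(rep2 <- yield_report(inv, c("lu177g", "lu175")))
  expect_equal(rep2$activity_gbq[rep2$nuclide == "lu175"], 0)
})

test_that("isomer activity ratio and specific activities match the study", {
  routes <- lu177_routes(table5_rates)
  eoi <- inventory_during_irradiation(routes, 5, unit = "d")
  rep <- yield_report(eoi, c("lu177m", "lu177g", "lu176m", "lu174m", "lu174g"))
  ratio <- rep$activity_gbq[rep$nuclide == "lu177m"] /
    rep$activity_gbq[rep$nuclide == "lu177g"]
  expect_equal(ratio, 1.03e-3, tolerance = 0.03)
  fin <- inventory_post_irradiation(eoi, 48, unit = "h")
  expect_equal(specific_activity(fin, "lu177g", basis = "element"),
               594, tolerance = 0.03)
  expect_equal(specific_activity(fin, "lu177g", basis = "radionuclide",
                                 nuclides = c("lu177m", "lu177g", "lu176m",
                                              "lu174m", "lu174g")),
               3750, tolerance = 0.03)
})
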