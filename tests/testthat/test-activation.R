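test_that("integrated flux matches the published value and scales linearly", {
  expect_equal(beam_flux(ref_beam, include_transmission = FALSE), 1.99e16,
               tolerance = 0.005)
  expect_equal(beam_flux(ref_beam), 0.985 * beam_flux(ref_beam, FALSE))
  expect_equal(beam_flux(beam(current_ma = 1e-12)) /
                 beam_flux(beam(current_ma = 1)), 1e-12)
  expect_error(beam(radius_cm = 0), class = "radyield_error_input")
})

test_that("production rate reproduces the published (d,p) formation rate", {
  # with the published averaged cross section inserted directly
  expect_equal(production_rate(ref_beam, ref_target, sigma_mb = 175.4),
               1.065e13, tolerance = 0.02)
  # and end to end through the fixture excitation curve
  xs <- yb176_xs_library("nagai")$dp_yb177
  expect_equal(production_rate(ref_beam, ref_target, xs), 1.065e13,
               tolerance = 0.02)
})

test_that("production rate is linear in its scenario factors", {
  base <- production_rate(ref_beam, ref_target, sigma_mb = 100)
  # eta
  tg0 <- irradiation_target(yb2o3, exit_energy_mev = 8, enrichment = 0.5)
  expect_equal(production_rate(ref_beam, tg0, sigma_mb = 100), base * 0.5 / 0.99)
  # current and transmission
  b2 <- beam(current_ma = 20); b3 <- beam(transmission = 0.985 / 2)
  expect_equal(production_rate(b2, ref_target, sigma_mb = 100), 2 * base)
  expect_equal(production_rate(b3, ref_target, sigma_mb = 100), base / 2)
  # small-thickness limit: Gamma ~ T
  t1 <- irradiation_target(yb2o3, thickness_mm = 1e-4)
  t2 <- irradiation_target(yb2o3, thickness_mm = 2e-4)
  r1 <- production_rate(ref_beam, t1, sigma_mb = 100)
  r2 <- production_rate(ref_beam, t2, sigma_mb = 100)
  expect_equal(r2 / r1, 2, tolerance = 1e-6)
})

test_that("enrichment zero yields nothing", {
  expect_error(irradiation_target(yb2o3, exit_energy_mev = 8, enrichment = 0),
               class = "radyield_error_input")
  # the closest admissible statement: rate is proportional to enrichment
  tg <- irradiation_target(yb2o3, exit_energy_mev = 8, enrichment = 1e-9)
  expect_lt(production_rate(ref_beam, tg, sigma_mb = 175.4), 1e5)
})

test_that("doubling the radius at fixed current leaves the rate unchanged", {
  b <- beam(radius_cm = 2)
  tg <- irradiation_target(yb2o3, radius_cm = 2, exit_energy_mev = 8)
  expect_equal(production_rate(b, tg, sigma_mb = 175.4),
               production_rate(ref_beam, ref_target, sigma_mb = 175.4),
               tolerance = 1e-12)
})

test_that("thick targets are rejected with a pointer to the stopping module", {
  tg <- irradiation_target(yb2o3, exit_energy_mev = 0.5)
  expect_error(production_rate(ref_beam, tg, sigma_mb = 100),
               class = "radyield_error_thick_target")
})

test_that("figures of merit reproduce the design study and its ranking", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  fom <- figures_of_merit(
    tibble::tibble(energy_mev = c(16, 18, 20), exit_energy_mev = c(6, 8, 10)),
    yb2o3, xs)
  expect_equal(fom$de_per_t_mev_mm, c(31.3, 27.8, 25.0), tolerance = 0.02)
  # production-per-beam-energy key selects the 18 MeV design...
  expect_identical(which.max(fom$t_sigma_per_e_mm_mb_mev), 2L)
  # ...while raw production would select 20 MeV
  expect_identical(which.max(fom$t_sigma_mm_mb), 3L)
  expect_error(figures_of_merit(
    tibble::tibble(energy_mev = 18, exit_energy_mev = 18), yb2o3, xs),
    class = "radyield_error_interval")
})

test_that("rate tables are self-consistent through the averaged cross section", {
  tab <- reaction_rates(ref_beam, ref_target, yb176_xs_library("nagai"))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$rate_atoms_per_s[i],
                 production_rate(ref_beam, ref_target,
                                 sigma_mb = tab$sigma_avg_mb[i]),
                 tolerance = 1e-3)
  }
})

test_that("burn-up rates reproduce the published values for both targets", {
  lib <- yb176_xs_library("tendl_dagger")
  expect_equal(burnup_rate(ref_beam, ref_target, lib), 6.07e13,
               tolerance = 0.02)
  tab <- reaction_rates(ref_beam, ref_target, lib)
  expect_equal(tab$rate_atoms_per_s[tab$reaction == "d_nonelastic"],
               7.105e13, tolerance = 0.02)
  # the same cross sections on a metallic target, 18 -> 8 MeV
  tg_metal <- irradiation_target(yb_metal, exit_energy_mev = 8)
  expect_equal(burnup_rate(ref_beam, tg_metal, lib), 7.77e13,
               tolerance = 0.02)
  # ordering invariant: non-elastic >= burn-up >= 0
  expect_gte(tab$rate_atoms_per_s[tab$reaction == "d_nonelastic"],
             tab$rate_atoms_per_s[tab$reaction == "d_burnup"])
})

test_that("time to 10 percent burn-up exceeds two months", {
  lib <- yb176_xs_library("tendl_dagger")
  expect_gt(time_to_burnup_fraction(0.10, ref_beam, ref_target, lib), 60)
  # continuity at zero depletion
  expect_lt(time_to_burnup_fraction(1e-9, ref_beam, ref_target, lib), 1e-3)
  expect_error(time_to_burnup_fraction(0, ref_beam, ref_target, lib),
               class = "radyield_error_input")
})
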