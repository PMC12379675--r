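test_that("interpolation is exact on nodes, zero below threshold, capped above", {
  xs <- excitation_function(
    data.frame(energy_mev = c(2, 4, 6, 10), sigma_mb = c(0, 5, 40, 10)))
  expect_identical(sigma_at(xs, c(2, 4, 6, 10)), c(0, 5, 40, 10))
  expect_equal(sigma_at(xs, 5), 22.5)  # linear between nodes
  expect_identical(sigma_at(xs, 1), 0)
  expect_error(sigma_at(xs, 11), class = "radyield_error_extrapolation")
})

test_that("excitation function constructor enforces its invariants", {
  expect_error(excitation_function(
    data.frame(energy_mev = c(2, 2), sigma_mb = c(1, 1))),
    class = "radyield_error_input")
  expect_error(excitation_function(
    data.frame(energy_mev = c(1, 2), sigma_mb = c(-1, 1))),
    class = "radyield_error_input")
})

test_that("the (d,p) fixture reproduces its published anchors", {
  lib <- yb176_xs_library("nagai")
  xs <- lib$dp_yb177
  expect_equal(sigma_at(xs, 12.5), 230, tolerance = 1e-6)
  expect_identical(sigma_at(xs, 4), 0)     # below the 5 MeV threshold
  expect_identical(sigma_at(xs, 5), 0)
  expect_gt(sigma_at(xs, 5.5), 0)
  # Table-4 thin-target averages within the fixture calibration tolerance
  expect_equal(thin_target_avg_xs(xs, yb2o3, 16, 6), 167.4, tolerance = 0.03)
  expect_equal(thin_target_avg_xs(xs, yb2o3, 18, 8), 175.4, tolerance = 0.03)
  expect_equal(thin_target_avg_xs(xs, yb2o3, 20, 10), 167.9, tolerance = 0.03)
})

test_that("range-averaged cross section of a constant curve is the constant", {
  const <- excitation_function(
    data.frame(energy_mev = c(0, 30), sigma_mb = c(42, 42)))
  expect_equal(range_averaged_xs(const, yb2o3, 17.9), 42, tolerance = 1e-12)
  expect_equal(range_averaged_xs(const, yb2o3, 17.9, mode = "approximate"),
               42, tolerance = 1e-12)
  expect_equal(thin_target_avg_xs(const, yb2o3, 18, 8), 42, tolerance = 1e-12)
})

test_that("averaged cross sections are bounded by the curve extremes", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  for (e in c(10, 14, 17.9)) {
    v <- range_averaged_xs(xs, yb2o3, e)
    expect_gte(v, 0)
    expect_lte(v, max(xs$sigma_mb))
  }
})

test_that("range-averaged cross section peaks near the design beam energy", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  es <- seq(10, 20, by = 0.25)
  ra <- vapply(es, function(e) range_averaged_xs(xs, yb2o3, e), numeric(1))
  expect_gt(es[which.max(ra)], 16)
  expect_lt(es[which.max(ra)], 19)
})

test_that("precise and approximate averaging modes agree to first order", {
  # the energy-weighted form treats the slowly varying logarithm in S as
  # constant; over the full tracking window (cutoff to 17.9 MeV) the
  # logarithm still varies enough that the two differ by several percent
  xs <- yb176_xs_library("nagai")$dp_yb177
  p <- range_averaged_xs(xs, yb2o3, 17.9, mode = "precise")
  a <- range_averaged_xs(xs, yb2o3, 17.9, mode = "approximate")
  expect_equal(a / p, 1, tolerance = 0.10)
})

test_that("quadrature agrees with a 1 keV trapezoid oracle", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  expect_equal(thin_target_avg_xs(xs, yb2o3, 18, 8),
               trapz_avg_xs(xs, yb2o3, 18, 8), tolerance = 1e-6)
  expect_equal(thin_target_avg_xs(xs, yb2o3, 16, 6),
               trapz_avg_xs(xs, yb2o3, 16, 6), tolerance = 1e-6)
})

test_that("thin-target average is grid-refinement invariant", {
  # re-tabulating the same piecewise-linear curve on a finer grid must not
  # change the converged quadrature
  xs <- yb176_xs_library("nagai")$dp_yb177
  fine_e <- seq(0, 30, by = 0.025)
  fine <- excitation_function(
    data.frame(energy_mev = fine_e, sigma_mb = sigma_at(xs, fine_e)))
  expect_equal(thin_target_avg_xs(fine, yb2o3, 18, 8),
               thin_target_avg_xs(xs, yb2o3, 18, 8), tolerance = 1e-9)
})

test_that("thin-target average reduces to the range average at the cutoff", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  emin <- energy_cutoff(yb2o3)
  expect_equal(thin_target_avg_xs(xs, yb2o3, 18, emin * (1 + 1e-12)),
               range_averaged_xs(xs, yb2o3, 18, mode = "precise"),
               tolerance = 1e-9)
  expect_error(thin_target_avg_xs(xs, yb2o3, 18, 19),
               class = "radyield_error_interval")
  expect_error(thin_target_avg_xs(xs, yb2o3, 18, 0.5),
               class = "radyield_error_interval")
})

test_that("burn-up composition subtracts the retention channels", {
  lib <- yb176_xs_library("tendl_dagger")
  bx <- burnup_xs(lib)
  expect_identical(attr(bx, "provenance"), "composed")
  # non-negative and bounded by the non-elastic curve everywhere
  expect_true(all(bx$sigma_mb >= 0))
  expect_true(all(bx$sigma_mb <= sigma_at(lib$d_nonelastic, bx$energy_mev) + 1e-9))

  # channels exhausting the non-elastic curve leave nothing
  flat <- function(v) excitation_function(
    data.frame(energy_mev = c(0, 30), sigma_mb = c(v, v)))
  zero_lib <- list(d_nonelastic = flat(100), d_dprime = flat(60),
                   d_np = flat(40))
  expect_true(all(burnup_xs(zero_lib)$sigma_mb == 0))
  expect_error(burnup_xs(list(d_dprime = flat(1))),
               class = "radyield_error_input")
})

test_that("excitation tables survive a write/read round trip losslessly", {
  xs <- yb176_xs_library("nagai")$dp_yb177
  path <- withr::local_tempfile(fileext = ".csv")
  write_excitation_csv(xs, path)
  back <- read_excitation_csv(path)
  expect_identical(back$energy_mev, xs$energy_mev)
  expect_identical(back$sigma_mb, xs$sigma_mb)
  expect_identical(attr(back, "reaction"), attr(xs, "reaction"))
  expect_identical(attr(back, "provenance"), attr(xs, "provenance"))
})

test_that("fixture datasets carry the published reaction sets", {
  nag <- yb176_xs_library("nagai")
  expect_setequal(names(nag), c("dp_yb177", "dn_lu177g", "d2ng_lu176m",
                                "d4ng_lu174m", "d4n_lu174g"))
  tdl <- yb176_xs_library("tendl_dagger")
  # the evaluated set's (d,p) curve is the same experimental interpolation
  expect_identical(tdl$dp_yb177$sigma_mb, nag$dp_yb177$sigma_mb)
  expect_true(all(c("d_nonelastic", "d_dprime", "d_np") %in% names(tdl)))
  expect_error(yb176_xs_library("exfor"), class = "radyield_error_input")
})

test_that("reaction ids enforce baryon and charge balance", {
  rx <- reaction_id("yb176", c(p = 1), "yb177")
  expect_identical(rx$label, "176Yb(d,p)177Yb")
  expect_identical(reaction_id("yb176", c(n = 2), "lu176m")$label,
                   "176Yb(d,2n)176Lum")
  expect_error(reaction_id("yb176", c(p = 1), "lu177g"),
               class = "radyield_error_input")
})
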