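# Shared fixtures: reference materials, beam/target, the published rate set
# used as chain inputs, and independent numerical oracles.

yb2o3 <- yb2o3_target()
yb_metal <- yb_metal_target()
ref_beam <- beam()  # 18 MeV, 10 mA, 0.985, r = 1 cm
ref_target <- irradiation_target(yb2o3, exit_energy_mev = 8)

# published ion-formation rates (atoms/s) for the reference scenario,
# with the default dataset choice per reaction
table5_rates <- c(
  dp_yb177 = 1.065e13, dn_lu177g = 3.853e11, dng_lu177m = 2.122e11,
  d2ng_lu176m = 9.02e12, d2n_lu176g = 1.259e13, d3n_lu175 = 2.885e13,
  d4ng_lu174m = 1.418e10, d4n_lu174g = 4.642e11)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# independent brute-force range oracle: fixed-step midpoint sum of 1/S
marching_range <- function(material, energy_mev, ion = radyield::ion("d"),
                           step_mev = 1e-3) {
  emin <- energy_cutoff(material, ion)
  grid <- seq(emin, energy_mev, by = step_mev)
  if (tail(grid, 1L) < energy_mev) grid <- c(grid, energy_mev)
  mids <- (head(grid, -1L) + tail(grid, -1L)) / 2
  sum(diff(grid) / stopping_power(material, mids, ion))
}

# independent ODE oracle for linear chains with a constant source
ode_oracle <- function(lambda, source, time_s, n_init = rep(0, length(lambda)),
                       rtol = 1e-11) {
  n <- length(lambda)
  deriv <- function(t, y, p) {
    list(c(source, lambda[-n] * y[-n]) - lambda * y)
  }
  scale <- max(abs(n_init), source * time_s, 1)
  out <- deSolve::lsoda(y = n_init, times = c(0, time_s), func = deriv,
                        parms = NULL, rtol = rtol, atol = scale * 1e-13,
                        maxsteps = 1e6)
  as.numeric(out[nrow(out), -1L])
}

# per-component chain comparison: relative where the oracle can resolve the
# component, absolute at the oracle's resolution floor otherwise
expect_chain_close <- function(got, oracle, tol = 1e-8) {
  floor_abs <- tol * max(abs(oracle))
  ok <- abs(got - oracle) <= pmax(tol * abs(oracle), floor_abs)
  expect_true(all(ok))
}

# brute-force trapezoid quadrature of sigma/S on a uniform fine grid
trapz_avg_xs <- function(xs, material, e_hi, e_lo, ion = radyield::ion("d"),
                         step_mev = 1e-3) {
  grid <- seq(e_lo, e_hi, by = step_mev)
  if (tail(grid, 1L) < e_hi) grid <- c(grid, e_hi)
  f <- sigma_at(xs, grid) / stopping_power(material, grid, ion)
  g <- 1 / stopping_power(material, grid, ion)
  trap <- function(v) sum(diff(grid) * (head(v, -1L) + tail(v, -1L)) / 2)
  trap(f) / trap(g)
}
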