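# Electronic stopping power (compact Bethe-Bloch form), CSDA range and its
# inverse maps.  Internal unit convention: energies MeV, lengths mm, number
# densities 1/cm3.  Shell and density-effect corrections are deliberately
# omitted: they are small for deuterons in the few-to-twenty MeV window this
# package targets, and the compact logarithmic form keeps the range integral
# and its calibration transparent.

# omega = 4 pi n_e m_e c^2 r_e^2, in MeV/cm
.omega_mev_cm <- function(material) {
  4 * pi * material$electron_density_cm3 * .codata$me_c2_mev * .codata$r_e_cm^2
}

# kappa = 2 m_e c^2 / <I>, dimensionless once multiplied by beta^2
.kappa <- function(material) {
  2 * .codata$me_c2_mev / (material$mean_excitation_ev * 1e-6)
}

# relativistic beta^2 from kinetic energy and rest mass
.beta2 <- function(energy_mev, ion) {
  1 - (ion$rest_mass_mev / (energy_mev + ion$rest_mass_mev))^2
}

#' Low-energy validity cutoff of the stopping-power model
#'
#' The compact Bethe-Bloch form `S = (omega z^2 / beta^2) ln(kappa beta^2)`
#' turns unphysical (negative) once `kappa beta^2 <= 1`.  The package
#' integrates ranges from the energy at which `kappa beta^2 = e`, i.e. where
#' the logarithm equals 1; below that the model is not evaluated.
#'
#' @param material An `ry_material`.
#' @param ion Projectile, see [ion()].
#' @return The cutoff kinetic energy in MeV.
#' @export
#' @examples
#' energy_cutoff(yb2o3_target()) # about 1.28 MeV for deuterons
energy_cutoff <- function(material, ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  b2 <- exp(1) / .kappa(material)
  ion$rest_mass_mev * (1 / sqrt(1 - b2) - 1)
}

#' Electronic stopping power
#'
#' Mean energy loss per unit path length of a light ion in a material,
#' \deqn{S = \frac{\omega z^2}{\beta^2}\,\ln(\kappa\beta^2),}
#' with \eqn{\omega = 4\pi n_e m_e c^2 r_e^2} and
#' \eqn{\kappa = 2 m_e c^2/\langle I\rangle}.  \eqn{\beta^2} is computed
#' relativistically from the kinetic energy and the ion rest mass.
#'
#' @param material An `ry_material`.
#' @param energy_mev Kinetic energy (MeV); vectorised.
#' @param ion Projectile, see [ion()].
#' @return Stopping power in MeV/mm.
#' @export
#' @examples
#' stopping_power(yb2o3_target(), 10)
stopping_power <- function(material, energy_mev, ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  emin <- energy_cutoff(material, ion)
  if (any(energy_mev < emin)) {
    abort(sprintf(
      "energy below the stopping-power validity cutoff (%.4f MeV for %s in %s)",
      emin, ion$symbol, material$name),
      class = "radyield_error_domain")
  }
  b2 <- .beta2(energy_mev, ion)
  s_cm <- .omega_mev_cm(material) * ion$z^2 / b2 * log(.kappa(material) * b2)
  s_cm / 10  # MeV/cm -> MeV/mm
}

# range integral between two energies (mm), adaptive quadrature
.range_integral <- function(material, e_lo, e_hi, ion) {
  if (e_hi <= e_lo) return(0)
  res <- tryCatch(
    integrate(function(e) 1 / stopping_power(material, e, ion),
              lower = e_lo, upper = e_hi,
              rel.tol = 1e-10, abs.tol = 1e-9, subdivisions = 400L),
    error = function(e) {
      abort(paste0("range quadrature failed on [",
                   signif(e_lo, 6), ", ", signif(e_hi, 6), "] MeV: ",
                   conditionMessage(e)),
            class = "radyield_error_numeric")
    })
  res$value
}

# first-order continuation below the cutoff: a particle at E_min is assumed
# to stop over E_min / S(E_min)
.subcutoff_residual <- function(material, ion) {
  emin <- energy_cutoff(material, ion)
  emin / stopping_power(material, emin, ion)
}

#' CSDA range
#'
#' Path length accumulated under the continuous-slowing-down approximation,
#' \eqn{R(E) = \int dE'/S(E')}, by adaptive quadrature from the model cutoff
#' ([energy_cutoff()]) up to `energy_mev`.  Below the cutoff the logarithmic
#' stopping model is invalid; by default the small residual path there is
#' approximated by constant-stopping continuation, `E_min / S(E_min)`
#' (about 15 um in Yb2O3 for deuterons).  Set `subcutoff = "zero"` to drop
#' it; interval quantities such as [thickness_for_interval()] are unaffected
#' either way because the residual cancels in range differences.
#'
#' @inheritParams stopping_power
#' @param subcutoff `"continuation"` (default) or `"zero"`: treatment of the
#'   path below the validity cutoff.
#' @return Range in mm; vectorised over `energy_mev`.
#' @export
#' @examples
#' csda_range(yb2o3_target(), 17.9) # about 0.49 mm
csda_range <- function(material, energy_mev, ion = radyield::ion("d"),
                       subcutoff = c("continuation", "zero")) {
  ion <- radyield::ion(ion)
  subcutoff <- match.arg(subcutoff)
  emin <- energy_cutoff(material, ion)
  if (any(energy_mev < emin)) {
    abort(sprintf("energy below the validity cutoff (%.4f MeV)", emin),
          class = "radyield_error_domain")
  }
  res <- if (subcutoff == "continuation") .subcutoff_residual(material, ion) else 0
  vapply(energy_mev,
         function(e) res + .range_integral(material, emin, e, ion),
         numeric(1))
}

#' Slab thickness spanning an energy interval
#'
#' The thickness a projectile needs to slow from `energy_mev` down to
#' `exit_energy_mev`: \eqn{T = R(E) - R(E_T)}.
#'
#' @inheritParams stopping_power
#' @param exit_energy_mev Exit (residual) energy, MeV.
#' @return Thickness in mm.
#' @export
#' @examples
#' thickness_for_interval(yb2o3_target(), 18, 8) # about 0.36 mm
thickness_for_interval <- function(material, energy_mev, exit_energy_mev,
                                   ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  if (exit_energy_mev > energy_mev) {
    abort("exit energy exceeds entry energy: not a slowing-down interval",
          class = "radyield_error_interval")
  }
  emin <- energy_cutoff(material, ion)
  if (exit_energy_mev < emin) {
    abort(sprintf("exit energy below the validity cutoff (%.4f MeV)", emin),
          class = "radyield_error_domain")
  }
  .range_integral(material, exit_energy_mev, energy_mev, ion)
}

#' Residual energy after a slab
#'
#' Solves \eqn{R(E) - R(E_T) = T} for the mean exit energy \eqn{E_T} of a
#' projectile entering a slab of thickness `thickness_mm` at `energy_mev`,
#' by bracketed root-finding; the defining identity is satisfied to better
#' than 1e-9 mm.
#'
#' @inheritParams stopping_power
#' @param thickness_mm Slab thickness, mm; must be smaller than the
#'   in-target range so the beam traverses the slab (thin-target regime).
#' @return Exit energy in MeV.
#' @export
#' @examples
#' residual_energy(yb2o3_target(), 18, 0.36) # about 8 MeV
residual_energy <- function(material, energy_mev, thickness_mm,
                            ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  if (thickness_mm < 0) {
    abort("thickness must be >= 0", class = "radyield_error_input")
  }
  if (thickness_mm == 0) return(energy_mev)
  emin <- energy_cutoff(material, ion)
  max_t <- .range_integral(material, emin, energy_mev, ion)
  if (thickness_mm >= max_t) {
    abort(sprintf(paste0(
      "slab of %.4g mm stops the beam (in-model range above cutoff: %.4g mm);",
      " this is a thick target, outside the transmission regime"),
      thickness_mm, max_t),
      class = "radyield_error_thick_target")
  }
  f <- function(et) .range_integral(material, et, energy_mev, ion) - thickness_mm
  root <- uniroot(f, lower = emin, upper = energy_mev, tol = 1e-12)
  et <- root$root
  # polish: Newton step in range space (dT/dE_T = -1/S)
  resid <- f(et)
  et <- et + resid * stopping_power(material, et, ion)
  if (abs(f(et)) > 1e-9) {
    abort("residual-energy inversion did not reach 1e-9 mm",
          class = "radyield_error_numeric")
  }
  et
}
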