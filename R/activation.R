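# Beam/target model: integrated flux, production rates, figures of merit for
# the target-thickness / beam-energy trade-off, and burn-up rates.

#' Define a beam
#'
#' @param energy_mev Beam kinetic energy, MeV.
#' @param current_ma Beam current, mA.
#' @param transmission Line transmission efficiency, fraction in (0, 1].
#' @param radius_cm Beam radius, cm; the beam area is assumed equal to the
#'   frontal target area.
#' @param ion Projectile, see [ion()].
#' @return An object of class `ry_beam`.
#' @export
#' @examples
#' beam() # the 10 mA, 18 MeV deuteron reference beam
beam <- function(energy_mev = 18, current_ma = 10, transmission = 0.985,
                 radius_cm = 1, ion = "d") {
  if (energy_mev <= 0 || current_ma < 0 || radius_cm <= 0) {
    abort("need energy > 0, current >= 0, radius > 0",
          class = "radyield_error_input")
  }
  if (transmission <= 0 || transmission > 1) {
    abort("transmission must lie in (0, 1]", class = "radyield_error_input")
  }
  structure(list(energy_mev = energy_mev, current_ma = current_ma,
                 transmission = transmission, radius_cm = radius_cm,
                 ion = radyield::ion(ion)),
            class = "ry_beam")
}

#' @export
print.ry_beam <- function(x, ...) {
  cat(sprintf("<beam>  %.4g MeV %s, %.4g mA, transmission %.3f, r = %.3g cm\n",
              x$energy_mev, x$ion$symbol, x$current_ma, x$transmission,
              x$radius_cm))
  invisible(x)
}

#' Define an irradiation target
#'
#' A thin disc target, specified by either its physical thickness or the
#' exit energy of the traversing beam (the other is derived through the
#' stopping module once a beam energy is known).
#'
#' @param material An `ry_material`.
#' @param radius_cm Target (= beam) radius, cm.
#' @param thickness_mm Target thickness, mm (give this or
#'   `exit_energy_mev`).
#' @param exit_energy_mev Design exit energy, MeV.
#' @param enrichment Fraction of the active nuclide among its element,
#'   in (0, 1].
#' @param active_element Element symbol carrying the active nuclide
#'   (default `"Yb"`).
#' @return An object of class `ry_target`.
#' @export
#' @examples
#' irradiation_target(yb2o3_target(), exit_energy_mev = 8)
irradiation_target <- function(material, radius_cm = 1, thickness_mm = NULL,
                               exit_energy_mev = NULL, enrichment = 0.99,
                               active_element = "Yb") {
  if (is.null(thickness_mm) == is.null(exit_energy_mev)) {
    abort("give exactly one of thickness_mm or exit_energy_mev",
          class = "radyield_error_input")
  }
  if (enrichment <= 0 || enrichment > 1) {
    abort("enrichment must lie in (0, 1]", class = "radyield_error_input")
  }
  if (!active_element %in% material$composition$symbol) {
    abort(paste0("active element ", active_element, " not in material ",
                 material$name), class = "radyield_error_input")
  }
  structure(list(material = material, radius_cm = radius_cm,
                 thickness_mm = thickness_mm,
                 exit_energy_mev = exit_energy_mev,
                 enrichment = enrichment, active_element = active_element),
            class = "ry_target")
}

#' @export
print.ry_target <- function(x, ...) {
  geom <- if (!is.null(x$thickness_mm)) {
    sprintf("T = %.4g mm", x$thickness_mm)
  } else sprintf("exit energy %.4g MeV", x$exit_energy_mev)
  cat(sprintf("<target>  %s disc, r = %.3g cm, %s, enrichment %.3f (%s)\n",
              x$material$name, x$radius_cm, geom, x$enrichment,
              x$active_element))
  invisible(x)
}

# resolve thickness (mm) and exit energy (MeV) for a given beam
.target_geometry <- function(beam, target) {
  m <- target$material
  if (!is.null(target$thickness_mm)) {
    t_mm <- target$thickness_mm
    et <- residual_energy(m, beam$energy_mev, t_mm, beam$ion)
  } else {
    et <- target$exit_energy_mev
    emin <- energy_cutoff(m, beam$ion)
    if (et <= emin) {
      abort(sprintf(paste0(
        "design exit energy %.4g MeV is at or below the stopping cutoff ",
        "(%.4g MeV): a stopping (thick) target; shorten the interval or use ",
        "the stopping module directly"), et, emin),
        class = "radyield_error_thick_target")
    }
    t_mm <- thickness_for_interval(m, beam$energy_mev, et, beam$ion)
  }
  list(thickness_mm = t_mm, exit_energy_mev = et)
}

# number density (1/cm3) of atoms of the active element in the material
.active_atom_density <- function(target) {
  comp <- target$material$composition
  comp$atom_density_cm3[comp$symbol == target$active_element]
}

#' Initial number of active nuclide atoms in the target
#'
#' \eqn{N_0 = \eta\, N\, \pi r^2 T} with \eqn{N} the active element's atom
#' number density; used as the initial condition of burn-up/depletion
#' calculations.
#'
#' @param beam An [beam()]; fixes the thickness when the target is specified
#'   by exit energy.
#' @param target An [irradiation_target()].
#' @return Number of atoms.
#' @export
target_atoms <- function(beam, target) {
  geom <- .target_geometry(beam, target)
  target$enrichment * .active_atom_density(target) *
    pi * target$radius_cm^2 * (geom$thickness_mm / 10)
}

#' Integrated beam flux on target
#'
#' \eqn{\phi = \epsilon J / (q a)} with \eqn{a = \pi r^2}; with
#' `include_transmission = FALSE` the bare accelerator flux \eqn{J/(qa)} is
#' returned.
#'
#' @param beam An [beam()].
#' @param include_transmission Multiply by the line transmission (default).
#' @return Flux in particles/cm2/s.
#' @export
#' @examples
#' beam_flux(beam(), include_transmission = FALSE) # about 1.99e16 d/cm2/s
beam_flux <- function(beam, include_transmission = TRUE) {
  eff <- if (include_transmission) beam$transmission else 1
  eff * (beam$current_ma * 1e-3) /
    (beam$ion$z * .codata$q_coulomb * pi * beam$radius_cm^2)
}

#' Production rate of one reaction
#'
#' Thin-target production rate
#' \deqn{\Gamma = \eta\,\epsilon\,\frac{J}{q}\,T\,N\,
#'   \langle\sigma\rangle_T(E),}
#' with \eqn{T} in cm, \eqn{N} the active element's atom number density and
#' \eqn{\langle\sigma\rangle_T} the thin-target averaged cross section over
#' the beam-entry to exit-energy interval.  Note the area cancels between
#' the flux and the target face, so \eqn{\Gamma} has no explicit radius
#' dependence.
#'
#' @param beam An [beam()].
#' @param target An [irradiation_target()].
#' @param xs An [excitation_function()]; ignored when `sigma_mb` is given.
#' @param sigma_mb Optional pre-averaged cross section in mb, bypassing the
#'   quadrature (useful for published averaged values).
#' @return Production rate in atoms/s.
#' @export
#' @examples
#' b <- beam(); tg <- irradiation_target(yb2o3_target(), exit_energy_mev = 8)
#' production_rate(b, tg, yb176_xs_library("nagai")$dp_yb177) # about 1.06e13
production_rate <- function(beam, target, xs = NULL, sigma_mb = NULL) {
  geom <- .target_geometry(beam, target)
  if (is.null(sigma_mb)) {
    if (is.null(xs)) abort("need an excitation function or sigma_mb",
                           class = "radyield_error_input")
    sigma_mb <- thin_target_avg_xs(xs, target$material, beam$energy_mev,
                                   geom$exit_energy_mev, beam$ion)
  }
  target$enrichment * beam$transmission *
    (beam$current_ma * 1e-3) / (beam$ion$z * .codata$q_coulomb) *
    (geom$thickness_mm / 10) * .active_atom_density(target) *
    (sigma_mb * 1e-27)
}

#' Rate table for a full excitation library
#'
#' Evaluates [production_rate()] for every reaction in the library (burn-up
#' channel curves are composed into a single burn-up entry, and the
#' non-elastic aggregate is reported as a reaction rate), mirroring the
#' published rate-table layout.
#'
#' @inheritParams production_rate
#' @param library An `xs_library`.
#' @return A tibble with columns `reaction`, `product`, `dataset`,
#'   `sigma_avg_mb`, `rate_atoms_per_s`.
#' @export
reaction_rates <- function(beam, target, library) {
  geom <- .target_geometry(beam, target)
  ids <- setdiff(names(library), c("d_dprime", "d_np"))
  rows <- purrr::map(ids, function(id) {
    xs <- library[[id]]
    sig <- thin_target_avg_xs(xs, target$material, beam$energy_mev,
                              geom$exit_energy_mev, beam$ion)
    tibble(reaction = id,
           product = attr(xs, "product") %||% NA_character_,
           dataset = attr(library, "dataset"),
           sigma_avg_mb = sig,
           rate_atoms_per_s = production_rate(beam, target, sigma_mb = sig))
  })
  out <- dplyr::bind_rows(rows)
  if ("d_nonelastic" %in% names(library)) {
    bx <- burnup_xs(library)
    sig <- thin_target_avg_xs(bx, target$material, beam$energy_mev,
                              geom$exit_energy_mev, beam$ion)
    out <- dplyr::bind_rows(out, tibble(
      reaction = "d_burnup", product = NA_character_,
      dataset = attr(library, "dataset"), sigma_avg_mb = sig,
      rate_atoms_per_s = production_rate(beam, target, sigma_mb = sig)))
  }
  out
}

#' Figures of merit for candidate beam/target intervals
#'
#' For each candidate energy interval (beam entry `energy_mev` to exit
#' `exit_energy_mev`) tabulates the slab thickness, deposited energy, heat
#' proxy \eqn{\Delta E/T}, thin-target averaged cross section, the
#' production-rate proxy \eqn{T\langle\sigma\rangle_T} and the
#' production-per-beam-energy proxy \eqn{T\langle\sigma\rangle_T/E} -- the
#' ranking keys of the thickness/energy optimisation.
#'
#' @param intervals A data frame with columns `energy_mev` and
#'   `exit_energy_mev`, one candidate per row.
#' @param material An `ry_material`.
#' @param xs The production [excitation_function()].
#' @param ion Projectile, see [ion()].
#' @return The input tibble extended with `thickness_mm`, `delta_e_mev`,
#'   `de_per_t_mev_mm`, `sigma_avg_mb`, `t_sigma_mm_mb`,
#'   `t_sigma_per_e_mm_mb_mev`.
#' @export
figures_of_merit <- function(intervals, material, xs,
                             ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  df <- as_tibble(intervals)
  if (any(df$exit_energy_mev >= df$energy_mev)) {
    abort("each interval needs exit energy < beam energy (zero-thickness targets are rejected)",
          class = "radyield_error_interval")
  }
  df |>
    dplyr::rowwise() |>
    dplyr::mutate(
      thickness_mm = thickness_for_interval(material, .data$energy_mev,
                                            .data$exit_energy_mev, ion),
      delta_e_mev = .data$energy_mev - .data$exit_energy_mev,
      de_per_t_mev_mm = .data$delta_e_mev / .data$thickness_mm,
      sigma_avg_mb = thin_target_avg_xs(xs, material, .data$energy_mev,
                                        .data$exit_energy_mev, ion),
      t_sigma_mm_mb = .data$thickness_mm * .data$sigma_avg_mb,
      t_sigma_per_e_mm_mb_mev = .data$t_sigma_mm_mb / .data$energy_mev) |>
    dplyr::ungroup()
}

#' Target burn-up rate and depletion timescale
#'
#' `burnup_rate()` evaluates the production-rate formula with the composed
#' burn-up cross section \eqn{\sigma^*} in place of the production cross
#' section, giving the rate at which target nuclei are consumed.
#' `time_to_burnup_fraction()` inverts the exponential depletion law
#' \eqn{1 - e^{-\phi\langle\sigma\rangle^*_T t} = f} for the time at which a
#' fraction `fraction` of the target nuclide is gone.
#'
#' @inheritParams production_rate
#' @param library An `xs_library` holding the non-elastic and retention
#'   channels (see [burnup_xs()]).
#' @return `burnup_rate()`: reactions/s.
#' @export
burnup_rate <- function(beam, target, library) {
  production_rate(beam, target, xs = burnup_xs(library))
}

#' @rdname burnup_rate
#' @param fraction Depleted fraction in (0, 1).
#' @return `time_to_burnup_fraction()`: time in days (`Inf` when the burn-up
#'   rate is zero).
#' @export
time_to_burnup_fraction <- function(fraction, beam, target, library) {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)", class = "radyield_error_input")
  }
  rate <- burnup_rate(beam, target, library)
  if (rate <= 0) return(Inf)
  n0 <- target_atoms(beam, target)
  k <- rate / n0  # = phi <sigma*>_T, 1/s
  -log(1 - fraction) / k / 86400
}
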