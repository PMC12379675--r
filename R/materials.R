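# Material model: stoichiometric composition, density, and the derived
# quantities entering the Bethe-Bloch formula (mean excitation potential by
# Bragg's rule, electron density, per-species atom number densities).

#' Bragg-rule mean excitation potential
#'
#' Combines per-element mean excitation potentials into the effective value
#' for a compound by the electron-weighted logarithmic mean
#' \deqn{\ln\langle I\rangle = \frac{\sum_i N_i Z_i \ln I_i}{\sum_i N_i Z_i},}
#' where \eqn{N_i} is the stoichiometric count and \eqn{Z_i} the atomic
#' number of element \eqn{i}.
#'
#' @param composition A data frame with columns `count`, `z` and `i_ev`
#'   (one row per element), or a material built with [material()].
#' @return The mean excitation potential in eV.
#' @export
#' @examples
#' # ytterbium oxide from I(Yb) = 684 eV and I(O) = 95 eV
#' bragg_mean_excitation(
#'   data.frame(count = c(2, 3), z = c(70, 8), i_ev = c(684, 95))
#' )
bragg_mean_excitation <- function(composition) {
  if (inherits(composition, "ry_material")) {
    composition <- composition$composition
  }
  df <- as.data.frame(composition)
  need <- c("count", "z", "i_ev")
  if (!all(need %in% names(df))) {
    abort("composition needs columns count, z, i_ev",
          class = "radyield_error_input")
  }
  if (nrow(df) == 0L) {
    abort("empty composition", class = "radyield_error_input")
  }
  if (any(df$count < 1) || any(df$i_ev <= 0) || any(df$z < 1)) {
    abort("composition requires count >= 1, z >= 1 and i_ev > 0",
          class = "radyield_error_input")
  }
  w <- df$count * df$z
  exp(sum(w * log(df$i_ev)) / sum(w))
}

.parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(tibble(symbol = names(formula), count = unname(formula)))
  }
  if (is.character(formula) && length(formula) == 1L) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (length(parts) == 0L || paste(parts, collapse = "") != formula) {
      abort(paste0("cannot parse chemical formula '", formula, "'"),
            class = "radyield_error_input")
    }
    sym <- sub("[0-9]*$", "", parts)
    cnt <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                             sub("^[A-Za-z]+", "", parts), "1"))
    return(tibble(symbol = sym, count = cnt))
  }
  abort("formula must be a string like \"Yb2O3\" or a named count vector",
        class = "radyield_error_input")
}

#' Define a target material
#'
#' Builds a stoichiometric material and derives the quantities needed by the
#' stopping-power and activation machinery: molar mass, Bragg-rule mean
#' excitation potential, electron density and per-species atom number
#' densities.
#'
#' @param formula Chemical formula, either a string (`"Yb2O3"`) or a named
#'   count vector (`c(Yb = 2, O = 3)`).
#' @param density_g_cm3 Mass density in g/cm3.
#' @param molar_mass Optional named vector of per-element molar masses
#'   (g/mol) overriding [element_data()]; use this for isotopically enriched
#'   materials.
#' @param excitation_ev Optional named vector of per-element mean excitation
#'   potentials (eV) overriding [element_data()].
#' @param name Optional display name.
#' @return An object of class `ry_material`: a list with `name`,
#'   `composition` (tibble: `symbol`, `count`, `z`, `molar_mass_gmol`,
#'   `i_ev`, `atom_density_cm3`), `density_g_cm3`, `molar_mass_gmol`,
#'   `mean_excitation_ev` and `electron_density_cm3`.
#' @export
#' @examples
#' material("Yb2O3", density_g_cm3 = 9.2)
material <- function(formula, density_g_cm3, molar_mass = NULL,
                     excitation_ev = NULL, name = NULL) {
  if (!is.numeric(density_g_cm3) || density_g_cm3 <= 0) {
    abort("density_g_cm3 must be > 0", class = "radyield_error_input")
  }
  comp <- .parse_formula(formula)
  if (any(comp$count < 1)) {
    abort("stoichiometric counts must be >= 1", class = "radyield_error_input")
  }
  ref <- element_data()
  comp <- dplyr::left_join(comp, ref, by = "symbol")
  if (anyNA(comp$z)) {
    abort(paste0("unknown element(s): ",
                 paste(comp$symbol[is.na(comp$z)], collapse = ", ")),
          class = "radyield_error_input")
  }
  override <- function(col, vals) {
    if (is.null(vals)) return(comp[[col]])
    bad <- setdiff(names(vals), comp$symbol)
    if (length(bad)) abort(paste0("override for element not in formula: ",
                                  paste(bad, collapse = ", ")),
                           class = "radyield_error_input")
    out <- comp[[col]]
    idx <- match(names(vals), comp$symbol)
    out[idx] <- unname(vals)
    out
  }
  comp$molar_mass_gmol <- override("molar_mass_gmol", molar_mass)
  comp$i_ev <- override("i_ev", excitation_ev)

  mm <- sum(comp$count * comp$molar_mass_gmol)
  n_formula <- density_g_cm3 * .codata$n_avogadro / mm  # formula units / cm3
  comp$atom_density_cm3 <- n_formula * comp$count
  ne <- n_formula * sum(comp$count * comp$z)

  structure(list(
    name = name %||% (if (is.character(formula)) formula
                      else paste0(comp$symbol, comp$count, collapse = "")),
    composition = comp[, c("symbol", "count", "z", "molar_mass_gmol", "i_ev",
                           "atom_density_cm3")],
    density_g_cm3 = density_g_cm3,
    molar_mass_gmol = mm,
    mean_excitation_ev = bragg_mean_excitation(comp),
    electron_density_cm3 = ne
  ), class = "ry_material")
}

#' @export
print.ry_material <- function(x, ...) {
  cat(sprintf("<material %s>  rho = %.3g g/cm3, M = %.2f g/mol\n",
              x$name, x$density_g_cm3, x$molar_mass_gmol))
  cat(sprintf("  <I> = %.1f eV (Bragg), n_e = %.4g /cm3\n",
              x$mean_excitation_ev, x$electron_density_cm3))
  invisible(x)
}

# Packaged scenario materials ------------------------------------------------
# The enriched variants carry the 176Yb atomic mass (175.9426 g/mol); the
# natural ones the abundance-weighted 173.045 g/mol.

.m_yb176 <- 175.942574

#' Ytterbium oxide and ytterbium metal target materials
#'
#' Convenience constructors for the two reference target materials:
#' crystalline Yb2O3 (9.2 g/cm3) and metallic Yb (6.9 g/cm3), with the mean
#' excitation potentials I(Yb) = 684 eV and I(O) = 95 eV.  With
#' `enriched = TRUE` (the default) the ytterbium molar mass is that of the
#' 176-isotope, as appropriate for a highly enriched production target.
#'
#' @param enriched Use the 176Yb isotopic molar mass instead of the natural
#'   abundance-weighted one.
#' @return An `ry_material`.
#' @export
#' @examples
#' yb2o3_target()
yb2o3_target <- function(enriched = TRUE) {
  material(c(Yb = 2, O = 3), density_g_cm3 = 9.2,
           molar_mass = if (enriched) c(Yb = .m_yb176),
           name = if (enriched) "[176Yb]Yb2O3" else "Yb2O3")
}

#' @rdname yb2o3_target
#' @export
yb_metal_target <- function(enriched = TRUE) {
  material(c(Yb = 1), density_g_cm3 = 6.9,
           molar_mass = if (enriched) c(Yb = .m_yb176),
           name = if (enriched) "176Yb metal" else "Yb metal")
}
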