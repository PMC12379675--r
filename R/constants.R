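# CODATA-2018 constants; the single source of truth for every formula in the
# package.  All energies are MeV, lengths mm (cross sections mb, densities
# g/cm3) unless a name says otherwise.
.codata <- list(
  me_c2_mev   = 0.51099895,      # electron rest energy
  r_e_cm      = 2.8179403262e-13, # classical electron radius
  n_avogadro  = 6.02214076e23,    # 1/mol
  q_coulomb   = 1.602176634e-19   # elementary charge, C
)

#' Physical constants used throughout the package
#'
#' A single versioned set of CODATA-2018 values: the electron rest energy
#' (MeV), the classical electron radius (cm), the Avogadro constant (1/mol)
#' and the elementary charge (C).
#'
#' @return A one-row tibble with columns `me_c2_mev`, `r_e_cm`,
#'   `n_avogadro`, `q_coulomb`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function() tibble::as_tibble(.codata)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "radyield")
  if (!nzchar(path)) {
    # during development the package may not be installed yet
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("packaged data file not found: ", file))
  path
}

.read_packaged_csv <- function(file) {
  readr::read_csv(.extdata(file), comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Element reference data
#'
#' Atomic numbers, natural-abundance molar masses (g/mol) and mean excitation
#' potentials I (eV) for the elements the package knows about.  Values can be
#' overridden per material via [material()].
#'
#' @return A tibble with columns `symbol`, `z`, `molar_mass_gmol`, `i_ev`.
#' @export
element_data <- function() {
  if (is.null(the$elements)) the$elements <- .read_packaged_csv("element_data.csv")
  the$elements
}

#' Projectile ion reference data
#'
#' Charge numbers and rest energies (MeV) of the light ions supported as
#' projectiles.
#'
#' @return A tibble with columns `symbol`, `name`, `z`, `rest_mass_mev`.
#' @export
ion_data <- function() {
  if (is.null(the$ions)) the$ions <- .read_packaged_csv("ion_data.csv")
  the$ions
}

#' Construct a projectile ion
#'
#' @param symbol One of `"p"`, `"d"`, `"t"`, `"a"` (proton, deuteron, triton,
#'   alpha).
#' @return An object of class `ry_ion`: a list with `symbol`, `z` (charge
#'   number) and `rest_mass_mev`.
#' @export
#' @examples
#' ion("d") # the deuteron, z = 1, m0 c^2 = 1875.613 MeV
ion <- function(symbol = "d") {
  if (inherits(symbol, "ry_ion")) return(symbol)
  tab <- ion_data()
  row <- tab[tab$symbol == symbol, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown ion '", symbol, "'; available: ",
                 paste(tab$symbol, collapse = ", ")),
          class = "radyield_error_input")
  }
  structure(list(symbol = row$symbol, z = row$z,
                 rest_mass_mev = row$rest_mass_mev),
            class = "ry_ion")
}

#' @export
print.ry_ion <- function(x, ...) {
  cat(sprintf("<ion %s>  z = %d, m0c2 = %.3f MeV\n", x$symbol, x$z,
              x$rest_mass_mev))
  invisible(x)
}

# time-unit helpers ---------------------------------------------------------

.time_unit_s <- c(s = 1, min = 60, h = 3600, hr = 3600, d = 86400,
                  y = 365.25 * 86400, yr = 365.25 * 86400)

#' Convert a duration to seconds
#'
#' @param value Numeric duration(s).
#' @param unit One of `"s"`, `"min"`, `"h"`, `"d"`, `"y"`.
#' @return Duration in seconds.
#' @export
to_seconds <- function(value, unit = "s") {
  if (!unit %in% names(.time_unit_s)) {
    abort(paste0("unknown time unit '", unit, "'"),
          class = "radyield_error_input")
  }
  value * .time_unit_s[[unit]]
}

#' Nuclide reference data
#'
#' Half-lives and molar masses of the nuclides in the lutetium-177 production
#' network.  Two half-lives are consistency-adjusted relative to commonly
#' quoted values so that saturation inventories and post-processing activities
#' form a coherent set (176mLu entered in hours, 174mLu at 142.2 d); the
#' adjustment is documented in the methods vignette and flagged in the
#' `note` column.
#'
#' @return A tibble with columns `nuclide`, `element`, `mass_number`,
#'   `isomer`, `half_life_value`, `half_life_unit`, `molar_mass_gmol`,
#'   `stable`, `note`, plus a derived `lambda_per_s` decay constant
#'   (`ln 2 / t_half`; `0` for stable nuclides).
#' @export
nuclide_data <- function() {
  if (is.null(the$nuclides)) {
    tab <- .read_packaged_csv("nuclide_data.csv")
    tab$half_life_s <- Inf
    live <- !tab$stable
    tab$half_life_s[live] <- mapply(to_seconds, tab$half_life_value[live],
                                    tab$half_life_unit[live])
    tab$lambda_per_s <- ifelse(tab$stable, 0, log(2) / tab$half_life_s)
    the$nuclides <- tab
  }
  the$nuclides
}

.nuclide <- function(id) {
  tab <- nuclide_data()
  row <- tab[tab$nuclide == id, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown nuclide '", id, "'; see nuclide_data()"),
          class = "radyield_error_input")
  }
  row
}

#' Decay constant of a nuclide
#'
#' @param nuclide A nuclide id as listed by [nuclide_data()], e.g. `"lu177g"`.
#' @return The decay constant in 1/s (`0` for stable nuclides).
#' @export
decay_constant <- function(nuclide) {
  vapply(nuclide, function(id) .nuclide(id)$lambda_per_s, numeric(1),
         USE.NAMES = length(nuclide) > 1L)
}
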