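# Excitation-function data model: sigma(E) tables with piecewise-linear
# interpolation, range-averaged and thin-target-averaged cross sections, and
# burn-up cross-section composition.

#' Construct an excitation function
#'
#' An excitation function is one reaction's cross-section table sigma(E),
#' stored as a tibble with columns `energy_mev` (strictly ascending) and
#' `sigma_mb` (non-negative), interpolated piecewise-linearly between nodes.
#' No extrapolation is ever performed above the grid; below the first node
#' the cross section is zero (sub-threshold).
#'
#' @param data A data frame with columns `energy_mev` and `sigma_mb`.
#' @param reaction Reaction id, e.g. `"dp_yb177"`; see [reaction_id()].
#' @param product Product nuclide id (see [nuclide_data()]), if any.
#' @param provenance Free-text provenance tag (`"fixture"`, `"file"`,
#'   `"composed"`, ...).
#' @return A tibble of class `excitation_function` with attributes
#'   `reaction`, `product`, `provenance`.
#' @export
excitation_function <- function(data, reaction = NA_character_,
                                product = NA_character_,
                                provenance = "file") {
  df <- as_tibble(as.data.frame(data)[, c("energy_mev", "sigma_mb")])
  if (nrow(df) < 2L) {
    abort("an excitation function needs at least two grid points",
          class = "radyield_error_input")
  }
  if (is.unsorted(df$energy_mev, strictly = TRUE)) {
    abort("energy grid must be strictly ascending",
          class = "radyield_error_input")
  }
  if (any(df$sigma_mb < 0)) {
    abort("cross sections must be >= 0", class = "radyield_error_input")
  }
  structure(df,
            class = c("excitation_function", class(df)),
            reaction = reaction, product = product, provenance = provenance)
}

#' @export
print.excitation_function <- function(x, ...) {
  cat(sprintf("<excitation function %s -> %s (%s)>  %d nodes, %.3g-%.3g MeV, peak %.4g mb\n",
              attr(x, "reaction"), attr(x, "product"), attr(x, "provenance"),
              nrow(x), min(x$energy_mev), max(x$energy_mev), max(x$sigma_mb)))
  invisible(x)
}

#' Interpolate an excitation function
#'
#' Piecewise-linear interpolation of sigma(E).  Energies below the first
#' grid node return 0 (sub-threshold); energies above the last node raise an
#' error rather than extrapolate, so activation integrals can never invent
#' cross section.
#'
#' @param xs An [excitation_function()].
#' @param energy_mev Energies (MeV); vectorised.
#' @return Cross sections in mb.
#' @export
sigma_at <- function(xs, energy_mev) {
  emax <- max(xs$energy_mev)
  if (any(energy_mev > emax + 1e-12)) {
    abort(sprintf(
      "energy %.6g MeV is above the tabulated grid (max %.6g MeV); extrapolation is not allowed",
      max(energy_mev), emax),
      class = "radyield_error_extrapolation")
  }
  out <- approx(xs$energy_mev, xs$sigma_mb, xout = pmin(energy_mev, emax),
                method = "linear", yleft = 0, rule = c(1, 2))$y
  out[energy_mev < xs$energy_mev[1L]] <- 0
  out
}

# cross-section table file dialect -------------------------------------------
# CSV, '#'-prefixed header lines carrying reaction id, units and provenance,
# then two columns energy_mev, sigma_mb.

#' Read / write excitation-function tables
#'
#' The on-disk dialect is delimited text: `#`-prefixed header lines carrying
#' the reaction id, units and provenance, followed by a CSV body with columns
#' `energy_mev`, `sigma_mb`.  [write_excitation_csv()] emits the identical
#' dialect, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return [read_excitation_csv()] returns an [excitation_function()];
#'   [write_excitation_csv()] returns `path` invisibly.
#' @export
read_excitation_csv <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
    else NA_character_
  }
  # base read.csv: correctly rounded double parsing, so that a write/read
  # round trip of %.17g output is bit-exact
  df <- utils::read.csv(path, comment.char = "#")
  excitation_function(df,
                      reaction = pick("reaction"),
                      product = pick("product"),
                      provenance = pick("provenance") %||% "file")
}

#' @rdname read_excitation_csv
#' @param xs An [excitation_function()].
#' @export
write_excitation_csv <- function(xs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# reaction: ", attr(xs, "reaction")),
    paste0("# product: ", attr(xs, "product")),
    paste0("# provenance: ", attr(xs, "provenance")),
    "# units: energy_mev [MeV], sigma_mb [mb]",
    "energy_mev,sigma_mb"), con)
  writeLines(sprintf("%.17g,%.17g", xs$energy_mev, xs$sigma_mb), con)
  invisible(path)
}

# quadrature -----------------------------------------------------------------
# Integrals of f(E) over [a, b] where f involves the piecewise-linear sigma:
# split at the sigma grid nodes (the integrand has kinks there) and apply
# 7-point Gauss-Legendre on each segment, where the integrand is smooth.

.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
        0.1294849661688697))

.segment_quad <- function(f, a, b, knots = numeric(0)) {
  if (b <= a) return(0)
  brk <- sort(unique(c(a, b, knots[knots > a & knots < b])))
  lo <- head(brk, -1L); hi <- tail(brk, -1L)
  half <- (hi - lo) / 2; mid <- (hi + lo) / 2
  nodes <- as.vector(outer(.gl7$x, half) + rep(mid, each = 7L))
  wts <- as.vector(outer(.gl7$w, half))
  sum(wts * f(nodes))
}

#' Range-averaged cross section
#'
#' The cross section averaged over the full slowing-down path of a beam of
#' energy `energy_mev`,
#' \deqn{\langle\sigma\rangle =
#'   \frac{\int \sigma(E')/S(E')\,dE'}{\int dE'/S(E')},}
#' integrated from the model cutoff.  `mode = "precise"` weights by the
#' inverse stopping power; `mode = "approximate"` uses the energy-weighted
#' form \eqn{\int\sigma E\,dE / \int E\,dE}, which is nearly identical
#' because the logarithm in S varies slowly -- the comparison of the two is
#' the standard argument that the average is nearly independent of the
#' stopping material.
#'
#' @param xs An [excitation_function()].
#' @param material An `ry_material`.
#' @param energy_mev Beam energy, MeV.
#' @param ion Projectile, see [ion()].
#' @param mode `"precise"` (1/S-weighted, default) or `"approximate"`
#'   (energy-weighted).
#' @return The averaged cross section in mb.
#' @export
range_averaged_xs <- function(xs, material, energy_mev,
                              ion = radyield::ion("d"),
                              mode = c("precise", "approximate")) {
  mode <- match.arg(mode)
  ion <- radyield::ion(ion)
  emin <- energy_cutoff(material, ion)
  if (energy_mev <= emin) {
    abort(sprintf("beam energy must exceed the validity cutoff (%.4f MeV)",
                  emin), class = "radyield_error_domain")
  }
  knots <- xs$energy_mev
  if (mode == "precise") {
    num <- .segment_quad(function(e) sigma_at(xs, e) / stopping_power(material, e, ion),
                         emin, energy_mev, knots)
    den <- .segment_quad(function(e) 1 / stopping_power(material, e, ion),
                         emin, energy_mev, knots)
  } else {
    num <- .segment_quad(function(e) sigma_at(xs, e) * e, emin, energy_mev, knots)
    den <- .segment_quad(function(e) e, emin, energy_mev, knots)
  }
  num / den
}

#' Thin-target averaged cross section
#'
#' The cross section averaged over the energy interval a projectile spans
#' while fully traversing a slab,
#' \deqn{\langle\sigma\rangle_T = \frac{1}{T}\int_{E_T}^{E}
#'   \frac{\sigma(E')}{S(E')}\,dE', \qquad T = R(E) - R(E_T).}
#' As the exit energy approaches the model cutoff this reduces to the
#' precise-mode [range_averaged_xs()].
#'
#' @inheritParams range_averaged_xs
#' @param exit_energy_mev Exit energy \eqn{E_T}, MeV
#'   (cutoff < \eqn{E_T} <= `energy_mev`).
#' @return The averaged cross section in mb.
#' @export
#' @examples
#' lib <- yb176_xs_library("nagai")
#' thin_target_avg_xs(lib$dp_yb177, yb2o3_target(), 18, 8) # about 175 mb
thin_target_avg_xs <- function(xs, material, energy_mev, exit_energy_mev,
                               ion = radyield::ion("d")) {
  ion <- radyield::ion(ion)
  emin <- energy_cutoff(material, ion)
  if (exit_energy_mev <= emin || exit_energy_mev > energy_mev) {
    abort(sprintf(
      "need cutoff (%.4f MeV) < exit energy <= beam energy; got %.4g -> %.4g",
      emin, energy_mev, exit_energy_mev),
      class = "radyield_error_interval")
  }
  knots <- xs$energy_mev
  num <- .segment_quad(function(e) sigma_at(xs, e) / stopping_power(material, e, ion),
                       exit_energy_mev, energy_mev, knots)
  den <- .segment_quad(function(e) 1 / stopping_power(material, e, ion),
                       exit_energy_mev, energy_mev, knots)
  num / den
}

# burn-up composition ---------------------------------------------------------

#' Target burn-up cross section
#'
#' Composes the burn-up excitation function
#' \deqn{\sigma^*(E) = \sigma^{non}(E) - \sigma(d,d') - \sigma(d,n+p),}
#' i.e. the non-elastic cross section minus the channels that retain the
#' target nuclide.  Curves are interpolated onto the union grid before
#' subtracting; negative differences are clipped to zero with a warning.
#'
#' @param library An `xs_library` (named list of excitation functions)
#'   containing `d_nonelastic` and, optionally, `d_dprime` and `d_np`.
#' @return An [excitation_function()] with provenance `"composed"`.
#' @export
burnup_xs <- function(library) {
  non <- library$d_nonelastic
  if (is.null(non)) {
    abort("library has no non-elastic curve ('d_nonelastic'); cannot compose burn-up",
          class = "radyield_error_input")
  }
  channels <- Filter(Negate(is.null), library[c("d_dprime", "d_np")])
  grids <- c(list(non$energy_mev), lapply(channels, function(x) x$energy_mev))
  grid <- sort(unique(unlist(grids)))
  grid <- grid[grid <= min(vapply(grids, max, numeric(1)))]
  total <- sigma_at(non, grid)
  for (ch in channels) total <- total - sigma_at(ch, grid)
  if (any(total < -1e-9)) {
    warn(sprintf(
      "burn-up composition clipped negative values (most negative %.4g mb) to zero",
      min(total)))
  }
  excitation_function(tibble(energy_mev = grid, sigma_mb = pmax(total, 0)),
                      reaction = "d_burnup", product = NA_character_,
                      provenance = "composed")
}

# reaction ids ---------------------------------------------------------------

#' Construct and validate a reaction id
#'
#' A reaction couples a target nuclide and a projectile to an ejectile
#' multiset and a product nuclide (with ground/metastable flag).  Baryon and
#' charge balance between target + projectile and ejectiles + product is
#' enforced.
#'
#' @param target Target nuclide id, e.g. `"yb176"`.
#' @param ejectiles Named integer vector over `c(n, p, d, t, a, g)` counts;
#'   gammas (`g`) carry no baryon number or charge.
#' @param product Product nuclide id, e.g. `"yb177"` or `"lu177m"`.
#' @param projectile Projectile ion symbol.
#' @return A list of class `ry_reaction` with a canonical `label` like
#'   `"176Yb(d,p)177Yb"`.
#' @export
reaction_id <- function(target, ejectiles, product, projectile = "d") {
  part <- function(sym) switch(sym,
    n = c(a = 1, z = 0), p = c(a = 1, z = 1), d = c(a = 2, z = 1),
    t = c(a = 3, z = 1), a = c(a = 4, z = 2), g = c(a = 0, z = 0),
    abort(paste0("unknown particle '", sym, "'"), class = "radyield_error_input"))
  parse_nuc <- function(id) {
    m <- regmatches(id, regexec("^([a-z]+)([0-9]+)([gm]?)$", id))[[1]]
    if (length(m) == 0L) abort(paste0("cannot parse nuclide id '", id, "'"),
                               class = "radyield_error_input")
    sym <- paste0(toupper(substr(m[2], 1, 1)), substr(m[2], 2, nchar(m[2])))
    el <- element_data()
    z <- el$z[match(sym, el$symbol)]
    if (is.na(z)) abort(paste0("unknown element in nuclide '", id, "'"),
                        class = "radyield_error_input")
    list(id = id, symbol = sym, z = z, a = as.integer(m[3]),
         isomer = if (nzchar(m[4])) m[4] else "g")
  }
  tg <- parse_nuc(target); pr <- parse_nuc(product)
  pj <- part(projectile)
  ej <- vapply(names(ejectiles), part, numeric(2))
  a_out <- sum(ej["a", ] * ejectiles) + pr$a
  z_out <- sum(ej["z", ] * ejectiles) + pr$z
  if (tg$a + pj[["a"]] != a_out || tg$z + pj[["z"]] != z_out) {
    abort(sprintf("reaction does not balance: A %d+%d != %d, Z %d+%d != %d",
                  tg$a, pj[["a"]], a_out, tg$z, pj[["z"]], z_out),
          class = "radyield_error_input")
  }
  ej_lab <- paste0(mapply(function(n, s) if (n > 1) paste0(n, s) else s,
                          ejectiles, names(ejectiles)), collapse = "+")
  structure(list(target = tg, projectile = projectile, ejectiles = ejectiles,
                 product = pr,
                 label = sprintf("%d%s(%s,%s)%d%s%s", tg$a, tg$symbol,
                                 projectile, ej_lab, pr$a, pr$symbol,
                                 if (pr$isomer == "m") "m" else "")),
            class = "ry_reaction")
}

#' @export
print.ry_reaction <- function(x, ...) {
  cat("<reaction ", x$label, ">\n", sep = "")
  invisible(x)
}
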