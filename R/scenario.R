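# Configuration-driven front end: load a scenario from YAML, run the full
# stopping -> averaged cross section -> rates -> decay chain -> report
# pipeline, and emit the stage tables.

.cfg_get <- function(cfg, path, required = TRUE, default = NULL) {
  node <- cfg
  for (key in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required) {
        abort(paste0("scenario config is missing required field '", path, "'"),
              class = "radyield_error_config")
      }
      return(default)
    }
    node <- node[[key]]
  }
  node
}

.cfg_num <- function(cfg, path, required = TRUE, default = NULL,
                     positive = FALSE) {
  v <- .cfg_get(cfg, path, required, default)
  if (is.null(v)) return(v)
  if (!is.numeric(v) || length(v) != 1L || (positive && v <= 0)) {
    abort(paste0("scenario field '", path, "' must be a ",
                 if (positive) "positive " else "", "number"),
          class = "radyield_error_config")
  }
  v
}

#' Read and validate a scenario configuration
#'
#' Scenarios are YAML files binding a beam, a target, a rate source, an
#' irradiation/processing schedule and report options; the packaged
#' reference scenario is at
#' `system.file("extdata", "lu177_reference.yaml", package = "radyield")`.
#' Keys carry explicit units (`energy_mev`, `current_ma`, `thickness_mm`).
#'
#' @param path Path to a YAML (or JSON) scenario file.
#' @return A validated scenario object of class `ry_scenario` (a named
#'   list mirroring the file).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("scenario file not found: ", path),
          class = "radyield_error_config")
  }
  cfg <- yaml::read_yaml(path)
  as_scenario(cfg)
}

#' @rdname read_scenario
#' @param cfg A scenario given as a nested list (already parsed).
#' @export
as_scenario <- function(cfg) {
  .cfg_num(cfg, "beam.energy_mev", positive = TRUE)
  .cfg_num(cfg, "beam.current_ma", positive = TRUE)
  .cfg_num(cfg, "target.enrichment", positive = TRUE)
  .cfg_get(cfg, "target.material.formula")
  .cfg_num(cfg, "target.material.density_g_cm3", positive = TRUE)
  if (is.null(.cfg_get(cfg, "target.thickness_mm", required = FALSE)) &&
      is.null(.cfg_get(cfg, "target.exit_energy_mev", required = FALSE))) {
    abort("scenario needs target.thickness_mm or target.exit_energy_mev",
          class = "radyield_error_config")
  }
  irr <- .cfg_num(cfg, "schedule.irradiation.value")
  if (irr < 0) abort("schedule.irradiation.value must be >= 0",
                     class = "radyield_error_config")
  src <- .cfg_get(cfg, "rates.source", required = FALSE, default = "fixtures")
  if (!src %in% c("fixtures", "reference")) {
    abort("rates.source must be 'fixtures' or 'reference'",
          class = "radyield_error_config")
  }
  structure(cfg, class = c("ry_scenario", "list"))
}

#' @export
print.ry_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s>  %.4g MeV, %.4g mA; %s; %g %s irradiation\n",
              x$name %||% "(unnamed)", x$beam$energy_mev, x$beam$current_ma,
              x$target$material$formula, x$schedule$irradiation$value,
              x$schedule$irradiation$unit %||% "s"))
  invisible(x)
}

.scenario_material <- function(sc) {
  m <- sc$target$material
  material(m$formula, m$density_g_cm3,
           molar_mass = unlist(m$molar_mass),
           excitation_ev = unlist(m$excitation_ev),
           name = m$name %||% m$formula)
}

.scenario_beam <- function(sc) {
  b <- sc$beam
  beam(energy_mev = b$energy_mev, current_ma = b$current_ma,
       transmission = b$transmission %||% 1,
       radius_cm = b$radius_cm %||% 1, ion = b$ion %||% "d")
}

.scenario_target <- function(sc, mat) {
  tg <- sc$target
  irradiation_target(mat, radius_cm = tg$radius_cm %||% 1,
                     thickness_mm = tg$thickness_mm,
                     exit_energy_mev = tg$exit_energy_mev,
                     enrichment = tg$enrichment,
                     active_element = tg$active_element %||% "Yb")
}

#' Published reference rate table
#'
#' The packaged ion-formation rates for the 10 mA, 18 MeV reference
#' scenario, usable as scenario inputs in place of rates recomputed from the
#' fixture excitation library (`rates.source: reference`).
#'
#' @param defaults_only Keep only the dataset marked as the default choice
#'   for each reaction.
#' @return A tibble with columns `reaction`, `dataset`, `rate_atoms_per_s`.
#' @export
lu177_reference_rates <- function(defaults_only = TRUE) {
  tab <- .read_packaged_csv("lu177_reference_rates.csv")
  if (defaults_only) tab <- tab[tab$default == 1, ]
  tab[, c("reaction", "dataset", "rate_atoms_per_s")]
}

# per-reaction dataset selection, fixture route
.scenario_rates <- function(sc, beam, target) {
  sel <- .cfg_get(sc, "rates.datasets", required = FALSE, default = list())
  src <- .cfg_get(sc, "rates.source", required = FALSE, default = "fixtures")
  if (src == "reference") {
    ref <- lu177_reference_rates(defaults_only = FALSE)
    if (length(sel)) {
      keep <- ref$reaction %in% names(sel) &
        ref$dataset == unlist(sel)[ref$reaction]
      rates <- ref[keep, ]
    } else {
      rates <- lu177_reference_rates(defaults_only = TRUE)
    }
    return(rates)
  }
  if (!length(sel)) {
    sel <- list(dp_yb177 = "nagai", dn_lu177g = "nagai",
                dng_lu177m = "tendl_dagger", d2ng_lu176m = "nagai",
                d2n_lu176g = "tendl_dagger", d3n_lu175 = "tendl_dagger",
                d4ng_lu174m = "nagai", d4n_lu174g = "nagai")
  }
  libs <- lapply(setNames(nm = unique(unlist(sel))), yb176_xs_library)
  purrr::imap(sel, function(ds, rx) {
    xs <- libs[[ds]][[rx]]
    if (is.null(xs)) {
      abort(paste0("reaction '", rx, "' not in dataset '", ds, "'"),
            class = "radyield_error_config")
    }
    tibble(reaction = rx, dataset = ds,
           rate_atoms_per_s = production_rate(beam, target, xs))
  }) |> dplyr::bind_rows()
}

.timeline <- function(routes, t_irr_s, t_proc_s, n_points = 25L) {
  snap <- function(inv, t_abs, phase) {
    nd <- nuclide_data()
    as_tibble(inv) |>
      dplyr::mutate(
        time_s = t_abs, phase = phase,
        activity_gbq = nd$lambda_per_s[match(.data$nuclide, nd$nuclide)] *
          .data$atoms / 1e9) |>
      dplyr::select("time_s", "phase", "nuclide", "atoms", "activity_gbq")
  }
  irr_times <- seq(0, t_irr_s, length.out = n_points)
  eoi <- inventory_during_irradiation(routes, t_irr_s)
  rows <- purrr::map(irr_times, function(t) {
    snap(inventory_during_irradiation(routes, t), t, "irradiating")
  })
  if (t_proc_s > 0) {
    proc_times <- seq(0, t_proc_s, length.out = n_points)[-1L]
    rows <- c(rows, purrr::map(proc_times, function(tau) {
      snap(inventory_post_irradiation(eoi, tau), t_irr_s + tau, "cooling")
    }))
  }
  dplyr::bind_rows(rows)
}

#' Run a production scenario end to end
#'
#' Executes the full pipeline for a scenario: target geometry through the
#' stopping module, thin-target averaged cross sections and production
#' rates (from the fixture library or the packaged reference table),
#' burn-up, chain inventories over the irradiation and processing schedule,
#' and the final yield report with specific activities.  The run is fully
#' deterministic: repeated runs produce identical outputs.
#'
#' @param scenario An `ry_scenario` from [read_scenario()]/[as_scenario()],
#'   or a path to a YAML file.
#' @param out_dir Optional directory; when given, the stage tables are
#'   written there (`ranges.csv`, `figures_of_merit.csv`, `rates.csv`,
#'   `inventory_timeline.csv`, `yield_report.csv`, or `.json` mirrors).
#' @param format `"csv"` (default) or `"json"` for the written files.
#' @return An object of class `ry_scenario_result`: a list with the stage
#'   tables (`ranges`, `figures_of_merit`, `rates`, `timeline`,
#'   `report_end_irradiation`, `report_final`) and a one-row `summary`
#'   tibble; see also [tidy.ry_scenario_result()] and
#'   [glance.ry_scenario_result()].
#' @export
#' @examples
#' \donttest{
#' path <- system.file("extdata", "lu177_reference.yaml", package = "radyield")
#' res <- run_scenario(path)
#' glance(res)
#' }
run_scenario <- function(scenario, out_dir = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  sc <- scenario
  mat <- .scenario_material(sc)
  bm <- .scenario_beam(sc)
  tg <- .scenario_target(sc, mat)
  geom <- .target_geometry(bm, tg)

  ranges <- tibble(
    material = mat$name,
    beam_energy_mev = bm$energy_mev,
    exit_energy_mev = geom$exit_energy_mev,
    cutoff_mev = energy_cutoff(mat, bm$ion),
    csda_range_mm = csda_range(mat, bm$energy_mev, bm$ion),
    thickness_mm = geom$thickness_mm)

  fom <- figures_of_merit(
    tibble(energy_mev = bm$energy_mev, exit_energy_mev = geom$exit_energy_mev),
    mat, yb176_xs_library("nagai")$dp_yb177, bm$ion)

  rates <- .scenario_rates(sc, bm, tg)

  # burn-up: composed from the evaluated library unless reference rates asked
  src <- .cfg_get(sc, "rates.source", required = FALSE, default = "fixtures")
  burn <- if (src == "reference") {
    ref <- lu177_reference_rates()
    ref$rate_atoms_per_s[ref$reaction == "d_burnup"]
  } else {
    burnup_rate(bm, tg, yb176_xs_library("tendl_dagger"))
  }
  n0 <- target_atoms(bm, tg)
  t_burn10_d <- -log(1 - 0.10) / (burn / n0) / 86400

  t_irr <- to_seconds(sc$schedule$irradiation$value,
                      sc$schedule$irradiation$unit %||% "s")
  t_proc <- if (!is.null(sc$schedule$processing)) {
    to_seconds(sc$schedule$processing$value,
               sc$schedule$processing$unit %||% "s")
  } else 0

  routes <- lu177_routes(rates)
  rep_nucl <- unlist(.cfg_get(sc, "report.nuclides", required = FALSE,
                              default = list("lu177m", "lu177g", "lu176m",
                                             "lu174m", "lu174g")))
  reference <- .cfg_get(sc, "report.reference", required = FALSE,
                        default = "lu177g")
  if (t_irr > 0) {
    eoi <- inventory_during_irradiation(routes, t_irr)
    fin <- if (t_proc > 0) inventory_post_irradiation(eoi, t_proc) else eoi
    report_eoi <- yield_report(eoi, rep_nucl)
    report_fin <- yield_report(fin, rep_nucl)
    timeline <- .timeline(routes, t_irr, t_proc,
                          .cfg_get(sc, "schedule.timeline_points",
                                   required = FALSE, default = 25L))
    sa_el <- specific_activity(fin, reference, basis = "element")
    sa_rn <- specific_activity(fin, reference, basis = "radionuclide",
                               nuclides = rep_nucl)
  } else {
    # zero-duration irradiation: empty inventory, purity table suppressed
    eoi <- fin <- NULL
    report_eoi <- report_fin <- NULL
    timeline <- tibble(time_s = numeric(0), phase = character(0),
                       nuclide = character(0), atoms = numeric(0),
                       activity_gbq = numeric(0))
    sa_el <- sa_rn <- NA_real_
  }

  summary <- tibble(
    scenario = sc$name %||% "(unnamed)",
    irradiation_s = t_irr, processing_s = t_proc,
    thickness_mm = geom$thickness_mm,
    exit_energy_mev = geom$exit_energy_mev,
    reference = reference,
    reference_atoms = if (!is.null(report_fin)) {
      report_fin$atoms[report_fin$nuclide == reference]
    } else 0,
    reference_mass_mg = if (!is.null(report_fin)) {
      report_fin$mass_mg[report_fin$nuclide == reference]
    } else 0,
    reference_activity_gbq = if (!is.null(report_fin)) {
      report_fin$activity_gbq[report_fin$nuclide == reference]
    } else 0,
    radiopurity_pct = if (!is.null(report_fin)) {
      report_fin$radiopurity_pct[report_fin$nuclide == reference]
    } else NA_real_,
    specific_activity_element_gbq_mg = sa_el,
    specific_activity_radionuclide_gbq_mg = sa_rn,
    burnup_rate_per_s = burn,
    time_to_10pct_burnup_d = t_burn10_d)

  res <- structure(list(
    scenario = sc, material = mat, beam = bm, target = tg,
    geometry = geom, ranges = ranges, figures_of_merit = fom,
    rates = rates, routes = routes, timeline = timeline,
    inventory_end_irradiation = eoi, inventory_final = fin,
    report_end_irradiation = report_eoi, report_final = report_fin,
    summary = summary), class = "ry_scenario_result")

  if (!is.null(out_dir)) write_scenario_outputs(res, out_dir, format)
  res
}

#' @export
print.ry_scenario_result <- function(x, ...) {
  cat("<scenario result ", x$summary$scenario, ">\n", sep = "")
  cat(sprintf("  target: %s, T = %.4g mm (%.4g -> %.4g MeV)\n",
              x$material$name, x$geometry$thickness_mm,
              x$beam$energy_mev, x$geometry$exit_energy_mev))
  if (!is.null(x$report_final)) {
    cat("  yield report after processing:\n")
    print(x$report_final)
  } else {
    cat("  zero-duration irradiation: empty inventory\n")
  }
  invisible(x)
}

#' Write the stage tables of a scenario run
#'
#' @param result An `ry_scenario_result`.
#' @param out_dir Output directory (created if missing).
#' @param format `"csv"` or `"json"`.
#' @return The output paths, invisibly.
#' @export
write_scenario_outputs <- function(result, out_dir,
                                   format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- dplyr::bind_rows(
    if (!is.null(result$report_end_irradiation)) {
      dplyr::mutate(result$report_end_irradiation,
                    phase = "end_of_irradiation", .before = 1L)
    },
    if (!is.null(result$report_final)) {
      dplyr::mutate(result$report_final, phase = "after_processing",
                    .before = 1L)
    })
  tables <- list(ranges = result$ranges,
                 figures_of_merit = result$figures_of_merit,
                 rates = result$rates,
                 inventory_timeline = result$timeline,
                 yield_report = reports)
  paths <- purrr::imap_chr(tables, function(tab, nm) {
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "csv") {
      readr::write_csv(tab, path)
    } else {
      jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                           pretty = TRUE)
    }
    path
  })
  invisible(paths)
}

#' Rank candidate beam/target intervals
#'
#' Evaluates the figure-of-merit table for a set of candidate energy
#' intervals and ranks them by the chosen key: production per unit beam
#' energy (`"t_sigma_per_e"`, the design's efficiency criterion) or raw
#' production (`"t_sigma"`).
#'
#' @param scenario An `ry_scenario` (or YAML path) providing the material
#'   and the production excitation function.
#' @param intervals A data frame with columns `energy_mev`,
#'   `exit_energy_mev`; one candidate per row.
#' @param rank_by `"t_sigma_per_e"` (default) or `"t_sigma"`.
#' @return The figure-of-merit tibble sorted best-first, with a `rank`
#'   column and the best row as attribute `best`.
#' @export
optimize_interval <- function(scenario, intervals,
                              rank_by = c("t_sigma_per_e", "t_sigma")) {
  rank_by <- match.arg(rank_by)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if (nrow(as_tibble(intervals)) < 1L) {
    abort("need at least one candidate interval",
          class = "radyield_error_input")
  }
  mat <- .scenario_material(scenario)
  ds <- .cfg_get(scenario, "rates.datasets.dp_yb177", required = FALSE,
                 default = "nagai")
  xs <- yb176_xs_library(ds)$dp_yb177
  key <- if (rank_by == "t_sigma_per_e") "t_sigma_per_e_mm_mb_mev" else "t_sigma_mm_mb"
  fom <- figures_of_merit(intervals, mat, xs) |>
    dplyr::arrange(dplyr::desc(.data[[key]])) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
  attr(fom, "best") <- fom[1L, ]
  fom
}

# broom-style accessors -------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for scenario results
#'
#' `tidy()` returns the after-processing yield report (one row per reported
#' nuclide); `glance()` returns the one-row scenario summary.
#'
#' @param x An `ry_scenario_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ry_scenario_result <- function(x, ...) {
  x$report_final %||% tibble(nuclide = character(0), atoms = numeric(0),
                             mass_mg = numeric(0), activity_gbq = numeric(0),
                             radiopurity_pct = numeric(0))
}

#' @rdname tidy.ry_scenario_result
#' @export
glance.ry_scenario_result <- function(x, ...) x$summary
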