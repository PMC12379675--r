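# Closed-form solver for linear production-decay chains with a constant
# source term (the generalized Bateman solutions), plus the post-irradiation
# decay forms and the exponential target-depletion law.  Near-degenerate
# decay constants fall back to a stiff ODE integration: correctness over
# closed-form purity.

.DEGENERATE_RTOL <- 1e-9

.has_degenerate <- function(lambda) {
  lam <- lambda[lambda > 0]
  if (length(lam) < 2L) return(FALSE)
  lam <- sort(lam)
  any(diff(lam) / lam[-1L] < .DEGENERATE_RTOL)
}

# ODE route: dN1 = source - l1 N1 ; dNj = l_{j-1} N_{j-1} - l_j N_j
.ode_chain <- function(n_init, lambda, source, time_s,
                       rtol = 1e-10, atol = NULL) {
  n <- length(lambda)
  if (time_s == 0) return(n_init)
  scale <- max(abs(n_init), source * time_s, 1)
  atol <- atol %||% (scale * 1e-14)
  deriv <- function(t, y, p) {
    inflow <- c(source, lambda[-n] * y[-n])
    list(inflow - lambda * y)
  }
  out <- deSolve::lsoda(y = n_init, times = c(0, time_s), func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  as.numeric(out[nrow(out), -1L])
}

#' Closed-form chain inventory during irradiation
#'
#' Solves the linear chain fed by a constant source `source_rate` into its
#' first member,
#' \deqn{N_n(t) = \frac{\Gamma}{\lambda_n}\sum_{j=1}^{n}
#'   \left(1 - e^{-\lambda_j t}\right)
#'   \prod_{k\ne j}\lambda_k(\lambda_k-\lambda_j)^{-1},}
#' for every member of the chain.  A terminal stable member
#' (\eqn{\lambda = 0}) is treated as a sink and filled by atom conservation.
#' If two decay constants agree to better than 1e-9 relative the closed form
#' is numerically singular and a stiff ODE integration is used instead.
#'
#' @param lambda Decay constants (1/s) of the chain members, in decay order;
#'   only the last may be 0 (a stable sink).
#' @param source_rate Constant production rate into the first member,
#'   atoms/s.
#' @param time_s Irradiation time, s.
#' @return Numeric vector of atom counts, one per chain member.
#' @export
#' @examples
#' # saturation of a single-step product: N -> source/lambda
#' bateman_during(log(2) / 6880, 1e13, 5 * 86400)
bateman_during <- function(lambda, source_rate, time_s) {
  n <- length(lambda)
  if (time_s < 0) abort("time must be >= 0", class = "radyield_error_input")
  if (n == 0L) return(numeric(0))
  if (any(lambda < 0)) abort("decay constants must be >= 0",
                             class = "radyield_error_input")
  if (any(lambda[-n] == 0)) {
    abort("only the terminal chain member may be stable",
          class = "radyield_error_input")
  }
  if (time_s == 0) return(rep(0, n))
  sink <- lambda[n] == 0
  n_act <- if (sink) n - 1L else n
  if (.has_degenerate(lambda[seq_len(n_act)])) {
    return(.ode_chain(rep(0, n), lambda, source_rate, time_s))
  }
  out <- numeric(n)
  lam <- lambda[seq_len(n_act)]
  for (m in seq_len(n_act)) {
    terms <- vapply(seq_len(m), function(j) {
      others <- lam[seq_len(m)][-j]
      -expm1(-lam[j] * time_s) *
        prod(others / (others - lam[j]))
    }, numeric(1))
    out[m] <- source_rate / lam[m] * sum(terms)
  }
  if (sink) out[n] <- source_rate * time_s - sum(out[seq_len(n_act)])
  if (n_act == 0L) out[n] <- source_rate * time_s
  out
}

#' Closed-form chain decay after irradiation
#'
#' Decays an end-of-irradiation chain state with in-growth from surviving
#' precursors,
#' \deqn{N_m(\tau) = \frac{1}{\lambda_m}\sum_{j=1}^{m} N'_j
#'   \sum_{k=j}^{m}\lambda_k e^{-\lambda_k\tau}
#'   \prod_{l=j,\,l\ne k}^{m}\lambda_l(\lambda_l-\lambda_k)^{-1},}
#' where \eqn{N'_j} are the member inventories when the beam stops.  A
#' terminal stable sink is filled by atom conservation; near-degenerate
#' decay constants fall back to the ODE route.
#'
#' @param n_init Atom counts at the end of irradiation, one per member.
#' @param lambda Decay constants (1/s), as in [bateman_during()].
#' @param time_s Cooling time, s.
#' @return Numeric vector of atom counts after `time_s`.
#' @export
bateman_decay <- function(n_init, lambda, time_s) {
  n <- length(lambda)
  stopifnot(length(n_init) == n)
  if (time_s < 0) abort("time must be >= 0", class = "radyield_error_input")
  if (time_s == 0 || n == 0L) return(n_init)
  if (any(lambda[-n] == 0)) {
    abort("only the terminal chain member may be stable",
          class = "radyield_error_input")
  }
  sink <- lambda[n] == 0
  n_act <- if (sink) n - 1L else n
  if (.has_degenerate(lambda[seq_len(n_act)])) {
    return(.ode_chain(n_init, lambda, 0, time_s))
  }
  out <- numeric(n)
  lam <- lambda[seq_len(n_act)]
  for (m in seq_len(n_act)) {
    acc <- 0
    for (j in seq_len(m)) {
      idx <- j:m
      ks <- vapply(idx, function(k) {
        others <- lam[setdiff(idx, k)]
        lam[k] * exp(-lam[k] * time_s) *
          prod(others / (others - lam[k]))
      }, numeric(1))
      acc <- acc + n_init[j] * sum(ks)
    }
    out[m] <- acc / lam[m]
  }
  if (sink) out[n] <- sum(n_init[seq_len(n)]) - sum(out[seq_len(n_act)])
  out
}

#' Exponential target depletion
#'
#' Survival of the target nuclide under a constant burn-up reaction
#' probability: \eqn{N(t) = N_0\,e^{-\phi\langle\sigma\rangle^* t}}.
#'
#' @param n0_atoms Initial atom count.
#' @param depletion_const_per_s Per-atom burn-up probability
#'   \eqn{\phi\langle\sigma\rangle^*_T} in 1/s (the burn-up rate divided by
#'   the initial atom count).
#' @param time_s Irradiation time, s.
#' @return Remaining atoms.
#' @export
target_depletion <- function(n0_atoms, depletion_const_per_s, time_s) {
  if (any(c(n0_atoms, depletion_const_per_s, time_s) < 0)) {
    abort("all arguments must be >= 0", class = "radyield_error_input")
  }
  n0_atoms * exp(-depletion_const_per_s * time_s)
}

# routes ---------------------------------------------------------------------

#' Define a production-decay route
#'
#' One reaction's contribution to the inventory: a constant production rate
#' feeding a linear decay chain (produced member first).  The overall
#' inventory of an isotope is the sum of its contributions over all routes.
#'
#' @param nuclides Character vector of nuclide ids in decay order, e.g.
#'   `c("yb177", "lu177g")` for the indirect route.
#' @param source_rate Production rate into the first member, atoms/s.
#' @param name Route label; defaults to the nuclide path.
#' @return An object of class `ry_route`.
#' @export
decay_route <- function(nuclides, source_rate, name = NULL) {
  lam <- decay_constant(nuclides)
  structure(list(name = name %||% paste(nuclides, collapse = " -> "),
                 nuclides = nuclides, lambda = unname(lam),
                 source_rate = source_rate),
            class = "ry_route")
}

#' @export
print.ry_route <- function(x, ...) {
  cat(sprintf("<route %s>  source %.4g atoms/s\n", x$name, x$source_rate))
  invisible(x)
}

.as_route_list <- function(routes) {
  if (inherits(routes, "ry_route")) list(routes) else routes
}

.inventory_from_states <- function(states, time_s, phase, cool_s = 0) {
  if (length(states) == 0L) {
    inv <- tibble(nuclide = character(0), atoms = numeric(0))
  } else {
    inv <- purrr::map(states, function(st) {
      tibble(nuclide = st$route$nuclides, atoms = st$n)
    }) |>
      dplyr::bind_rows() |>
      dplyr::group_by(.data$nuclide) |>
      dplyr::summarise(atoms = sum(.data$atoms), .groups = "drop")
  }
  structure(inv, class = c("ry_inventory", class(inv)),
            time_s = time_s, cool_s = cool_s, phase = phase,
            states = states)
}

#' Inventory during irradiation
#'
#' Evaluates every route's chain with [bateman_during()] at time `time` and
#' sums contributions per nuclide.
#'
#' @param routes An [decay_route()] or a list of them.
#' @param time Irradiation duration.
#' @param unit Time unit (`"s"`, `"min"`, `"h"`, `"d"`, `"y"`).
#' @return A tibble of class `ry_inventory` with columns `nuclide`, `atoms`
#'   and attributes `time_s`, `phase` and the per-route states needed by
#'   [inventory_post_irradiation()].
#' @export
inventory_during_irradiation <- function(routes, time, unit = "s") {
  routes <- .as_route_list(routes)
  t_s <- to_seconds(time, unit)
  states <- purrr::map(routes, function(r) {
    n <- bateman_during(r$lambda, r$source_rate, t_s)
    list(route = r, n = n,
         decayed_out = r$source_rate * t_s - sum(n))
  })
  .inventory_from_states(states, t_s, "irradiating")
}

#' Inventory after a cooling / processing period
#'
#' Decays an end-of-irradiation inventory for `time` with in-growth from
#' surviving precursors ([bateman_decay()] per route).
#'
#' @param inv An `ry_inventory` from [inventory_during_irradiation()].
#' @param time Cooling duration.
#' @param unit Time unit.
#' @return A tibble of class `ry_inventory`, phase `"cooling"`.
#' @export
inventory_post_irradiation <- function(inv, time, unit = "s") {
  tau <- to_seconds(time, unit)
  states <- attr(inv, "states")
  if (is.null(states)) abort("inventory carries no route states",
                             class = "radyield_error_input")
  states <- purrr::map(states, function(st) {
    n <- bateman_decay(st$n, st$route$lambda, tau)
    st$decayed_out <- st$decayed_out + sum(st$n) - sum(n)
    st$n <- n
    st
  })
  .inventory_from_states(states, attr(inv, "time_s"), "cooling",
                         cool_s = attr(inv, "cool_s") + tau)
}

#' Sum inventories over production routes
#'
#' Per-isotope sums over all contributing reactions (e.g. the (d,p) plus
#' beta-decay route and the direct (d,n) route for the same product).  An
#' empty route set gives a zero inventory.
#'
#' @param invs A list of `ry_inventory` objects sharing the same schedule.
#' @return A combined `ry_inventory`.
#' @export
combine_routes <- function(invs) {
  if (length(invs) == 0L) return(.inventory_from_states(list(), 0, "irradiating"))
  states <- unlist(lapply(invs, attr, "states"), recursive = FALSE)
  .inventory_from_states(states, attr(invs[[1L]], "time_s"),
                         attr(invs[[1L]], "phase"),
                         cool_s = attr(invs[[1L]], "cool_s"))
}

#' @export
print.ry_inventory <- function(x, ...) {
  cat(sprintf("<inventory>  %s, t = %.4g s irradiation", attr(x, "phase"),
              attr(x, "time_s")))
  if (attr(x, "cool_s") > 0) cat(sprintf(" + %.4g s cooling", attr(x, "cool_s")))
  cat("\n")
  print(as_tibble(x))
  invisible(x)
}

# reporting ------------------------------------------------------------------

#' Yield report: atoms, mass, activity, radiopurity
#'
#' For the requested nuclide set, tabulates atom counts, masses
#' (\eqn{m = N M / N_A}), activities (\eqn{\alpha = \lambda N}) and
#' radionuclidic purities (each nuclide's activity as a percentage of the
#' set's total activity; the column sums to 100).
#'
#' @param inv An `ry_inventory`.
#' @param nuclides Nuclide ids to report; default: every radioactive nuclide
#'   present.  Stable nuclides may be requested; they report zero activity.
#' @return A tibble with columns `nuclide`, `atoms`, `mass_mg`,
#'   `activity_gbq`, `radiopurity_pct`.
#' @export
yield_report <- function(inv, nuclides = NULL) {
  nd <- nuclide_data()
  df <- as_tibble(inv)[, c("nuclide", "atoms")]
  if (is.null(nuclides)) {
    nuclides <- df$nuclide[df$nuclide %in% nd$nuclide[!nd$stable]]
  }
  missing <- setdiff(nuclides, df$nuclide)
  if (length(missing)) {
    df <- dplyr::bind_rows(df, tibble(nuclide = missing, atoms = 0))
  }
  out <- df |>
    dplyr::filter(.data$nuclide %in% nuclides) |>
    dplyr::left_join(nd[, c("nuclide", "molar_mass_gmol", "lambda_per_s",
                            "stable")], by = "nuclide")
  if (any(out$stable)) {
    rlang::inform(paste0("stable nuclide(s) reported with zero activity: ",
                         paste(out$nuclide[out$stable], collapse = ", ")))
  }
  out <- out |>
    dplyr::mutate(
      mass_mg = .data$atoms * .data$molar_mass_gmol / .codata$n_avogadro * 1e3,
      activity_gbq = .data$lambda_per_s * .data$atoms / 1e9) |>
    dplyr::mutate(radiopurity_pct = if (sum(.data$activity_gbq) > 0) {
      100 * .data$activity_gbq / sum(.data$activity_gbq)
    } else 0) |>
    dplyr::select("nuclide", "atoms", "mass_mg", "activity_gbq",
                  "radiopurity_pct")
  out[match(nuclides, out$nuclide), ]
}

#' Specific activity of a reference isotope
#'
#' Two conventions are supported: `basis = "radionuclide"` divides the
#' reference isotope's activity by the summed mass of the co-produced
#' radioactive set; `basis = "element"` divides by the total mass of the
#' reference element in the inventory, including stable and effectively
#' stable co-products -- the figure that matters once carrier isotopes
#' dilute the product.
#'
#' @param inv An `ry_inventory`.
#' @param reference Reference nuclide id (default `"lu177g"`).
#' @param basis `"element"` (default) or `"radionuclide"`.
#' @param nuclides Radionuclide set for the `"radionuclide"` basis; default
#'   as in [yield_report()].
#' @return Specific activity in GBq/mg.
#' @export
specific_activity <- function(inv, reference = "lu177g",
                              basis = c("element", "radionuclide"),
                              nuclides = NULL) {
  basis <- match.arg(basis)
  nd <- nuclide_data()
  df <- as_tibble(inv)[, c("nuclide", "atoms")]
  ref <- .nuclide(reference)
  ref_atoms <- sum(df$atoms[df$nuclide == reference])
  act_gbq <- ref$lambda_per_s * ref_atoms / 1e9
  mass_mg <- function(ids) {
    sub <- df[df$nuclide %in% ids, ]
    mm <- nd$molar_mass_gmol[match(sub$nuclide, nd$nuclide)]
    sum(sub$atoms * mm / .codata$n_avogadro * 1e3)
  }
  denom <- if (basis == "radionuclide") {
    set <- nuclides %||% df$nuclide[df$nuclide %in% nd$nuclide[!nd$stable]]
    mass_mg(set)
  } else {
    mass_mg(nd$nuclide[nd$element == ref$element])
  }
  act_gbq / denom
}

# the standard lutetium-177 production network -------------------------------

.lu177_route_map <- function() {
  tibble::tribble(
    ~reaction,     ~chain,
    "dp_yb177",    list(c("yb177", "lu177g")),
    "dn_lu177g",   list("lu177g"),
    "dng_lu177m",  list("lu177m"),
    "d2ng_lu176m", list("lu176m"),
    "d2n_lu176g",  list("lu176g"),
    "d3n_lu175",   list("lu175"),
    "d4ng_lu174m", list("lu174m"),
    "d4n_lu174g",  list("lu174g")
  )
}

#' Build the lutetium-177 production route set
#'
#' Maps a table of reaction rates onto the standard linear routes of the
#' network: the indirect (d,p) route through 177Yb beta decay, the direct
#' (d,n) route, the isomer and contaminant channels, and the stable /
#' long-lived co-products that only matter for element-basis specific
#' activity.  Reactions absent from `rates` are skipped; non-production
#' entries (non-elastic, burn-up) are ignored.
#'
#' @param rates A data frame with columns `reaction` and `rate_atoms_per_s`
#'   (e.g. from [reaction_rates()] or [lu177_reference_rates()]), or a named
#'   numeric vector.
#' @return A named list of [decay_route()]s.
#' @export
lu177_routes <- function(rates) {
  if (is.numeric(rates) && !is.null(names(rates))) {
    rates <- tibble(reaction = names(rates), rate_atoms_per_s = unname(rates))
  }
  map <- .lu177_route_map()
  rates <- as_tibble(rates)[, c("reaction", "rate_atoms_per_s")]
  rates <- rates[rates$reaction %in% map$reaction, ]
  routes <- purrr::pmap(rates, function(reaction, rate_atoms_per_s) {
    chain <- map$chain[[match(reaction, map$reaction)]][[1L]]
    decay_route(chain, rate_atoms_per_s, name = reaction)
  })
  setNames(routes, rates$reaction)
}
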