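# Flux balance analysis and flux variability analysis on small networks,
# following the study's procedure: fix the measured growth rate, minimize
# substrate uptake, calibrate the maintenance (NGAM) flux against the
# measured uptake, then bracket every flux with FVA at the fixed optimum.

# Internal LP front end.  Solves
#   optimize  obj' v   s.t.  S v = 0,  extra_A v = extra_b,  lb <= v <= ub
# with the package's bounded-variable simplex (lp_bounded_simplex).
solve_lp <- function(obj, S, lb, ub, extra_A = NULL, extra_b = NULL,
                     maximize = FALSE) {
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("all flux bounds must be finite", call. = FALSE)
  }
  Aeq <- S
  beq <- numeric(nrow(S))
  if (!is.null(extra_A)) {
    Aeq <- rbind(Aeq, extra_A)
    beq <- c(beq, extra_b)
  }
  res <- lp_bounded_simplex(obj, Aeq, beq, unname(lb), unname(ub),
                            maximize = maximize)
  list(status = res$status, fluxes = res$x, objective = res$objective)
}

#' Solve a flux balance analysis problem
#'
#' Linear programming over the steady-state flux cone: optimize the flux
#' through `objective_reaction` subject to `S v = 0`, the network's bounds,
#' and optional fixed-flux constraints.
#'
#' @param network a [metabolic_network()].
#' @param objective_reaction reaction id to optimize (default: the biomass
#'   reaction).
#' @param sense `"max"` or `"min"`.
#' @param fixed optional named numeric vector of fluxes to fix exactly
#'   (e.g. `c(R_biomass = 0.2)`).
#' @return An object of class `"flux_distribution"`: list with `fluxes`
#'   (named), `objective`, `objective_reaction`, `status` (`"optimal"`,
#'   `"infeasible"`, or `"not_converged"`).  Infeasibility is reported in
#'   `status`, never as silent zeros.
#' @export
solve_fba <- function(network, objective_reaction = network$biomass,
                      sense = c("max", "min"), fixed = NULL) {
  sense <- match.arg(sense)
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(objective_reaction)) {
    stop("no objective reaction given and no biomass designated",
         call. = FALSE)
  }
  j <- match(objective_reaction, network$rxns)
  if (is.na(j)) stop("unknown objective reaction: ", objective_reaction,
                     call. = FALSE)
  obj <- numeric(length(network$rxns))
  obj[j] <- 1
  extra_A <- NULL
  extra_b <- NULL
  if (!is.null(fixed)) {
    idx <- match(names(fixed), network$rxns)
    if (anyNA(idx)) stop("unknown reaction in `fixed`: ",
                         paste(names(fixed)[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    extra_A <- matrix(0, length(fixed), length(network$rxns))
    extra_A[cbind(seq_along(idx), idx)] <- 1
    extra_b <- as.numeric(fixed)
  }
  res <- solve_lp(obj, network$S, network$lb, network$ub,
                  extra_A, extra_b, maximize = sense == "max")
  if (res$status == "optimal") names(res$fluxes) <- network$rxns
  structure(list(fluxes = res$fluxes, objective = res$objective,
                 objective_reaction = objective_reaction,
                 sense = sense, status = res$status, fixed = fixed),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("FBA solution (%s %s): status %s", x$sense,
              x$objective_reaction, x$status))
  if (x$status == "optimal") cat(sprintf(", objective %.6g", x$objective))
  cat("\n")
  if (!is.null(x$fluxes)) print(round(x$fluxes, 6))
  invisible(x)
}

#' Minimize substrate uptake at a measured growth rate
#'
#' Fixes the biomass flux to the experimentally measured growth rate and
#' minimizes the flux through the substrate uptake reaction.
#'
#' @param network a [metabolic_network()] with a designated biomass
#'   reaction.
#' @param growth_rate_measured measured specific growth rate (biomass flux
#'   units).
#' @param substrate uptake reaction to minimize (default: the network's
#'   first designated uptake).
#' @return A `"flux_distribution"` (status `"infeasible"` when the growth
#'   rate is unattainable at any uptake).
#' @export
minimize_substrate_uptake <- function(network, growth_rate_measured,
                                      substrate = network$uptakes[1]) {
  if (is.null(network$biomass)) {
    stop("network has no designated biomass reaction", call. = FALSE)
  }
  if (is.na(substrate) || is.null(substrate)) {
    stop("no substrate uptake reaction given", call. = FALSE)
  }
  solve_fba(network, objective_reaction = substrate, sense = "min",
            fixed = stats::setNames(growth_rate_measured, network$biomass))
}

#' Calibrate the NGAM parameter against a measured uptake
#'
#' Adjusts the non-growth-associated maintenance flux so that the
#' growth-constrained minimal substrate uptake matches the measured uptake
#' (bisection to `tol` relative).  The calibrated value is intended to be
#' reused across conditions.
#'
#' @inheritParams minimize_substrate_uptake
#' @param uptake_measured measured substrate uptake rate; must be at least
#'   the minimal uptake at NGAM = 0.
#' @param tol relative tolerance of the match.
#' @param ngam_max upper limit of the search.
#' @return The calibrated NGAM value (numeric scalar) with attribute
#'   `"uptake"` (the minimized uptake at that value).
#' @export
calibrate_ngam <- function(network, growth_rate_measured, uptake_measured,
                           substrate = network$uptakes[1], tol = 1e-6,
                           ngam_max = 1e4) {
  if (is.null(network$ngam)) {
    stop("network has no designated NGAM reaction", call. = FALSE)
  }
  uptake_at <- function(ngam) {
    sol <- minimize_substrate_uptake(set_ngam(network, ngam),
                                     growth_rate_measured, substrate)
    if (sol$status != "optimal") return(NA_real_)
    sol$objective
  }
  u0 <- uptake_at(0)
  if (!is.finite(u0)) {
    stop("growth rate infeasible even at NGAM = 0", call. = FALSE)
  }
  scale <- max(abs(uptake_measured), 1e-12)
  if (uptake_measured < u0 - tol * scale) {
    stop(sprintf(paste0("calibration infeasible: measured uptake %.6g is ",
                        "below the NGAM = 0 minimum %.6g"),
                 uptake_measured, u0), call. = FALSE)
  }
  if (abs(uptake_measured - u0) <= tol * scale) {
    return(structure(0, uptake = u0))
  }
  hi <- 1
  while (hi < ngam_max) {
    uh <- uptake_at(hi)
    if (!is.finite(uh)) { hi <- hi / 2; break }
    if (uh >= uptake_measured) break
    hi <- hi * 2
  }
  if (!is.finite(uptake_at(hi)) || uptake_at(hi) < uptake_measured) {
    stop("could not bracket the measured uptake within the NGAM search ",
         "range", call. = FALSE)
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    um <- uptake_at(mid)
    if (!is.finite(um) || um > uptake_measured) hi <- mid else lo <- mid
    if (is.finite(um) && abs(um - uptake_measured) <= tol * scale) {
      return(structure(mid, uptake = um))
    }
    if (hi - lo < 1e-14 * max(1, hi)) break
  }
  structure((lo + hi) / 2, uptake = uptake_at((lo + hi) / 2))
}

#' Flux variability analysis
#'
#' With the objective fixed at its optimal value, computes the attainable
#' minimum and maximum of every reaction's flux; narrow ranges show that
#' alternate optima with a different flux pattern are excluded.
#'
#' @param network a [metabolic_network()].
#' @param solution the `"flux_distribution"` whose objective is fixed
#'   (default: growth-maximizing FBA).
#' @param reactions reaction ids to scan (default: all).
#' @return An object of class `"fva_result"`: data frame with columns
#'   `reaction`, `nominal`, `min`, `max`, `rel_range_percent` (the latter
#'   via [fva_relative_range()], `NA` where the nominal flux is 0).
#' @export
fva <- function(network, solution = solve_fba(network),
                reactions = network$rxns) {
  if (solution$status != "optimal") {
    stop("FVA needs an optimal FBA solution (status: ", solution$status,
         ")", call. = FALSE)
  }
  # fix the optimum plus every constraint the original problem carried
  fix <- stats::setNames(solution$objective, solution$objective_reaction)
  extra <- solution$fixed[setdiff(names(solution$fixed), names(fix))]
  fix <- c(fix, extra)
  rows <- lapply(reactions, function(rid) {
    lohi <- vapply(c("min", "max"), function(sense) {
      sol <- solve_fba(network, objective_reaction = rid, sense = sense,
                       fixed = fix)
      if (sol$status != "optimal") {
        stop("FVA LP failed for reaction ", rid, " (", sense, "): ",
             sol$status, call. = FALSE)
      }
      sol$objective
    }, numeric(1))
    data.frame(reaction = rid, nominal = unname(solution$fluxes[rid]),
               min = lohi[["min"]], max = lohi[["max"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rel_range_percent <- suppressWarnings(
    fva_relative_range(out$nominal, out$min, out$max))
  class(out) <- c("fva_result", "data.frame")
  out
}

# round half away from zero (the convention behind the printed FVA
# percentage summaries; R's round() would give 1.2 for 1.25)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Relative FVA range in percent
#'
#' The deviation between the minimal and maximal flux relative to the
#' nominal value, `100 * (max - min) / nominal`, rounded half-up to one
#' decimal (the summary convention of the flux variability tables).
#'
#' @param nominal,vmin,vmax numeric vectors of nominal, minimal and
#'   maximal fluxes.
#' @return Percentages rounded to one decimal; `NA` (with a warning) where
#'   `nominal == 0`.
#' @examples
#' fva_relative_range(6.32, 6.18, 6.35)  # 2.7
#' @export
fva_relative_range <- function(nominal, vmin, vmax) {
  out <- 100 * (vmax - vmin) / nominal
  undef <- nominal == 0
  if (any(undef)) {
    warning("relative range undefined for zero nominal flux",
            call. = FALSE)
    out[undef] <- NA_real_
  }
  round_half_up(out, 1)
}
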