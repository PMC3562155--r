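# Steady-state phosphoryl flux split between the two PTS branches for the
# wild type growing on CAA plus fructose.

#' Steady-state branch fluxes and the Ntr share
#'
#' Solves the wild-type steady state for a thermodynamically closed
#' parameter set with fructose uptake `r_fru` and returns all net rates
#' together with the share of the uptake flux supplied by each branch.  At
#' steady state the chain carries one common flux (`r1 = r2 = r3 = -r5`)
#' which is delivered to FruB by cross talk, and the C branch supplies the
#' rest directly from PEP (`r3 + r4 = r_fru`).  The Ntr share is
#' `r3/r_fru`, the C share `r4/r_fru`.
#'
#' @param params a thermodynamically closed [pts_parameters()] object.
#' @param pp PEP/pyruvate ratio (defaults to `params$pp`).
#' @param r_fru scaled fructose uptake rate (defaults to `params$r_fru`).
#' @return An object of class `"branch_flux_result"`: a list with `rates`
#'   (named vector `r1..r5, r_fru`), `state` (the steady [pts_state()]),
#'   `ntr_share`, `c_share` (both `NA` with `shares_defined = FALSE` when
#'   `r_fru = 0`).
#' @examples
#' res <- steady_branch_fluxes(default_pts_parameters(), pp = 0.49,
#'                             r_fru = 0.05)
#' res$ntr_share
#' @export
steady_branch_fluxes <- function(params, pp = NULL, r_fru = NULL) {
  if (!is.null(pp)) params$pp <- pp
  if (!is.null(r_fru)) params$r_fru <- r_fru
  validate_pts_parameters(params)
  if (!is_thermo_closed(params, tol = 1e-6)) {
    stop("steady_branch_fluxes expects a thermodynamically closed ",
         "parameter set (K1*K2*K3 = K4*K5)", call. = FALSE)
  }
  geno <- strain_genotype("WT")
  st <- tryCatch(steady_state(params, geno),
                 error = function(e) {
                   stop("branch-flux solve failed (is r_fru larger than ",
                        "the maximal transferable flux?): ",
                        conditionMessage(e), call. = FALSE)
                 })
  r <- reaction_rates(st, params, geno)
  out <- list(rates = r, state = st)
  if (params$r_fru > 0) {
    out$ntr_share <- unname(r[["r3"]] / params$r_fru)
    out$c_share <- unname(r[["r4"]] / params$r_fru)
    out$shares_defined <- TRUE
  } else {
    out$ntr_share <- NA_real_
    out$c_share <- NA_real_
    out$shares_defined <- FALSE
  }
  structure(out, class = "branch_flux_result")
}

#' @export
print.branch_flux_result <- function(x, ...) {
  cat("PTS branch flux decomposition\n")
  print(round(x$rates, 6))
  if (x$shares_defined) {
    cat(sprintf("  Ntr share (r3/r_fru): %.4f   C share (r4/r_fru): %.4f\n",
                x$ntr_share, x$c_share))
  } else {
    cat("  shares undefined (r_fru = 0)\n")
  }
  invisible(x)
}

#' Share of fructose phosphorylation supplied by the Ntr branch
#'
#' `r3/r_fru` (equivalently `-r5/r_fru`) from a [steady_branch_fluxes()]
#' result.
#'
#' @param result a `"branch_flux_result"`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
ntr_share <- function(result) {
  stopifnot(inherits(result, "branch_flux_result"))
  if (!result$shares_defined) {
    stop("the branch share is undefined when r_fru = 0", call. = FALSE)
  }
  result$ntr_share
}

#' Quasi-equilibrium phosphorylated fraction of FruB
#'
#' With the fitted constants the cross talk forces a very small
#' `K4 = Keq/K5`, i.e. a high PEP affinity of FruB; at r4-equilibrium the
#' phosphorylated fraction is `(pp/K4) / (1 + pp/K4)`, which for the
#' reported constants exceeds 99% — leaving little unphosphorylated FruB
#' and keeping the direct flux `r4` low.
#'
#' @param Keq overall equilibrium constant.
#' @param K5 cross-talk equilibrium constant.
#' @param pp PEP/pyruvate ratio.
#' @return The equilibrium phosphorylated fraction of FruB in `[0, 1]`.
#' @examples
#' fruB_quasi_equilibrium_fraction(0.02, 654.6, 0.49)
#' @export
fruB_quasi_equilibrium_fraction <- function(Keq, K5, pp) {
  stopifnot(Keq > 0, K5 > 0, pp > 0)
  K4 <- Keq / K5
  q <- pp / K4
  q / (1 + q)
}

#' Rescale relative fluxes to absolute units
#'
#' The relay is solved in scaled units (protein totals of 1, a chosen time
#' constant); converting to absolute fluxes multiplies each rate by the
#' reference concentration/time factor of its carrier.  A pure unit
#' conversion; [unscale_fluxes()] is its inverse.
#'
#' @param scaled_fluxes named numeric vector of scaled rates.
#' @param reference named numeric vector of positive reference factors, one
#'   per entry of `scaled_fluxes`.
#' @return Named numeric vector of absolute fluxes.
#' @export
rescale_fluxes <- function(scaled_fluxes, reference) {
  missing <- setdiff(names(scaled_fluxes), names(reference))
  if (length(missing) > 0) {
    stop("missing reference entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- reference[names(scaled_fluxes)]
  if (any(ref <= 0)) stop("reference factors must be > 0", call. = FALSE)
  scaled_fluxes * ref
}

#' @rdname rescale_fluxes
#' @param absolute_fluxes named numeric vector of absolute fluxes.
#' @export
unscale_fluxes <- function(absolute_fluxes, reference) {
  missing <- setdiff(names(absolute_fluxes), names(reference))
  if (length(missing) > 0) {
    stop("missing reference entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- reference[names(absolute_fluxes)]
  if (any(ref <= 0)) stop("reference factors must be > 0", call. = FALSE)
  absolute_fluxes / ref
}
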