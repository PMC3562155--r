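# Two-point power-law characterization of the PEP/pyruvate node.
#
# The node is reduced to five lumped fluxes: input ra (via oxaloacetate),
# lumped pyruvate drain rb, pyruvate -> PEP (PEP synthase) rc, and
# PEP -> upper glycolysis rd, with rb linearly interpolated between
# conditions (slope k = d rb / d ra).  Steady state forces rc = rd and
# rc = (1 - k) * ra.  Power-law kinetics rc = kc * Pyr^nc, rd = kd * PEP^nd
# give the PEP/pyruvate ratio pp = alpha^(1/nd) * (rc/kc)^n' with
# alpha = kc/kd and n' = 1/nd - 1/nc; two (rc, pp) calibration points then
# determine alpha and n' (hence kd, nd) exactly once kc = nc = 1 is fixed
# (only the comparison between the two enzymes is of interest).

#' Fit power-law kinetics through two operating points
#'
#' Solves `pp_i = alpha^(1/nd) * (rc_i/kc)^(n')`, `n' = 1/nd - 1/nc`,
#' exactly through two `(rc, pp)` points with the PEP-synthase parameters
#' fixed (`kc = 1`, `nc = 1` by convention).
#'
#' @param point1,point2 numeric length-2 vectors `c(rc, pp)`: a flux
#'   through the pyruvate -> PEP reaction and the corresponding
#'   PEP/pyruvate ratio.
#' @param kc,nc PEP-synthase constants (normalization convention).
#' @return An object of class `"powerlaw_fit"`: list with `kc`, `nc`,
#'   `kd`, `nd`, `alpha = kc/kd`, `n_prime = 1/nd - 1/nc`.
#' @examples
#' fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
#' @export
fit_powerlaw_two_points <- function(point1, point2, kc = 1, nc = 1) {
  stopifnot(length(point1) == 2, length(point2) == 2)
  rc <- c(point1[1], point2[1])
  pp <- c(point1[2], point2[2])
  if (any(rc <= 0) || any(pp <= 0) || kc <= 0 || nc <= 0) {
    stop("fluxes, ratios and constants must be positive", call. = FALSE)
  }
  if (rc[1] == rc[2]) {
    stop("degenerate fit: the two rc values must differ", call. = FALSE)
  }
  n_prime <- log(pp[1] / pp[2]) / log(rc[1] / rc[2])
  if (n_prime + 1 / nc <= 0) {
    stop("no positive exponent nd solves these points (n' = ",
         signif(n_prime, 4), ")", call. = FALSE)
  }
  nd <- 1 / (n_prime + 1 / nc)
  log_alpha <- nd * (log(pp[1]) - n_prime * log(rc[1] / kc))
  alpha <- exp(log_alpha)
  structure(list(kc = kc, nc = nc, kd = kc / alpha, nd = nd,
                 alpha = alpha, n_prime = n_prime),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("power-law fit of the PEP/pyruvate node\n")
  cat(sprintf("  PEP synthase (rc):     kc = %.4g  nc = %.4g (fixed)\n",
              x$kc, x$nc))
  cat(sprintf("  gluconeogenetic (rd):  kd = %.4g  nd = %.4g\n",
              x$kd, x$nd))
  cat(sprintf("  alpha = kc/kd = %.4g   n' = 1/nd - 1/nc = %.4g\n",
              x$alpha, x$n_prime))
  invisible(x)
}

#' Steady state of the reduced node
#'
#' For an input flux `ra` and drain slope `k`, the balanced flux is
#' `rc = rd = (1 - k) * ra`; inverting the power laws gives
#' `Pyr = (rc/kc)^(1/nc)`, `PEP = (rc/kd)^(1/nd)` and the ratio
#' `pp = PEP/Pyr`.
#'
#' @param ra input flux (vectorized).
#' @param k drain slope, `0 <= k < 1`.
#' @param fit a `"powerlaw_fit"`.
#' @return A data frame with columns `ra`, `rc`, `PEP`, `Pyr`, `pp`.
#' @export
reduced_steady_state <- function(ra, k, fit) {
  if (k >= 1 || k < 0) {
    stop("no steady state: the drain slope k must lie in [0, 1)",
         call. = FALSE)
  }
  rc <- (1 - k) * ra
  if (any(rc <= 0)) stop("(1 - k) * ra must be positive", call. = FALSE)
  Pyr <- (rc / fit$kc)^(1 / fit$nc)
  PEP <- (rc / fit$kd)^(1 / fit$nd)
  data.frame(ra = ra, rc = rc, PEP = PEP, Pyr = Pyr, pp = PEP / Pyr)
}

#' Does the PEP/pyruvate ratio increase with the input flux?
#'
#' The necessary condition for a positive slope of `pp(ra)` under the
#' power-law kinetics is `nc/nd > 1`.
#'
#' @param nc,nd positive exponents.
#' @return Logical scalar.
#' @export
monotonicity_condition <- function(nc, nd) {
  stopifnot(nc > 0, nd > 0)
  nc / nd > 1
}

#' Characteristic curve of the node with a slope-uncertainty band
#'
#' Evaluates `pp(ra)` at a nominal drain slope and brackets it with the
#' envelope over a slope range (the extreme slopes consistent with the
#' flux variability of the underlying flux table).
#'
#' @param fit a `"powerlaw_fit"`.
#' @param k_nominal nominal drain slope.
#' @param k_range length-2 vector `c(k_min, k_max)`.
#' @param ra_grid positive input-flux grid.
#' @return A data frame with columns `ra`, `pp`, `pp_lo`, `pp_hi`.
#' @export
characteristic_curve <- function(fit, k_nominal, k_range, ra_grid) {
  if (any(ra_grid <= 0)) stop("ra_grid must be positive", call. = FALSE)
  stopifnot(length(k_range) == 2, k_range[1] <= k_range[2])
  ks <- sort(unique(c(k_range, k_nominal)))
  pp_all <- vapply(ks, function(k) reduced_steady_state(ra_grid, k, fit)$pp,
                   numeric(length(ra_grid)))
  pp_all <- matrix(pp_all, nrow = length(ra_grid))
  data.frame(ra = ra_grid,
             pp = reduced_steady_state(ra_grid, k_nominal, fit)$pp,
             pp_lo = apply(pp_all, 1, min),
             pp_hi = apply(pp_all, 1, max))
}

#' Drain slope from a two-condition flux table
#'
#' The slope `k = delta rb / delta ra` between two conditions, with the
#' lumped drain closed as `rb = ra - rc` by default (the printed node
#' fluxes do not balance exactly because minor drains are not enumerated;
#' the closure preserves the reduced steady state exactly).  Alternatively
#' `rb_reaction` can name a printed drain flux (e.g. pyruvate to
#' acetyl-CoA) to use directly.
#'
#' @param flux_table data frame with columns `condition`, `reaction`,
#'   `nominal` (and optionally `min`, `max`), two conditions.
#' @param ra_reaction id of the input flux row (oxaloacetate -> pyruvate).
#' @param rc_reaction id of the pyruvate -> PEP row (used for the closure).
#' @param rb_reaction optional id of a printed drain flux; overrides the
#'   closure.
#' @param column which value column to read (default `"nominal"`).
#' @return The slope `k` (numeric scalar).
#' @examples
#' slope_k_from_conditions(node_flux_table())  # about 0.344
#' @export
slope_k_from_conditions <- function(flux_table,
                                    ra_reaction = "oaa_to_pyr",
                                    rc_reaction = "pyr_to_pep",
                                    rb_reaction = NULL,
                                    column = "nominal") {
  conds <- unique(flux_table$condition)
  if (length(conds) != 2) {
    stop("flux table must contain exactly two conditions", call. = FALSE)
  }
  val <- function(cond, rxn) {
    v <- flux_table[[column]][flux_table$condition == cond &
                                flux_table$reaction == rxn]
    if (length(v) != 1) stop("missing flux row: ", rxn, " under ", cond,
                             call. = FALSE)
    v
  }
  ra <- vapply(conds, val, numeric(1), rxn = ra_reaction)
  rb <- if (is.null(rb_reaction)) {
    ra - vapply(conds, val, numeric(1), rxn = rc_reaction)
  } else {
    vapply(conds, val, numeric(1), rxn = rb_reaction)
  }
  if (ra[1] == ra[2]) {
    stop("equal input fluxes: slope undefined", call. = FALSE)
  }
  unname((rb[1] - rb[2]) / (ra[1] - ra[2]))
}

#' @rdname slope_k_from_conditions
#' @details `slope_k_extremes()` enumerates all min/max combinations of
#'   the `ra` and `rc` flux-variability columns and returns the range of
#'   slopes they produce — the band used for the characteristic curve.
#' @return `slope_k_extremes()` returns `c(k_min, k_max)`.
#' @export
slope_k_extremes <- function(flux_table, ra_reaction = "oaa_to_pyr",
                             rc_reaction = "pyr_to_pep") {
  conds <- unique(flux_table$condition)
  if (length(conds) != 2) {
    stop("flux table must contain exactly two conditions", call. = FALSE)
  }
  val <- function(cond, rxn, col) {
    v <- flux_table[[col]][flux_table$condition == cond &
                             flux_table$reaction == rxn]
    if (length(v) != 1) stop("missing flux row: ", rxn, " under ", cond,
                             call. = FALSE)
    v
  }
  ks <- c()
  for (ra1 in c("min", "max")) for (rc1 in c("min", "max"))
    for (ra2 in c("min", "max")) for (rc2 in c("min", "max")) {
      ra <- c(val(conds[1], ra_reaction, ra1),
              val(conds[2], ra_reaction, ra2))
      rb <- ra - c(val(conds[1], rc_reaction, rc1),
                   val(conds[2], rc_reaction, rc2))
      if (ra[1] != ra[2]) ks <- c(ks, (rb[1] - rb[2]) / (ra[1] - ra[2]))
    }
  range(ks)
}

#' Published node fluxes for the two growth conditions
#'
#' The nominal FBA fluxes and FVA ranges at the PEP/pyruvate node for
#' growth on CAA and on CAA plus fructose (mmol/gDW/h): oxaloacetate ->
#' pyruvate (input), pyruvate -> acetyl-CoA (drain), pyruvate -> PEP
#' (PEP synthase) and PEP -> 2-phosphoglycerate (gluconeogenetic).  These
#' printed values are inputs to the node analysis (the genome-scale model
#' that produced them is not part of this package).
#'
#' @return A data frame with columns `condition`, `reaction`, `nominal`,
#'   `min`, `max`.
#' @export
node_flux_table <- function() {
  data.frame(
    condition = rep(c("CAA", "CAA_fructose"), each = 4),
    reaction = rep(c("oaa_to_pyr", "pyr_to_accoa", "pyr_to_pep",
                     "pep_to_2pg"), 2),
    nominal = c(6.32, 1.83, 4.00, 3.73,
                4.69, 1.47, 2.93, 2.64),
    min = c(6.18, 1.68, 3.96, 3.68,
            4.59, 1.36, 2.90, 2.61),
    max = c(6.35, 1.85, 4.01, 3.78,
            4.71, 1.49, 2.97, 2.68),
    stringsAsFactors = FALSE)
}
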