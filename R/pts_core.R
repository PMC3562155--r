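# Core forward model of the two-branch PTS phosphorelay.
#
# State variables are the phosphorylated fractions of the four PTS proteins
# (PtsP, PtsO, PtsN, FruB); the unphosphorylated pool of each protein is
# 1 - fraction times its total (conservation).  PEP and pyruvate enter only
# through their ratio `pp`: the pool is scaled to PEP + Pyr = 1, so
# PEP = pp/(1+pp) and Pyr = 1/(1+pp); velocity constants absorb the true
# pool size.

PTS_STRAINS <- c("WT", "delta_ptsP", "delta_ptsO", "delta_ptsN", "delta_fruB")
PTS_CONDITIONS <- c("CAA", "CAA_fructose", "CAA_glucose")
PTS_REACTIONS <- c("r1", "r2", "r3", "r4", "r5", "r_fru")
PTS_PROTEINS <- c("ptsP", "ptsO", "ptsN", "fruB")

#' Phosphorylation state of the PTS proteins
#'
#' Bundles the four dimensionless phosphorylated fractions (phosphorylated
#' amount over protein total).
#'
#' @param ptsP_p,ptsO_p,ptsN_p,fruB_p phosphorylated fractions in `[0, 1]`.
#' @return A named numeric vector of class `"pts_state"` with elements
#'   `ptsP_p`, `ptsO_p`, `ptsN_p`, `fruB_p`.
#' @examples
#' pts_state(0.5, 0.5, 0.5, 0.5)
#' @export
pts_state <- function(ptsP_p, ptsO_p, ptsN_p, fruB_p) {
  x <- c(ptsP_p = ptsP_p, ptsO_p = ptsO_p, ptsN_p = ptsN_p, fruB_p = fruB_p)
  validate_pts_state(x)
  structure(x, class = "pts_state")
}

validate_pts_state <- function(x) {
  if (length(x) != 4L || anyNA(x)) {
    stop("a PTS state needs four non-missing fractions", call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("phosphorylated fractions must lie in [0, 1]; got ",
         paste(signif(x, 4), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Kinetic parameters of the phosphorelay
#'
#' Velocity constants `k1`..`k5` (1/time after scaling), dimensionless
#' equilibrium constants `K1`..`K5`, protein totals, and the two system
#' inputs: the PEP/pyruvate ratio `pp` and the scaled fructose uptake rate
#' `r_fru`.
#'
#' The reaction cycle (PEP -> PtsP -> PtsO -> PtsN versus
#' PEP -> FruB -> PtsN) is thermodynamically closed when
#' `K1*K2*K3 == K4*K5`; [is_thermo_closed()] tests this.
#'
#' @param k1,k2,k3,k4,k5 non-negative velocity constants.
#' @param K1,K2,K3,K4,K5 positive equilibrium constants.
#' @param ptsP0,ptsO0,ptsN0,fruB0 non-negative protein totals (1 after
#'   scaling on each total).
#' @param pp positive PEP/pyruvate ratio.
#' @param r_fru non-negative scaled fructose uptake rate.
#' @return An object of class `"pts_parameters"` (a named list).
#' @seealso [pts_parameters_from_constants()] for the split convention used
#'   throughout the estimation code, [default_pts_parameters()] for the
#'   shipped calibration.
#' @export
pts_parameters <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1,
                           K1 = 1, K2 = 1, K3 = 1, K4 = 1, K5 = 1,
                           ptsP0 = 1, ptsO0 = 1, ptsN0 = 1, fruB0 = 1,
                           pp = 1, r_fru = 0) {
  p <- list(k = c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5),
            K = c(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5),
            totals = c(ptsP0 = ptsP0, ptsO0 = ptsO0, ptsN0 = ptsN0,
                       fruB0 = fruB0),
            pp = pp, r_fru = r_fru)
  validate_pts_parameters(p)
  structure(p, class = "pts_parameters")
}

validate_pts_parameters <- function(p) {
  if (any(p$k < 0)) stop("velocity constants must be >= 0", call. = FALSE)
  if (any(p$K <= 0)) stop("equilibrium constants must be > 0", call. = FALSE)
  if (any(p$totals < 0)) stop("protein totals must be >= 0", call. = FALSE)
  if (!is.finite(p$pp) || p$pp <= 0) {
    stop("the PEP/pyruvate ratio pp must be > 0", call. = FALSE)
  }
  if (p$r_fru < 0) stop("r_fru must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.pts_parameters <- function(x, ...) {
  cat("PTS phosphorelay parameters\n")
  cat("  k:  ", paste(sprintf("%s=%.4g", names(x$k), x$k), collapse = "  "), "\n")
  cat("  K:  ", paste(sprintf("%s=%.4g", names(x$K), x$K), collapse = "  "), "\n")
  cat("  totals:", paste(sprintf("%s=%.3g", names(x$totals), x$totals),
                         collapse = "  "), "\n")
  cat(sprintf("  pp=%.4g  r_fru=%.4g  thermodynamically closed: %s\n",
              x$pp, x$r_fru, is_thermo_closed(x)))
  invisible(x)
}

#' Is the reaction cycle thermodynamically closed?
#'
#' The two paths from PEP to PtsN share one overall equilibrium constant, so
#' closure requires `K1*K2*K3 == K4*K5`.
#'
#' @param params a [pts_parameters()] object.
#' @param tol relative tolerance on `|K1*K2*K3 - K4*K5| / (K4*K5)`.
#' @return Logical scalar.
#' @export
is_thermo_closed <- function(params, tol = 1e-9) {
  K <- params$K
  abs(K[["K1"]] * K[["K2"]] * K[["K3"]] - K[["K4"]] * K[["K5"]]) /
    (K[["K4"]] * K[["K5"]]) < tol
}

#' Build parameters from the overall and cross-talk equilibrium constants
#'
#' Applies the identifiability convention used by the fitting code: the
#' three chain constants share the cube root of the overall constant,
#' `K1 = K2 = K3 = Keq^(1/3)`, and the C branch satisfies the cycle
#' constraint exactly through `K4 = Keq/K5`.  Only products of constants
#' along equilibrium chains are identifiable from detailed-balance data, so
#' the split is a convention, not an estimate.
#'
#' @param Keq overall equilibrium constant `K1*K2*K3 = K4*K5`.
#' @param K5 cross-talk equilibrium constant (FruB~P + PtsN).
#' @param ... further arguments passed to [pts_parameters()] (velocity
#'   constants, totals, `pp`, `r_fru`).
#' @return A [pts_parameters()] object that is thermodynamically closed.
#' @export
pts_parameters_from_constants <- function(Keq, K5, ...) {
  stopifnot(Keq > 0, K5 > 0)
  pts_parameters(K1 = Keq^(1 / 3), K2 = Keq^(1 / 3), K3 = Keq^(1 / 3),
                 K4 = Keq / K5, K5 = K5, ...)
}

#' Strain genotypes and their removed reactions
#'
#' A deleted gene removes its protein's reactions entirely (their net rates
#' are identically zero): `delta_ptsP` removes `r1, r2`; `delta_ptsO`
#' removes `r2, r3`; `delta_ptsN` removes `r3, r5`; `delta_fruB` removes
#' `r4, r5, r_fru`.
#'
#' @param label one of `"WT"`, `"delta_ptsP"`, `"delta_ptsO"`,
#'   `"delta_ptsN"`, `"delta_fruB"`.
#' @return An object of class `"strain_genotype"` with fields `label` and
#'   `removed_reactions`.
#' @export
strain_genotype <- function(label = PTS_STRAINS) {
  label <- match.arg(label)
  removed <- switch(label,
    WT = character(0),
    delta_ptsP = c("r1", "r2"),
    delta_ptsO = c("r2", "r3"),
    delta_ptsN = c("r3", "r5"),
    delta_fruB = c("r4", "r5", "r_fru"))
  structure(list(label = label, removed_reactions = removed),
            class = "strain_genotype")
}

#' Growth conditions
#'
#' Encodes the environmental input to the relay: the PEP/pyruvate ratio
#' `pp`, whether the fructose (fru) operon is induced, and the scaled
#' fructose uptake rate `r_fru`.  Defaults follow the fitted values for the
#' three media: `pp = 1` on casamino acids (CAA, reference condition,
#' no uptake, operon uninduced), `pp = 0.49` on CAA plus fructose (operon
#' induced, uptake on), and `pp = 0.05` on CAA plus glucose (operon treated
#' as induced, zero uptake by default; pass `r_fru > 0` for the
#' residual-fructose variant).
#'
#' @param label one of `"CAA"`, `"CAA_fructose"`, `"CAA_glucose"`.
#' @param pp PEP/pyruvate ratio; `NULL` takes the condition default.
#' @param r_fru scaled uptake rate; `NULL` takes the condition default
#'   (0.05 for `CAA_fructose`, else 0).
#' @param fruB_induced is the fru operon induced?  `NULL` takes the default
#'   (`FALSE` only on plain CAA).
#' @return An object of class `"growth_condition"`.
#' @export
growth_condition <- function(label = PTS_CONDITIONS, pp = NULL, r_fru = NULL,
                             fruB_induced = NULL) {
  label <- match.arg(label)
  defaults <- switch(label,
    CAA          = list(pp = 1.00, r_fru = 0.00, fruB_induced = FALSE),
    CAA_fructose = list(pp = 0.49, r_fru = 0.05, fruB_induced = TRUE),
    CAA_glucose  = list(pp = 0.05, r_fru = 0.00, fruB_induced = TRUE))
  pp <- if (is.null(pp)) defaults$pp else pp
  r_fru <- if (is.null(r_fru)) defaults$r_fru else r_fru
  fruB_induced <- if (is.null(fruB_induced)) defaults$fruB_induced else fruB_induced
  if (label == "CAA" && (r_fru != 0 || isTRUE(fruB_induced))) {
    stop("on plain CAA the fru operon is uninduced and r_fru must be 0",
         call. = FALSE)
  }
  if (pp <= 0) stop("pp must be > 0", call. = FALSE)
  if (r_fru < 0) stop("r_fru must be >= 0", call. = FALSE)
  if (r_fru > 0 && !fruB_induced) {
    stop("r_fru > 0 requires an induced fru operon", call. = FALSE)
  }
  structure(list(label = label, pp = pp, r_fru = r_fru,
                 fruB_induced = fruB_induced),
            class = "growth_condition")
}

# Effective reaction removals for a genotype under a condition.  An
# uninduced fru operon leaves so little FruB that the C-branch reactions are
# kinetically frozen on the pseudo-steady-state timescale (their rates scale
# with k * fruB0 -> 0), so r4, r5 and r_fru are treated as removed for
# steady-state purposes.
effective_removed <- function(genotype, condition = NULL) {
  removed <- genotype$removed_reactions
  if (!is.null(condition) && !condition$fruB_induced) {
    removed <- union(removed, c("r4", "r5", "r_fru"))
  }
  removed
}

# Merge a growth condition's inputs into the parameter set.
apply_condition <- function(params, condition) {
  if (is.null(condition)) return(params)
  params$pp <- condition$pp
  params$r_fru <- condition$r_fru
  params
}

#' Net reaction rates of the phosphorelay
#'
#' Reversible mass-action rate law for each phosphoryl transfer,
#' `r_i = k_i * (X^P * Y - K_i * X * Y^P)` with donor/acceptor pairs
#' (PEP, PtsP), (PtsP, PtsO), (PtsO, PtsN), (PEP, FruB), (FruB, PtsN).
#' Reactions removed by the genotype (or a frozen, uninduced fru operon)
#' return exactly 0; `r_fru` is the externally imposed uptake rate.
#'
#' @param state a [pts_state()] (or numeric vector of the four fractions).
#' @param params a [pts_parameters()] object.
#' @param genotype a [strain_genotype()].
#' @param condition optional [growth_condition()]; supplies `pp`/`r_fru` and
#'   the induction flag.
#' @return Named numeric vector `r1..r5, r_fru` of net rates (1/time).
#' @examples
#' p <- pts_parameters(pp = 1)
#' reaction_rates(pts_state(0, 0, 0, 0), p, strain_genotype("WT"))
#' @export
reaction_rates <- function(state, params, genotype = strain_genotype("WT"),
                           condition = NULL) {
  validate_pts_state(state)
  validate_pts_parameters(params)
  params <- apply_condition(params, condition)
  removed <- effective_removed(genotype, condition)
  k <- params$k; K <- params$K; tot <- params$totals
  PEP <- params$pp / (1 + params$pp)
  Pyr <- 1 / (1 + params$pp)
  xp <- unname(as.numeric(state) * tot)        # phosphorylated pools
  x0 <- unname((1 - as.numeric(state)) * tot)  # unphosphorylated pools
  r <- c(
    r1 = k[["k1"]] * (PEP * x0[1] - K[["K1"]] * Pyr * xp[1]),
    r2 = k[["k2"]] * (xp[1] * x0[2] - K[["K2"]] * x0[1] * xp[2]),
    r3 = k[["k3"]] * (xp[2] * x0[3] - K[["K3"]] * x0[2] * xp[3]),
    r4 = k[["k4"]] * (PEP * x0[4] - K[["K4"]] * Pyr * xp[4]),
    r5 = k[["k5"]] * (xp[4] * x0[3] - K[["K5"]] * x0[4] * xp[3]),
    r_fru = params$r_fru)
  r[intersect(removed, names(r))] <- 0
  r
}

#' Time derivatives of the phosphorylated fractions
#'
#' The balance of each protein's phosphorylated pool, divided by its total:
#' `d(ptsP_p)/dt = (r1 - r2)/ptsP0`, `d(ptsO_p)/dt = (r2 - r3)/ptsO0`,
#' `d(ptsN_p)/dt = (r3 + r5)/ptsN0`,
#' `d(fruB_p)/dt = (r4 - r5 - r_fru)/fruB0`.  A protein with total 0 has its
#' derivative pinned to 0 (with a warning if the rate imbalance is nonzero).
#'
#' @inheritParams reaction_rates
#' @return Named numeric derivative vector over the four fractions.
#' @export
ode_rhs <- function(state, params, genotype = strain_genotype("WT"),
                    condition = NULL) {
  r <- reaction_rates(state, params, genotype, condition)
  tot <- params$totals
  imb <- c(ptsP_p = r[["r1"]] - r[["r2"]],
           ptsO_p = r[["r2"]] - r[["r3"]],
           ptsN_p = r[["r3"]] + r[["r5"]],
           fruB_p = r[["r4"]] - r[["r5"]] - r[["r_fru"]])
  zero_tot <- tot == 0
  if (any(zero_tot)) {
    if (any(abs(imb[zero_tot]) > 0)) {
      warning("protein(s) with zero total carry a rate imbalance; ",
              "derivative pinned to 0", call. = FALSE)
    }
    imb[zero_tot] <- 0
    tot[zero_tot] <- 1
  }
  imb / as.numeric(tot)
}

# Proteins whose fraction is actually determined by the active reaction set:
# a protein is "live" if at least one of its reactions is intact.
protein_reactions <- list(ptsP_p = c("r1", "r2"), ptsO_p = c("r2", "r3"),
                          ptsN_p = c("r3", "r5"),
                          fruB_p = c("r4", "r5", "r_fru"))

live_proteins <- function(removed, totals) {
  vapply(seq_along(protein_reactions), function(i) {
    totals[i] > 0 && length(setdiff(protein_reactions[[i]], removed)) > 0
  }, logical(1))
}

# Detailed-balance closed form: equilibrium fraction of each protein when
# no reaction carries flux.  Along any intact path from PEP the
# phosphorylation ratio X^P/X equals pp divided by the product of the
# path's equilibrium constants; ratios propagate in both directions along
# intact reactions (a protein downstream of a break still equilibrates
# backward against its phosphorylated neighbour).  Returns NULL when no
# flux-free solution applies (r_fru > 0 on an intact uptake path, or an
# intact cycle that is not thermodynamically closed).
detailed_balance_state <- function(params, removed, initial = rep(0, 4)) {
  if (params$r_fru > 0 && !("r_fru" %in% removed)) return(NULL)
  active <- setdiff(PTS_REACTIONS, removed)
  full_cycle <- all(c("r1", "r2", "r3", "r4", "r5") %in% active)
  if (full_cycle && !is_thermo_closed(params)) return(NULL)
  K <- params$K
  pp <- params$pp
  # q = X^P/X equilibrium ratios; propagate to a fixpoint over the intact
  # reaction edges (PEP, 'P', 'O', 'N', 'B' with q_PEP = pp known)
  q <- c(P = NA_real_, O = NA_real_, N = NA_real_, B = NA_real_)
  edges <- list(r1 = c("PEP", "P", K[["K1"]]), r2 = c("P", "O", K[["K2"]]),
                r3 = c("O", "N", K[["K3"]]), r4 = c("PEP", "B", K[["K4"]]),
                r5 = c("B", "N", K[["K5"]]))
  getq <- function(node) if (node == "PEP") pp else q[[node]]
  setq <- function(node, val) if (node != "PEP") q[node] <<- val
  repeat {
    changed <- FALSE
    for (rn in intersect(names(edges), active)) {
      e <- edges[[rn]]
      Ki <- as.numeric(e[3])
      qa <- getq(e[1]); qb <- getq(e[2])
      if (!is.na(qa) && is.na(qb)) { setq(e[2], qa / Ki); changed <- TRUE }
      if (is.na(qa) && !is.na(qb)) { setq(e[1], qb * Ki); changed <- TRUE }
    }
    if (!changed) break
  }
  x <- ifelse(is.na(q), as.numeric(initial), q / (1 + q))
  stats::setNames(x, PTS_PROTEINS_P)
}

#' Steady state of the phosphorelay
#'
#' Solves the four protein balances for the phosphorylated fractions at
#' pseudo-steady state.  When no reaction carries flux (`r_fru = 0` on the
#' effective reaction set and the cycle is thermodynamically closed) the
#' detailed-balance closed form is used: along any intact path from PEP the
#' phosphorylation ratio equals `pp` divided by the product of the path's
#' equilibrium constants; proteins unreachable from PEP keep their initial
#' value (their reactions are frozen).  Otherwise a damped Newton iteration
#' on the live protein fractions is used, with a long-time ODE integration
#' fallback.
#'
#' @inheritParams reaction_rates
#' @param initial starting fractions (default all 0, the unphosphorylated
#'   pool the frozen-dynamics convention assumes).
#' @param tol convergence tolerance on `max |ode_rhs|`.
#' @return A [pts_state()] with `max |ode_rhs| < tol`.
#' @examples
#' p <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6, pp = 1)
#' steady_state(p, strain_genotype("WT"), growth_condition("CAA"))
#' @export
steady_state <- function(params, genotype = strain_genotype("WT"),
                         condition = NULL, initial = rep(0, 4),
                         tol = 1e-10) {
  validate_pts_parameters(params)
  params <- apply_condition(params, condition)
  removed <- effective_removed(genotype, condition)
  if (params$r_fru > 0 && !is.null(condition) && !condition$fruB_induced) {
    stop("r_fru > 0 requires an induced fru operon", call. = FALSE)
  }

  db <- detailed_balance_state(params, removed, initial)
  if (!is.null(db)) {
    geno_eff <- genotype_with_removed(genotype, removed)
    if (max(abs(ode_rhs(db, params, geno_eff))) < tol) {
      return(structure(db, class = "pts_state"))
    }
    # e.g. a disconnected component started away from its internal
    # equilibrium: fall through to the numeric solver
  }

  live <- live_proteins(removed, params$totals)
  x <- as.numeric(initial)
  f_live <- function(xl) {
    x[live] <- pmin(pmax(xl, 0), 1)  # guard finite-difference excursions
    ode_rhs(x, params, genotype_with_removed(genotype, removed))[live]
  }
  sol <- damped_newton(f_live, pmin(pmax(x[live], 0.05), 0.95), tol = tol)
  if (!sol$converged) {
    # fall back: integrate the ODE a long way, then polish
    traj <- simulate_timecourse(x, params,
                                genotype_with_removed(genotype, removed),
                                t_grid = c(0, 10^seq(0, 6, by = 1)))
    xT <- as.numeric(traj[nrow(traj), PTS_PROTEINS_P])
    sol <- damped_newton(f_live, xT[live], tol = tol)
    if (!sol$converged) {
      stop(sprintf(paste0("steady-state solve did not converge ",
                          "(max residual %.3e after Newton + integration)"),
                   sol$resid), call. = FALSE)
    }
  }
  x[live] <- sol$x
  x <- pmin(pmax(x, 0), 1)
  structure(stats::setNames(x, PTS_PROTEINS_P), class = "pts_state")
}

PTS_PROTEINS_P <- c("ptsP_p", "ptsO_p", "ptsN_p", "fruB_p")

# genotype whose removed set is overridden (used to pass the effective,
# condition-aware removals down to reaction_rates once computed)
genotype_with_removed <- function(genotype, removed) {
  structure(list(label = genotype$label, removed_reactions = removed),
            class = "strain_genotype")
}

# Damped Newton with a finite-difference Jacobian and step halving that
# keeps fractions inside [0, 1].
damped_newton <- function(f, x0, tol = 1e-10, maxit = 200L) {
  x <- x0
  n <- length(x)
  if (n == 0L) return(list(x = x, converged = TRUE, resid = 0))
  fx <- f(x)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) return(list(x = x, converged = TRUE,
                                        resid = max(abs(fx))))
    J <- matrix(0, n, n)
    h <- 1e-7
    for (j in seq_len(n)) {
      xp <- x
      xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - fx) / h
    }
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, converged = FALSE,
                                 resid = max(abs(fx))))
    step <- 1
    repeat {
      xn <- pmin(pmax(x + step * dx, 0), 1)
      fn <- f(xn)
      if (max(abs(fn)) < max(abs(fx)) || step < 1e-10) break
      step <- step / 2
    }
    if (max(abs(fn)) >= max(abs(fx))) {
      return(list(x = x, converged = max(abs(fx)) < tol,
                  resid = max(abs(fx))))
    }
    x <- xn
    fx <- fn
  }
  list(x = x, converged = max(abs(fx)) < tol, resid = max(abs(fx)))
}

#' Simulate the relay's phosphorylation dynamics
#'
#' Integrates the four-fraction ODE system with `deSolve::ode` (lsoda).
#'
#' @inheritParams reaction_rates
#' @param initial initial fractions (length 4).
#' @param t_grid increasing vector of output times.
#' @return A data frame with columns `time`, `ptsP_p`, `ptsO_p`, `ptsN_p`,
#'   `fruB_p`; the trajectory stays inside the unit box.
#' @export
simulate_timecourse <- function(initial, params,
                                genotype = strain_genotype("WT"),
                                t_grid, condition = NULL) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  params <- apply_condition(params, condition)
  removed <- effective_removed(genotype, condition)
  geno <- genotype_with_removed(genotype, removed)
  deriv <- function(t, y, parms) {
    list(as.numeric(ode_rhs(pmin(pmax(y, 0), 1), params, geno)))
  }
  out <- deSolve::ode(y = stats::setNames(as.numeric(initial),
                                          PTS_PROTEINS_P),
                      times = t_grid, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  if (attr(out, "istate")[1] < 0) {
    stop("stiff-solver failure for parameter set: pp=", params$pp,
         " r_fru=", params$r_fru, call. = FALSE)
  }
  as.data.frame(out)
}

#' Scale a parameter set on the protein totals
#'
#' Divides each protein pool by its total so all totals become 1; velocity
#' constants are rescaled to leave every net rate (and hence all steady
#' states and fluxes) unchanged.  The bimolecular rate laws mix pairs of
#' proteins, so `k2`, `k3`, `k5` absorb the donor's total while `k1`, `k4`
#' absorb the acceptor's.
#'
#' @param params a [pts_parameters()] object with positive totals.
#' @return A [pts_parameters()] object with unit totals and identical
#'   steady-state behaviour (rates are reported per original units).
#' @export
scale_on_totals <- function(params) {
  tot <- params$totals
  if (any(tot <= 0)) stop("all totals must be > 0 to scale", call. = FALSE)
  k <- params$k
  # concentrations X = x * X0; each rate has a product of at most two pools
  k[["k1"]] <- k[["k1"]] * tot[["ptsP0"]]
  k[["k2"]] <- k[["k2"]] * tot[["ptsP0"]] * tot[["ptsO0"]]
  k[["k3"]] <- k[["k3"]] * tot[["ptsO0"]] * tot[["ptsN0"]]
  k[["k4"]] <- k[["k4"]] * tot[["fruB0"]]
  k[["k5"]] <- k[["k5"]] * tot[["fruB0"]] * tot[["ptsN0"]]
  pts_parameters(k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]],
                 k4 = k[["k4"]], k5 = k[["k5"]],
                 K1 = params$K[["K1"]], K2 = params$K[["K2"]],
                 K3 = params$K[["K3"]], K4 = params$K[["K4"]],
                 K5 = params$K[["K5"]],
                 pp = params$pp, r_fru = params$r_fru)
}
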