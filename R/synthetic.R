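# Synthetic data: phosphorylation datasets with the study's error
# structure, jittered flux tables, and a toy central-carbon network, so
# every pipeline stage is testable without external measurements.

#' Synthetic measurement design
#'
#' Bundles the strain x condition grid, the ground-truth parameters, the
#' relative-noise level and the seed that make a generated dataset
#' reproducible.  Relative errors of the underlying measurements are
#' reported as 5-30%, so `rel_error` must stay in `[0.05, 0.30]` unless
#' `allow_any_noise` is set.
#'
#' @param design strain x condition table, see [default_design()].
#' @param truth ground-truth generating parameters: list with `Keq`, `K5`,
#'   `k4` and a named `pp` vector per condition.
#' @param rel_error relative noise (scalar or one value per design row).
#' @param seed integer seed.
#' @param noise `"gaussian"` (multiplicative, truncated to `[0, 1]`) or
#'   `"beta"` (matched mean and relative sd).
#' @param allow_any_noise allow `rel_error` outside the reported 5-30% band
#'   (used for noiseless round-trip checks).
#' @return A list of class `"synthetic_design"`.
#' @export
synthetic_design <- function(design = default_design(),
                             truth = list(Keq = PTS_DEFAULT_KEQ,
                                          K5 = PTS_DEFAULT_K5,
                                          k4 = PTS_CALIBRATED_K4,
                                          pp = c(CAA = 1.0,
                                                 CAA_fructose = 0.49,
                                                 CAA_glucose = 0.05)),
                             rel_error = 0.05, seed = 1,
                             noise = c("gaussian", "beta"),
                             allow_any_noise = FALSE) {
  noise <- match.arg(noise)
  rel_error <- rep(rel_error, length.out = nrow(design))
  if (!allow_any_noise &&
      any(rel_error < 0.05 - 1e-12 | rel_error > 0.30 + 1e-12)) {
    stop("rel_error outside the reported 5-30% band; set allow_any_noise ",
         "to override", call. = FALSE)
  }
  missing_pp <- setdiff(unique(design$condition), names(truth$pp))
  if (length(missing_pp) > 0) {
    stop("truth$pp missing condition(s): ",
         paste(missing_pp, collapse = ", "), call. = FALSE)
  }
  structure(list(design = design, truth = truth, rel_error = rel_error,
                 seed = seed, noise = noise),
            class = "synthetic_design")
}

# run code under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic phosphorylation dataset
#'
#' Computes the forward steady-state PtsN fraction for every design cell
#' and adds multiplicative noise: Gaussian `value * (1 + rel_error * z)`
#' truncated to `[0, 1]`, or a beta draw with matched mean and relative
#' standard deviation.  Deterministic given the design's seed.
#'
#' @param sdesign a [synthetic_design()].
#' @return A data frame of measurements with columns `strain`, `condition`,
#'   `ptsN_fraction`, `rel_error`.
#' @examples
#' head(generate_phospho_dataset(synthetic_design(seed = 42)))
#' @export
generate_phospho_dataset <- function(sdesign) {
  stopifnot(inherits(sdesign, "synthetic_design"))
  d <- sdesign$design
  tr <- sdesign$truth
  truth_vals <- vapply(seq_len(nrow(d)), function(i) {
    v <- predict_cell(d$strain[i], d$condition[i],
                      unname(tr$pp[d$condition[i]]), d$r_fru[i],
                      d$fruB_induced[i], tr$Keq, tr$K5, tr$k4)
    if (!is.finite(v)) {
      stop("steady-state solve failed for cell ", d$strain[i], "/",
           d$condition[i], call. = FALSE)
    }
    v
  }, numeric(1))
  rel <- sdesign$rel_error
  noisy <- with_local_seed(sdesign$seed, {
    if (all(rel == 0)) truth_vals
    else if (sdesign$noise == "gaussian") {
      pmin(pmax(truth_vals * (1 + rel * stats::rnorm(length(truth_vals))),
                0), 1)
    } else {
      vapply(seq_along(truth_vals), function(i) {
        m <- truth_vals[i]
        s <- rel[i] * m
        if (m <= 0 || m >= 1 || s == 0) return(m)
        nu <- m * (1 - m) / s^2 - 1
        if (nu <= 0) return(min(max(m * (1 + rel[i] * stats::rnorm(1)), 0), 1))
        stats::rbeta(1, m * nu, (1 - m) * nu)
      }, numeric(1))
    }
  })
  data.frame(strain = d$strain, condition = d$condition,
             ptsN_fraction = noisy, rel_error = rel,
             stringsAsFactors = FALSE)
}

#' Jitter a node flux table
#'
#' Multiplies the nominal fluxes by `1 + rel_jitter * z` (seeded) and
#' rescales the min/max envelope proportionally, so the variability
#' sandwich `min <= nominal <= max` is preserved by construction.
#'
#' @param base a flux table like [node_flux_table()] (`nominal` nonzero).
#' @param rel_jitter relative jitter (0 returns `base` unchanged).
#' @param seed integer seed.
#' @return A flux table of the same shape.
#' @export
generate_flux_table <- function(base = node_flux_table(), rel_jitter = 0,
                                seed = 1) {
  if (any(base$nominal == 0)) {
    stop("base table must have nonzero nominal fluxes", call. = FALSE)
  }
  if (rel_jitter == 0) return(base)
  out <- base
  fac <- with_local_seed(seed,
                         1 + rel_jitter * stats::rnorm(nrow(base)))
  fac <- pmax(fac, 0.01)
  out$nominal <- base$nominal * fac
  out$min <- base$min * fac
  out$max <- base$max * fac
  out$min <- pmin(out$min, out$nominal)
  out$max <- pmax(out$max, out$nominal)
  out
}

#' Toy central-carbon network around the PEP/pyruvate hub
#'
#' A ~15-reaction network mirroring the organism's central topology at
#' desk scale: fructose enters by PTS uptake (consuming PEP to pyruvate,
#' feeding upper glycolysis), glucose enters upper glycolysis directly,
#' casamino acids enter at oxaloacetate, PEP and pyruvate interconvert
#' (pyruvate kinase down, PEP synthase up), pyruvate drains to acetyl-CoA
#' and energy, gluconeogenesis runs PEP to upper glycolysis at ATP cost,
#' and a biomass reaction draws on all precursors plus ATP.  A maintenance
#' (NGAM) drain burns ATP at a fixed lower bound.
#'
#' @param fructose_ub,glucose_ub,caa_ub uptake capacity bounds
#'   (mmol/gDW/h style units).
#' @param ngam maintenance flux (lower bound of the ATP drain).
#' @return A [metabolic_network()] with designated biomass, NGAM and
#'   uptake reactions.
#' @export
make_toy_network <- function(fructose_ub = 10, glucose_ub = 0, caa_ub = 10,
                             ngam = 0) {
  rx <- data.frame(
    id = c("R_fruPTS", "R_glcED", "EX_caa", "R_aa_oaa", "R_oaa_pyr",
           "R_emp", "R_gng", "R_pyk", "R_pps", "R_pc", "R_pdh", "R_tca",
           "R_ngam", "R_biomass"),
    equation = c(
      "pep -> upper + pyr",          # PTS: fructose in, PEP -> pyruvate
      "-> upper",                    # glucose via the ED route (lumped)
      "-> aa",                       # casamino acid uptake
      "aa -> oaa",                   # CAA enters at oxaloacetate
      "oaa -> pyr",                  # main input flux to the node
      "upper -> 2 pep",              # lower glycolysis
      "2 pep + atp -> upper",        # gluconeogenesis (PEP upward)
      "pep -> pyr + atp",            # pyruvate kinase
      "pyr + 2 atp -> pep",          # PEP synthase (ATP -> AMP: 2 ATP
                                     # equivalents)
      "pep -> oaa",                  # anaplerosis
      "pyr -> accoa",                # drain to acetyl-CoA
      "accoa -> 2 atp",              # lumped TCA / respiration
      "atp ->",                      # non-growth-associated maintenance
      "0.2 upper + 0.3 pep + 0.3 pyr + 0.2 oaa + 0.3 accoa + 1.5 atp ->"),
    lb = c(rep(0, 12), ngam, 0),
    ub = c(fructose_ub, glucose_ub, caa_ub, rep(1000, 11)),
    stringsAsFactors = FALSE)
  metabolic_network(rx, biomass = "R_biomass", ngam = "R_ngam",
                    uptakes = c("R_fruPTS", "R_glcED", "EX_caa"))
}

#' Check that a network cannot create mass from nothing
#'
#' Closes every designated uptake reaction and verifies that neither the
#' biomass flux nor any energy-dissipating cycle can run: the maximum
#' biomass and maximum NGAM fluxes must both be zero.
#'
#' @param network a [metabolic_network()].
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly, or an error describing the inconsistency.
#' @export
check_stoichiometric_consistency <- function(network, tol = 1e-8) {
  closed <- network
  for (u in network$uptakes) {
    closed$lb[u] <- 0
    closed$ub[u] <- 0
  }
  if (!is.null(closed$ngam)) closed$lb[closed$ngam] <- 0
  targets <- c(closed$biomass, closed$ngam)
  for (tg in targets) {
    sol <- solve_fba(closed, objective_reaction = tg, sense = "max")
    if (sol$status != "optimal" || sol$objective > tol) {
      stop("network can drive ", tg, " with all uptakes closed ",
           "(objective ", signif(sol$objective, 4), ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}
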