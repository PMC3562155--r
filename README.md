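# ptsflux

Phosphoryl-flux analysis of the two phosphotransferase system (PTS)
branches of *Pseudomonas putida*.

*P. putida* carries a fructose-uptake PTS branch (PEP → FruB → fructose)
and a regulatory branch (PEP → PtsP → PtsO → PtsN) that exchange
phosphoryl groups by direct cross talk between FruB and PtsN.  `ptsflux`
is for systems biologists who want to work with this signaling unit
quantitatively: it couples

- a **mass-action phosphorelay model** — one reversible transfer
  reaction per step, `r_i = k_i (X^P Y − K_i X Y^P)`, protein
  conservation, strain knockouts, and steady-state solving, with the
  thermodynamic cycle constraint `Keq = K1·K2·K3 = K4·K5`;
- **constraint-based estimation** of the equilibrium constants and the
  per-condition PEP/pyruvate ratios `pp` from strain × condition PtsN
  phosphorylation fractions (the relay maps `pp` to the PtsN state via
  `PtsN^P/PtsN0 = q/(1+q)`, `q = pp/Keq`), including prediction for
  held-out conditions;
- the **branch flux decomposition** at steady state, quantifying how
  much of the phosphoryl demand of fructose uptake is supplied by the
  regulatory branch through cross talk;
- a small-scale **FBA/FVA engine** with growth-constrained uptake
  minimization, NGAM calibration against a measured uptake, a
  virtual-carbon casamino-acid feed, and flux-variability summaries;
- **metabolic control analysis** utilities (structural rank via maximum
  bipartite matching, concentration control coefficients from
  `ε dc/du = −N_u⁻¹ N_kn β`) and the **two-point power-law
  characterization** of the PEP/pyruvate node
  (`r_c = k_c Pyr^{n_c}`, `r_d = k_d PEP^{n_d}`);
- a **synthetic-data generator** reproducing the measurement layout and
  its 5–30% relative error structure, so the whole pipeline is testable
  without wet-lab data.

## Worked example

Fit the relay to a synthetic dataset generated at the fitted constants
(`Keq = 0.02`, `K5 = 654.6`, `pp` of 1, 0.49 and 0.05 on CAA,
CAA+fructose and CAA+glucose), then decompose the wild-type branch
fluxes:

```r
library(ptsflux)

dat <- generate_phospho_dataset(synthetic_design(rel_error = 0,
                                                 allow_any_noise = TRUE))
fit <- fit_equilibrium_constants(dat)
fit
#> PTS equilibrium-constant fit
#>   Keq = 0.02   K5 = 654.6   (K4 = Keq/K5 = 3.055e-05)
#>   pp:  CAA = 1   CAA_fructose = 0.49   CAA_glucose = 0.05
#>   nuisance k4 = 154.8;  mean relative residual = 0.000

predict_ptsN(fit, "WT", "CAA_glucose")
#> [1] 0.7142857

steady_branch_fluxes(default_pts_parameters(), pp = 0.49, r_fru = 0.05)
#> PTS branch flux decomposition
#>     r1     r2     r3     r4     r5  r_fru
#>  0.039  0.039  0.039  0.011 -0.039  0.050
#>   Ntr share (r3/r_fru): 0.7800   C share (r4/r_fru): 0.2200
```

Noiseless data round-trip exactly.  With realistic noise (5–30%
relative) a *single* fit scatters widely — the reference cells sit at
98% phosphorylation, which amplifies measurement noise roughly 25-fold
on the equilibrium constants — but the estimator is median-centred, so
medians over seed ensembles recover the generating values; the vignette
quantifies this.  The predicted wild-type PtsN phosphorylation on
glucose, 0.714, matches the measured 0.7 ± 0.03.  The branch
decomposition shows the headline mechanism: with the
weak cross talk (`K5 = 654.6`) the cycle constraint forces a tiny
`K4 = Keq/K5`, FruB sits above 99% phosphorylated
(`fruB_quasi_equilibrium_fraction(0.02, 654.6, 0.49)` ≈ 0.9999), the
direct PEP → FruB flux is throttled, and 78% of the phosphoryl groups
for fructose uptake arrive through the regulatory branch.

The node kinetics follow from two printed operating points:

```r
fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
#> power-law fit of the PEP/pyruvate node
#>   PEP synthase (rc):     kc = 1  nc = 1 (fixed)
#>   gluconeogenetic (rd):  kd = 2.625  nd = 0.3038
#>   alpha = kc/kd = 0.3809   n' = 1/nd - 1/nc = 2.292
```

`run_pipeline(pipeline_config(out_dir = "run1", seed = 42))` chains all
stages (synthesize → fit → predict → FBA/FVA → power law → branch
fluxes) and writes the tables and a run log to `run1/`.

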