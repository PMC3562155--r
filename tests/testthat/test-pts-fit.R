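# Equilibrium relations, parameter recovery and prediction.

test_that("equilibrium relations reproduce the published restriction table", {
  rel <- function(s, c) equilibrium_relations(s, c)
  expect_setequal(rel("WT", "CAA")$equilibrium, c("r1", "r2", "r3"))
  expect_setequal(rel("delta_ptsP", "CAA")$equilibrium,
                  c("r3", "r4", "r5"))
  expect_setequal(rel("delta_ptsO", "CAA")$equilibrium,
                  c("r1", "r4", "r5"))
  expect_setequal(rel("delta_fruB", "CAA")$equilibrium, c("r1", "r2", "r3"))
  expect_setequal(rel("delta_ptsP", "CAA_fructose")$equilibrium,
                  c("r3", "r5"))
  expect_setequal(rel("delta_ptsO", "CAA_fructose")$equilibrium,
                  c("r1", "r5"))
  expect_setequal(rel("delta_fruB", "CAA_fructose")$equilibrium,
                  c("r1", "r2", "r3"))
  wt_fru <- rel("WT", "CAA_fructose")
  expect_length(wt_fru$equilibrium, 0)
  expect_true(wt_fru$no_equilibrium)
  expect_true("r_fru" %in% wt_fru$flux_carrying)
})

test_that("noiseless synthetic data round-trips through the fit exactly", {
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0,
                                                   allow_any_noise = TRUE))
  fit <- fit_equilibrium_constants(dat)
  expect_equal(fit$Keq, default_truth$Keq, tolerance = 1e-6)
  expect_equal(fit$K5, default_truth$K5, tolerance = 1e-6)
  expect_equal(unname(fit$pp["CAA_fructose"]),
               unname(default_truth$pp["CAA_fructose"]), tolerance = 1e-6)
  expect_equal(unname(fit$pp["CAA_glucose"]),
               unname(default_truth$pp["CAA_glucose"]), tolerance = 1e-6)
  # the cycle constraint holds exactly by construction
  K <- fit$K
  expect_lt(abs(K[["K1"]] * K[["K2"]] * K[["K3"]] - K[["K4"]] * K[["K5"]]) /
              (K[["K4"]] * K[["K5"]]), 1e-9)
  expect_lt(fit$diagnostics$mean_rel_residual, 1e-8)
})

test_that("fit is invariant under the chain-split convention", {
  # only products of chain constants are identifiable from detailed
  # balance; quantities estimated from those cells cannot depend on how
  # Keq is allocated over K1, K2, K3
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0.05,
                                                   seed = 3))
  f1 <- fit_equilibrium_constants(dat)
  f2 <- fit_equilibrium_constants(dat,
                                  chain_split = c(0.5, 0.3, 0.2))
  expect_equal(f1$Keq, f2$Keq, tolerance = 1e-9)
  expect_equal(f1$pp[["CAA_glucose"]], f2$pp[["CAA_glucose"]],
               tolerance = 1e-9)
  # the flux-loaded wild-type cell feels individual chain constants
  # (finite displacement at every chain step), so quantities that lean on
  # it shift with the convention — by far less than their sampling spread
  expect_equal(f1$pp[["CAA_fructose"]], f2$pp[["CAA_fructose"]],
               tolerance = 0.25)
  # individual chain constants differ but their product is the same
  expect_equal(prod(f1$K[1:3]), prod(f2$K[1:3]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$K[["K1"]], f2$K[["K1"]])))
})

test_that("under-determined data raises an identifiability error", {
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0,
                                                   allow_any_noise = TRUE))
  no_caa <- dat[dat$condition != "CAA", ]
  expect_error(fit_equilibrium_constants(no_caa), "Keq")
  no_mut <- dat[!(dat$strain %in% c("delta_ptsP", "delta_ptsO") &
                    dat$condition == "CAA_fructose"), ]
  expect_error(fit_equilibrium_constants(no_mut), "K5")
  expect_error(estimate_pp(dat[dat$condition == "CAA", ],
                           list(Keq = 0.02, K5 = 654.6)), "pp")
})

test_that("measurement validation catches malformed rows", {
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0,
                                                   allow_any_noise = TRUE))
  bad <- dat
  bad$strain[1] <- "delta_unknown"
  expect_error(fit_equilibrium_constants(bad), "unknown strain")
  bad2 <- dat
  bad2$ptsN_fraction[2] <- 1.4
  expect_error(fit_equilibrium_constants(bad2), "\\[0, 1\\]")
})

test_that("estimate_pp recovers the ratios with constants fixed", {
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0,
                                                   allow_any_noise = TRUE))
  est <- estimate_pp(dat, list(Keq = default_truth$Keq,
                               K5 = default_truth$K5,
                               k4 = default_truth$k4))
  expect_equal(unname(est$pp["CAA_fructose"]), 0.49, tolerance = 1e-6)
  expect_equal(unname(est$pp["CAA_glucose"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(est$pp["CAA"]), 1.0)
  # fitted ratios are ordered as reported: CAA > CAA+fructose > glucose
  expect_gt(est$pp[["CAA"]], est$pp[["CAA_fructose"]])
  expect_gt(est$pp[["CAA_fructose"]], est$pp[["CAA_glucose"]])
})

test_that("optimizer objective trace is non-increasing", {
  dat <- generate_phospho_dataset(synthetic_design(rel_error = 0.10,
                                                   seed = 11))
  fit <- fit_equilibrium_constants(dat)
  trace <- fit$diagnostics$rsstrace
  expect_true(all(diff(trace) <= 1e-9))
})

test_that("moderate noise keeps the mean relative residual in band", {
  # reported residual level: mean about 10% of measured values when the
  # data carry 5-30% errors (averaged over seeds; single draws vary)
  resid <- vapply(1:5, function(s) {
    dat <- generate_phospho_dataset(synthetic_design(rel_error = 0.10,
                                                     seed = s))
    fit_equilibrium_constants(dat)$diagnostics$mean_rel_residual
  }, numeric(1))
  expect_lte(mean(resid), 0.15)
})

test_that("predictions reproduce the held-out glucose measurements", {
  est <- list(Keq = 0.02, K5 = 654.6,
              pp = c(CAA_glucose = 0.05, CAA_fructose = 0.49))
  # wild type on glucose: 0.714 against the measured 0.7 +/- 0.03
  expect_equal(predict_ptsN(est, "WT", "CAA_glucose"), 0.714,
               tolerance = 1e-3)
  # identical equations for the wild type and fruB mutant on plain CAA
  expect_equal(predict_ptsN(est, "WT", "CAA"),
               predict_ptsN(est, "delta_fruB", "CAA"))
  # no PtsN, no phosphorylation signal
  for (cond in c("CAA", "CAA_fructose", "CAA_glucose")) {
    expect_identical(predict_ptsN(est, "delta_ptsN", cond), 0)
  }
})

test_that("closed-form cell predictions agree with the generic solver", {
  Keq <- 0.02; K5 <- 654.6; k4 <- default_truth$k4
  p <- pts_parameters_from_constants(Keq = Keq, K5 = K5, k4 = k4)
  for (strain in c("WT", "delta_ptsP", "delta_ptsO", "delta_fruB")) {
    for (cond_label in c("CAA", "CAA_fructose", "CAA_glucose")) {
      cond <- growth_condition(cond_label)
      if (strain == "delta_fruB" && cond$r_fru > 0) {
        cond <- growth_condition(cond_label, r_fru = 0)
      }
      fast <- ptsflux:::predict_cell(strain, cond_label, cond$pp,
                                     cond$r_fru, cond$fruB_induced,
                                     Keq, K5, k4)
      slow <- unname(steady_state(p, strain_genotype(strain),
                                  cond)["ptsN_p"])
      expect_equal(fast, slow, tolerance = 1e-8,
                   label = paste(strain, cond_label))
    }
  }
})
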