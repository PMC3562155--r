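# Forward model: rate laws, knockouts, conservation, steady states.

test_that("mass-action rates match direct substitution and knockouts", {
  p <- pts_parameters(pp = 1)  # all k = K = totals = 1
  st0 <- pts_state(0, 0, 0, 0)
  r <- reaction_rates(st0, p, strain_genotype("WT"))
  # PEP = Pyr = 0.5; only the PEP-donor reactions can run from the
  # unphosphorylated state
  expect_equal(unname(r[c("r1", "r4")]), c(0.5, 0.5))
  expect_equal(unname(r[c("r2", "r3", "r5")]), c(0, 0, 0))

  # a deleted ptsP removes r1 and r2 identically
  for (st in list(st0, pts_state(0.3, 0.7, 0.2, 0.9))) {
    rko <- reaction_rates(st, p, strain_genotype("delta_ptsP"))
    expect_identical(unname(rko[c("r1", "r2")]), c(0, 0))
  }

  # detailed balance: each ratio X^P*Y = K_i X Y^P gives zero net rates
  pdb <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6, pp = 0.7)
  cond <- growth_condition("CAA_glucose", pp = 0.7)  # closed, no uptake
  stdb <- steady_state(pdb, strain_genotype("WT"), cond)
  rdb <- reaction_rates(stdb, pdb, strain_genotype("WT"), cond)
  expect_lt(max(abs(rdb)), 1e-12)
})

test_that("rate law rejects invalid states and inputs", {
  p <- pts_parameters()
  expect_error(reaction_rates(c(-0.2, 0, 0, 0), p), "fractions")
  expect_error(pts_parameters(pp = 0), "pp")
  expect_error(pts_parameters(K3 = -1), "equilibrium")
})

test_that("ode_rhs encodes the protein balances", {
  p <- pts_parameters(pp = 1)
  d <- ode_rhs(pts_state(0, 0, 0, 0), p, strain_genotype("WT"))
  expect_equal(unname(d["ptsP_p"]), 0.5)  # r1 - r2 = 0.5
  # ptsN deletion pins the PtsN derivative to zero for any state
  for (st in list(c(0.1, 0.9, 0.4, 0.6), c(0.5, 0.5, 0.5, 0.5))) {
    d2 <- ode_rhs(st, p, strain_genotype("delta_ptsN"))
    expect_identical(unname(d2["ptsN_p"]), 0)
  }
  # zero total pins the derivative (with a warning when an imposed flux
  # leaves an imbalance)
  p0 <- pts_parameters(pp = 1, fruB0 = 0, r_fru = 0.1)
  expect_warning(d3 <- ode_rhs(pts_state(0, 0, 0, 0), p0), "zero total")
  expect_identical(unname(d3["fruB_p"]), 0)
})

test_that("detailed-balance steady state follows pp and the K products", {
  # ptsN ratio along the chain is pp / (K1 K2 K3) regardless of k's and
  # totals
  for (seed in 1:5) {
    set.seed(seed)
    ks <- runif(5, 0.1, 10)
    tots <- runif(4, 0.2, 5)
    p <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6,
                                       k1 = ks[1], k2 = ks[2], k3 = ks[3],
                                       k4 = ks[4], k5 = ks[5],
                                       ptsP0 = tots[1], ptsO0 = tots[2],
                                       ptsN0 = tots[3], fruB0 = tots[4],
                                       pp = 1)
    st <- steady_state(p, strain_genotype("WT"), growth_condition("CAA"))
    expect_equal(unname(st["ptsN_p"]), 50 / 51, tolerance = 1e-10)
  }
  # the glucose prediction: pp = 0.05, Keq = 0.02 -> 2.5/3.5
  pg <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6, pp = 0.05)
  stg <- steady_state(pg, strain_genotype("WT"),
                      growth_condition("CAA_glucose"))
  expect_equal(unname(stg["ptsN_p"]), 2.5 / 3.5, tolerance = 1e-10)
})

test_that("wild-type steady state with uptake satisfies the flux identities", {
  p <- default_pts_parameters(pp = 0.49, r_fru = 0.05)
  geno <- strain_genotype("WT")
  st <- steady_state(p, geno)
  r <- reaction_rates(st, p, geno)
  expect_lt(abs(r[["r1"]] - r[["r2"]]), 1e-8)
  expect_lt(abs(r[["r2"]] - r[["r3"]]), 1e-8)
  expect_lt(abs(r[["r3"]] + r[["r5"]]), 1e-8)
  expect_lt(abs(r[["r4"]] - r[["r5"]] - 0.05), 1e-8)
})

test_that("steady state agrees with long-time ODE integration", {
  set.seed(42)
  for (i in 1:5) {
    ks <- runif(5, 0.5, 5)
    rf <- runif(1, 0, 0.03)
    p <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6,
                                       k1 = ks[1], k2 = ks[2], k3 = ks[3],
                                       k4 = ks[4] * 100, k5 = ks[5],
                                       pp = runif(1, 0.2, 2), r_fru = rf)
    st <- steady_state(p, strain_genotype("WT"))
    traj <- simulate_timecourse(rep(0.5, 4), p, strain_genotype("WT"),
                                t_grid = c(0, 10^(0:6)))
    final <- as.numeric(traj[nrow(traj), PTS_PROTEINS_P])
    expect_equal(as.numeric(st), final, tolerance = 1e-6)
  }
})

test_that("trajectories stay inside the unit box and honour knockouts", {
  p <- default_pts_parameters(pp = 0.49, r_fru = 0.02)
  traj <- simulate_timecourse(c(0, 0, 0, 0), p, strain_genotype("WT"),
                              t_grid = seq(0, 100, by = 1))
  vals <- as.matrix(traj[, PTS_PROTEINS_P])
  expect_true(all(vals >= -1e-9 & vals <= 1 + 1e-9))

  # a fruB deletion freezes the FruB fraction at its initial value
  trajB <- simulate_timecourse(c(0, 0, 0, 0.37), p,
                               strain_genotype("delta_fruB"),
                               t_grid = c(0, 1, 10, 100))
  expect_equal(trajB$fruB_p, rep(0.37, 4), tolerance = 1e-12)

  # starting at the steady state stays there
  st <- steady_state(default_pts_parameters(pp = 1), strain_genotype("WT"),
                     growth_condition("CAA"))
  traj2 <- simulate_timecourse(as.numeric(st),
                               default_pts_parameters(pp = 1),
                               strain_genotype("WT"), t_grid = c(0, 10, 50),
                               condition = growth_condition("CAA"))
  expect_equal(as.numeric(traj2[3, PTS_PROTEINS_P]), as.numeric(st),
               tolerance = 1e-8)
})

test_that("futile cycle appears exactly when the cycle constraint is broken", {
  # closed cycle, no uptake: every individual rate vanishes
  closed <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6,
                                          k4 = 50, pp = 1)
  st <- steady_state(closed, strain_genotype("WT"),
                     growth_condition("CAA_glucose", pp = 1))
  r <- reaction_rates(st, closed, strain_genotype("WT"))
  expect_lt(max(abs(r)), 1e-10)

  # break the closure by 20%: a steady cyclic flux r1 = r2 = r3 = -r5 = -r4
  open <- closed
  open$K[["K5"]] <- open$K[["K5"]] * 1.2
  st2 <- steady_state(open, strain_genotype("WT"),
                      growth_condition("CAA_glucose", pp = 1))
  r2 <- reaction_rates(st2, open, strain_genotype("WT"))
  expect_gt(abs(r2[["r1"]]), 1e-8)
  expect_equal(r2[["r2"]], r2[["r1"]], tolerance = 1e-8)
  expect_equal(r2[["r3"]], r2[["r1"]], tolerance = 1e-8)
  expect_equal(-r2[["r5"]], r2[["r1"]], tolerance = 1e-8)
  expect_equal(-r2[["r4"]], r2[["r1"]], tolerance = 1e-8)
})

test_that("scaling on totals preserves the steady state", {
  p <- pts_parameters_from_constants(Keq = 0.02, K5 = 654.6, k4 = 120,
                                     ptsP0 = 2, ptsO0 = 0.5, ptsN0 = 3,
                                     fruB0 = 1.4, pp = 0.49, r_fru = 0.04)
  ps <- scale_on_totals(p)
  expect_equal(unname(ps$totals), rep(1, 4))
  st <- steady_state(p, strain_genotype("WT"))
  sts <- steady_state(ps, strain_genotype("WT"))
  expect_equal(as.numeric(st), as.numeric(sts), tolerance = 1e-8)
})

test_that("uninduced fru operon freezes the C branch", {
  p <- default_pts_parameters(pp = 1)
  # a ptsP deletion on plain CAA leaves PtsN unreachable: fraction stays 0
  st <- steady_state(p, strain_genotype("delta_ptsP"),
                     growth_condition("CAA"))
  expect_equal(unname(st["ptsN_p"]), 0)
  # the same deletion with the operon induced equilibrates via cross talk
  st2 <- steady_state(p, strain_genotype("delta_ptsP"),
                      growth_condition("CAA_glucose", pp = 1))
  expect_equal(unname(st2["ptsN_p"]), 50 / 51, tolerance = 1e-9)
})
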