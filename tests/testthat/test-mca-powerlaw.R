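# Structural rank, concentration control coefficients and the power-law
# characterization of the PEP/pyruvate node.

test_that("structural rank matches brute force on the canonical patterns", {
  # one dependency column: rank one; diagonal pattern: invertible
  expect_identical(structural_rank(matrix(c(1, 1, 0, 0), 2)), 1L)
  expect_identical(structural_rank(diag(2)), 2L)
  expect_identical(structural_rank(matrix(0, 3, 3)), 0L)

  set.seed(13)
  for (i in 1:25) {
    nr <- sample(1:5, 1)
    nc <- sample(1:5, 1)
    P <- matrix(stats::rbinom(nr * nc, 1, 0.4), nr, nc)
    expect_identical(structural_rank(P), brute_structural_rank(P),
                     label = paste("pattern", i))
  }
})

test_that("control coefficients reproduce the reduced-node closed form", {
  fit <- fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
  for (k in c(0.2, 0.344, 0.6)) {
    ra <- 5
    prob <- reduced_node_problem(fit, ra, k)
    dc <- concentration_control(prob)
    ss <- reduced_steady_state(ra, k, fit)
    eps_c <- fit$nc * (1 - k) * ra / ss$Pyr
    eps_d <- fit$nd * (1 - k) * ra / ss$PEP
    expect_equal(unname(dc["PEP"]), (1 - k) / eps_d, tolerance = 1e-12)
    expect_equal(unname(dc["Pyr"]), (1 - k) / eps_c, tolerance = 1e-12)
  }
})

test_that("control coefficients agree with finite-difference perturbation", {
  set.seed(31)
  for (i in 1:5) {
    kd <- runif(1, 0.5, 4)
    nd <- runif(1, 0.2, 0.9)
    fit <- structure(list(kc = 1, nc = 1, kd = kd, nd = nd,
                          alpha = 1 / kd, n_prime = 1 / nd - 1),
                     class = "powerlaw_fit")
    k <- runif(1, 0.1, 0.7)
    ra <- runif(1, 2, 8)
    dc <- concentration_control(reduced_node_problem(fit, ra, k))
    h <- 1e-6 * ra
    up <- reduced_steady_state(ra + h, k, fit)
    dn <- reduced_steady_state(ra - h, k, fit)
    expect_equal(unname(dc["PEP"]), (up$PEP - dn$PEP) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(unname(dc["Pyr"]), (up$Pyr - dn$Pyr) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("singular elasticity patterns are rejected", {
  prob <- list(epsilon = matrix(c(1, 1, 0, 0), 2),
               N_u = diag(2), N_kn = diag(2), beta = c(1, 0))
  expect_error(concentration_control(prob), "structural")
  prob2 <- list(epsilon = matrix(c(0, 0, 0, 0), 2),
                N_u = diag(2), N_kn = diag(2), beta = c(1, 0))
  expect_error(concentration_control(prob2), "structural")
})

test_that("two-point power-law fit matches the printed calibration", {
  fit <- fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
  # the gluconeogenetic exponent comes out at 0.30 relative to PEP synthase
  expect_equal(round(fit$nd, 2), 0.30)
  # the closed form puts the companion rate constant near 2.6
  expect_equal(fit$kd, 2.625, tolerance = 0.01)
  expect_equal(fit$alpha * fit$kd, fit$kc, tolerance = 1e-12)
  expect_equal(fit$n_prime, 1 / fit$nd - 1 / fit$nc, tolerance = 1e-12)

  # both calibration points are interpolated exactly
  for (pt in list(c(4.00, 1.0), c(2.93, 0.49))) {
    pp <- fit$alpha^(1 / fit$nd) * (pt[1] / fit$kc)^fit$n_prime
    expect_equal(pp, pt[2], tolerance = 1e-12)
  }
})

test_that("power-law fit round-trips random generating parameters", {
  set.seed(5)
  for (i in 1:10) {
    kd <- runif(1, 0.2, 5)
    nd <- runif(1, 0.1, 2)
    rc <- sort(runif(2, 1, 10))
    pp <- (rc / kd)^(1 / nd) / rc  # PEP/Pyr with kc = nc = 1
    fit <- fit_powerlaw_two_points(c(rc[1], pp[1]), c(rc[2], pp[2]))
    expect_equal(fit$kd, kd, tolerance = 1e-10)
    expect_equal(fit$nd, nd, tolerance = 1e-10)
  }
  expect_error(fit_powerlaw_two_points(c(4, 1), c(4, 0.5)), "degenerate")
  expect_error(fit_powerlaw_two_points(c(-4, 1), c(2, 0.5)), "positive")
})

test_that("reduced steady state inverts the kinetics", {
  fit <- fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
  k <- 0.344
  ss <- reduced_steady_state(c(4.00, 2.93) / (1 - k), k, fit)
  expect_equal(ss$pp, c(1.0, 0.49), tolerance = 1e-10)

  # numeric root of rc(Pyr) = rd(PEP) with rc = (1 - k) ra agrees
  ra <- 5.5
  rc <- (1 - k) * ra
  pyr_root <- uniroot(function(x) fit$kc * x^fit$nc - rc, c(1e-6, 1e3),
                      tol = 1e-12)$root
  pep_root <- uniroot(function(x) fit$kd * x^fit$nd - rc, c(1e-6, 1e3),
                      tol = 1e-12)$root
  ss2 <- reduced_steady_state(ra, k, fit)
  expect_equal(ss2$Pyr, pyr_root, tolerance = 1e-8)
  expect_equal(ss2$PEP, pep_root, tolerance = 1e-8)

  # identity kinetics force PEP = Pyr for every input
  ident <- structure(list(kc = 1, nc = 1, kd = 1, nd = 1, alpha = 1,
                          n_prime = 0), class = "powerlaw_fit")
  ssi <- reduced_steady_state(c(1, 3, 7), 0.2, ident)
  expect_equal(ssi$pp, rep(1, 3))
  expect_error(reduced_steady_state(2, 1.2, fit), "k must lie")
})

test_that("monotonicity condition gates the slope of pp(ra)", {
  expect_true(monotonicity_condition(1, 0.30))
  expect_false(monotonicity_condition(1, 1))
  expect_false(monotonicity_condition(0.5, 1))

  fit <- fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
  grid <- seq(1, 12, by = 0.5)
  pp <- reduced_steady_state(grid, 0.344, fit)$pp
  expect_true(all(diff(pp) > 0))  # nc/nd > 1: strictly increasing

  flat <- structure(list(kc = 1, nc = 1, kd = 2, nd = 1, alpha = 0.5,
                         n_prime = 0), class = "powerlaw_fit")
  ppf <- reduced_steady_state(grid, 0.344, flat)$pp
  expect_true(all(abs(diff(ppf)) < 1e-12))  # boundary case: flat
})

test_that("characteristic curve carries its calibration points and band", {
  fit <- fit_powerlaw_two_points(c(4.00, 1.0), c(2.93, 0.49))
  k <- slope_k_from_conditions(node_flux_table())
  band <- slope_k_extremes(node_flux_table())
  ra_cal <- c(4.00, 2.93) / (1 - k)
  curve <- characteristic_curve(fit, k, band, sort(c(ra_cal,
                                                     seq(2, 10, 0.5))))
  at_cal <- curve[match(ra_cal, curve$ra), ]
  expect_equal(at_cal$pp, c(1.0, 0.49), tolerance = 1e-10)
  expect_true(all(curve$pp_lo <= curve$pp + 1e-12))
  expect_true(all(curve$pp_hi >= curve$pp - 1e-12))
  # the band collapses when the slope range is degenerate
  flat_band <- characteristic_curve(fit, k, c(k, k), seq(2, 8, 1))
  expect_equal(flat_band$pp_lo, flat_band$pp, tolerance = 1e-12)
  expect_equal(flat_band$pp_hi, flat_band$pp, tolerance = 1e-12)
  # band edges are valid monotone curves under nc/nd > 1
  lo_curve <- reduced_steady_state(seq(2, 8, 1), band[2], fit)$pp
  expect_true(all(diff(lo_curve) > 0))
})

test_that("drain slope from the printed fluxes is about 0.344", {
  k <- slope_k_from_conditions(node_flux_table())
  expect_equal(k, (2.32 - 1.76) / (6.32 - 4.69), tolerance = 1e-12)
  expect_equal(round(k, 3), 0.344)
  # identical drains across conditions give slope zero
  tab2 <- node_flux_table()
  tab2$nominal[tab2$condition == "CAA_fructose"] <-
    tab2$nominal[tab2$condition == "CAA"] - c(1, 0, 1, 0)
  expect_equal(slope_k_from_conditions(tab2), 0, tolerance = 1e-12)
  # equal input fluxes are degenerate
  tab3 <- node_flux_table()
  tab3$nominal[tab3$reaction == "oaa_to_pyr"] <- 5
  expect_error(slope_k_from_conditions(tab3), "slope undefined")
  # FVA extremes produce a finite band containing the nominal slope
  band <- slope_k_extremes(node_flux_table())
  expect_lt(band[1], k)
  expect_gt(band[2], k)
})
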