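# Linear programming, FBA procedures and FVA.

test_that("network parsing handles the equation dialect", {
  net <- metabolic_network(data.frame(
    id = c("r1", "r2", "ex"),
    equation = c("2 A + B -> C", "C -> 0.5 D", "-> A"),
    lb = 0, ub = 10, stringsAsFactors = FALSE))
  expect_equal(net$S["A", "r1"], -2)
  expect_equal(net$S["B", "r1"], -1)
  expect_equal(net$S["C", "r1"], 1)
  expect_equal(net$S["D", "r2"], 0.5)
  expect_equal(net$S["A", "ex"], 1)
  expect_error(metabolic_network(data.frame(
    id = "bad", equation = "A + -> B", lb = 0, ub = 1)), "malformed")
  expect_error(metabolic_network(data.frame(
    id = "b2", equation = "A -> B", lb = 2, ub = 1)), "bound")
})

test_that("FBA solves chains and flags contradictions", {
  net <- chain_network(uptake_ub = 10)
  sol <- solve_fba(net)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  expect_lt(max(abs(net$S %*% sol$fluxes)), 1e-9)

  # contradictory fixed constraints are infeasible, not silently zero
  bad <- solve_fba(net, fixed = c(up = 3, bio = 5))
  expect_identical(bad$status, "infeasible")
  net2 <- chain_network()
  net2$lb["conv"] <- 20  # lower bound above the uptake capacity
  expect_identical(solve_fba(net2)$status, "infeasible")
})

test_that("uptake minimization hits the analytic yield", {
  # biomass draws 0.3 pyr + 0.3 pep + ... on the toy network; use the
  # fully determined chain for the closed form instead
  net <- chain_network(uptake_ub = 50)
  sol <- minimize_substrate_uptake(net, 7)
  expect_equal(sol$objective, 7, tolerance = 1e-9)  # 1:1 stoichiometry

  # toy central-carbon network: uptake at zero growth covers only NGAM
  toy <- make_toy_network(fructose_ub = 0, caa_ub = 50, ngam = 0.8)
  s0 <- minimize_substrate_uptake(toy, 0, substrate = "EX_caa")
  # NGAM ATP comes from aa -> oaa -> pyr -> accoa -> 2 atp: 0.4 aa needed
  expect_equal(s0$objective, 0.4, tolerance = 1e-9)
  s00 <- minimize_substrate_uptake(set_ngam(toy, 0), 0,
                                   substrate = "EX_caa")
  expect_equal(s00$objective, 0, tolerance = 1e-12)
})

test_that("NGAM calibration inverts the uptake curve", {
  toy <- make_toy_network(fructose_ub = 0, caa_ub = 50)
  uptake_at <- function(g) {
    minimize_substrate_uptake(set_ngam(toy, g), 0.2,
                              substrate = "EX_caa")$objective
  }
  # uptake(NGAM) is affine on this network: slope 1/2 (2 ATP per aa)
  u <- vapply(c(0, 1, 2), uptake_at, numeric(1))
  expect_equal(diff(u), c(0.5, 0.5), tolerance = 1e-9)

  target <- uptake_at(1.3)
  ng <- calibrate_ngam(toy, 0.2, target, substrate = "EX_caa")
  expect_equal(as.numeric(ng), 1.3, tolerance = 1e-5)
  expect_equal(attr(ng, "uptake"), target, tolerance = 1e-6)

  # measured uptake at the NGAM = 0 minimum calibrates to zero
  ng0 <- calibrate_ngam(toy, 0.2, uptake_at(0), substrate = "EX_caa")
  expect_equal(as.numeric(ng0), 0)
  # a target below the NGAM = 0 minimum is impossible
  expect_error(calibrate_ngam(toy, 0.2, uptake_at(0) * 0.5,
                              substrate = "EX_caa"), "below")
  # monotone: larger measured uptake, larger calibrated NGAM
  ng_small <- calibrate_ngam(toy, 0.2, uptake_at(0.5),
                             substrate = "EX_caa")
  ng_large <- calibrate_ngam(toy, 0.2, uptake_at(2.5),
                             substrate = "EX_caa")
  expect_lt(as.numeric(ng_small), as.numeric(ng_large))
})

test_that("virtual carbon feed counts amino-acid carbons", {
  toy <- make_toy_network(fructose_ub = 0, caa_ub = 0)
  vc <- add_virtual_carbon(toy, c(aa = 5))
  expect_true("EX_carbon" %in% vc$rxns)
  expect_equal(vc$S["carbon", "VC_aa"], -5)
  expect_equal(vc$S["aa", "VC_aa"], 1)
  expect_error(add_virtual_carbon(toy, c(gly = 2)), "gly")
  expect_error(add_virtual_carbon(toy, c(aa = 2.5)), "integer")

  # minimized carbon equals carbon count times amino-acid demand
  sol <- minimize_substrate_uptake(set_ngam(vc, 1), 0,
                                   substrate = "EX_carbon")
  # NGAM 1 needs 0.5 aa -> 2.5 carbon
  expect_equal(sol$objective, 2.5, tolerance = 1e-9)
})

test_that("FVA brackets agree with brute-force vertex enumeration", {
  # a two-path redundancy: A can reach B via r_a or r_b
  net <- metabolic_network(data.frame(
    id = c("up", "ra", "rb", "bio"),
    equation = c("-> A", "A -> B", "A -> B", "B ->"),
    lb = 0, ub = c(6, 5, 5, 100), stringsAsFactors = FALSE),
    biomass = "bio", uptakes = "up")
  sol <- solve_fba(net)
  expect_equal(sol$objective, 6, tolerance = 1e-9)
  res <- fva(net, sol)
  verts <- enumerate_vertices(net, fixed = c(bio = 6))
  expect_false(is.null(verts))
  for (j in seq_along(net$rxns)) {
    rid <- net$rxns[j]
    row <- res[res$reaction == rid, ]
    expect_equal(row$min, min(verts[, rid]), tolerance = 1e-7)
    expect_equal(row$max, max(verts[, rid]), tolerance = 1e-7)
    expect_lte(row$min, row$nominal + 1e-7)
    expect_gte(row$max + 1e-7, row$nominal)
  }
  # the redundant pair spans [1, 5] while forced reactions are pinned
  expect_equal(res$min[res$reaction == "ra"], 1, tolerance = 1e-7)
  expect_equal(res$max[res$reaction == "ra"], 5, tolerance = 1e-7)
  expect_equal(res$min[res$reaction == "up"],
               res$max[res$reaction == "up"], tolerance = 1e-9)
})

test_that("FVA on the toy network keeps the objective at its optimum", {
  toy <- make_toy_network(fructose_ub = 0, caa_ub = 30, ngam = 0.5)
  sol <- minimize_substrate_uptake(toy, 0.2, substrate = "EX_caa")
  res <- fva(toy, sol)
  expect_true(all(res$min <= res$nominal + 1e-7))
  expect_true(all(res$max >= res$nominal - 1e-7))
  # every FVA extreme keeps the minimized uptake (and the growth
  # constraint) pinned
  expect_equal(res$min[res$reaction == "EX_caa"], sol$objective,
               tolerance = 1e-7)
  expect_equal(res$max[res$reaction == "EX_caa"], sol$objective,
               tolerance = 1e-7)
  expect_equal(res$min[res$reaction == "R_biomass"], 0.2,
               tolerance = 1e-7)
})

test_that("relative FVA ranges reproduce the published summary", {
  caa <- fva_relative_range(c(6.32, 1.83, 4.00, 3.73),
                            c(6.18, 1.68, 3.96, 3.68),
                            c(6.35, 1.85, 4.01, 3.78))
  expect_identical(caa, c(2.7, 9.3, 1.3, 2.7))
  fru <- fva_relative_range(c(4.69, 1.47, 2.93, 2.64),
                            c(4.59, 1.36, 2.90, 2.61),
                            c(4.71, 1.49, 2.97, 2.68))
  expect_identical(fru, c(2.6, 8.8, 2.4, 2.7))
  expect_identical(fva_relative_range(3.3, 3.3, 3.3), 0)
  expect_warning(z <- fva_relative_range(0, -1, 1), "undefined")
  expect_true(is.na(z))
})

test_that("toy network is stoichiometrically consistent and behaves", {
  net <- make_toy_network(ngam = 0.5)
  expect_true(check_stoichiometric_consistency(net))
  # growth on fructose alone is feasible
  fru <- make_toy_network(fructose_ub = 10, caa_ub = 0, ngam = 0.5)
  expect_identical(solve_fba(fru)$status, "optimal")
  expect_gt(solve_fba(fru)$objective, 0)
  # removing the pyruvate -> PEP reaction kills growth on CAA
  caa <- make_toy_network(fructose_ub = 0, caa_ub = 10, ngam = 0.5)
  caa$ub["R_pps"] <- 0
  expect_identical(minimize_substrate_uptake(caa, 0.2,
                                             substrate = "EX_caa")$status,
                   "infeasible")
})

test_that("network TSV round trip is lossless", {
  net <- make_toy_network(ngam = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path)
  expect_equal(back$S, net$S)
  expect_equal(back$lb, net$lb)
  expect_equal(back$ub, net$ub)
  expect_identical(back$biomass, net$biomass)
  expect_identical(back$ngam, net$ngam)
  expect_identical(back$uptakes, net$uptakes)
})
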