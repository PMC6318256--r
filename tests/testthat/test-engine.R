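test_that("fugacity capacities compose as volume-weighted phase sums", {
  ibu <- default_chemicals()[["IBU"]]
  ctx <- property_context(25, 7)
  expect_equal(z_water(), 1)
  expect_equal(z_solids(ibu, ctx, 0), 0)
  expect_equal(z_solids(ibu, ctx, 0.06, 2.4),
               0.06 * 0.46 * 10^1.23 * 2.4, tolerance = 1e-12)
  # doubling Koc doubles the solids capacity
  ibu2 <- ibu; ibu2$koc_kow_ratio <- 2 * ibu$koc_kow_ratio
  expect_equal(z_solids(ibu2, ctx, 0.06), 2 * z_solids(ibu, ctx, 0.06))
  env <- ns_env_cached()
  comp <- env$compartments
  cbz <- env$chemicals[["CBZ"]]
  zb_w <- z_bulk(comp[comp$id == "NL3", ], cbz, env)
  zb_s <- z_bulk(comp[comp$id == "ST", ], cbz, env)
  expect_gt(zb_w, z_water(cbz, env)) # sorbed term strictly positive
  expect_gt(zb_s, 10 * zb_w)         # sediment capacity dominated by Koc
  # phi_ss = 0 water reduces to pure water capacity
  w0 <- compartment_spec("W", "surface_water", volume = 1,
                         ss_volume_fraction = 0, photolysis_multiplier = 0)
  expect_equal(z_bulk(w0, cbz, env), z_water(cbz, env))
})

test_that("single-box steady state matches the closed form", {
  E <- 0.01; G <- 500
  env <- toy_one_box(E = E, G = G)
  res <- solve_steady_state(env)
  zb <- z_bulk(env$compartments[1, ], env$chemicals$PAR, env)
  expect_equal(res$table$fugacity, E / (G * zb), tolerance = 1e-12)
  # concentration is independent of the normalization constant
  expect_equal(res$table$concentration, E / G * 200 * 1e6, tolerance = 1e-9)
})

test_that("parent-product pair matches the 2x2 closed form", {
  E <- 0.01; G <- 500; V <- 1e4
  env <- toy_parent_tp(E = E, G = G, V = V)
  res <- solve_steady_state(env)
  zb_par <- z_bulk(env$compartments[1, ], env$chemicals$PAR, env)
  zb_tp <- z_bulk(env$compartments[1, ], env$chemicals$TP, env)
  k_par <- log(2) / combine_half_lives(c(100, 50))
  k_tp <- log(2) / 30
  D_par <- G * zb_par + k_par * V * zb_par
  f_par <- E / D_par
  D_form <- tp_yield(100, combine_half_lives(c(100, 50))) * k_par * V * zb_par
  f_tp <- f_par * D_form / (G * zb_tp + k_tp * V * zb_tp)
  tab <- res$table
  expect_equal(tab$fugacity[tab$chemical == "PAR"], f_par, tolerance = 1e-12)
  expect_equal(tab$fugacity[tab$chemical == "TP"], f_tp, tolerance = 1e-12)
})

test_that("system dimensions follow compartments x chain size", {
  env <- ns_env_cached()
  chains <- reaction_chains(names(env$chemicals), env$reactions)
  ibu_chain <- chains[[which(vapply(chains, function(c) "IBU" %in% c,
                                    logical(1)))]]
  sys <- assemble_system(env, ibu_chain)
  # 4 chemicals across the 14 packaged compartments
  expect_equal(dim(sys$A), c(56, 56))
  expect_equal(nrow(sys$index), 56)
})

test_that("structurally singular systems are reported with the culprit", {
  ch <- list(PAR = make_chem())
  comps <- compartment_spec("LONER", "surface_water", volume = 100,
                           photolysis_multiplier = 0)
  links <- data.frame() # no loss paths at all
  env <- environment_spec(comps,
                          flow_link("advection", "inflow", "LONER", rate = 0),
                          emission_spec("LONER", "PAR", mol_h = 1),
                          ch, no_reactions())
  expect_error(solve_steady_state(env), "LONER")
})

test_that("outputs are invariant to the water-capacity normalization", {
  env <- toy_three_box()
  res1 <- solve_steady_state(env)
  env$options$z_water <- 1000
  res2 <- solve_steady_state(env)
  expect_equal(res2$table$concentration, res1$table$concentration,
               tolerance = 1e-10)
  expect_equal(res2$table$mass_mol, res1$table$mass_mol, tolerance = 1e-10)
  # flux ledger invariant too (sediment/water ratios preserved)
  expect_equal(res2$ledger$flow_mol_h, res1$ledger$flow_mol_h,
               tolerance = 1e-10)
})

test_that("solution is linear in emissions and zero without them", {
  env <- toy_three_box(E = 0.02)
  base <- solve_steady_state(env)
  env4 <- toy_three_box(E = 0.08)
  expect_equal(solve_steady_state(env4)$table$fugacity,
               4 * base$table$fugacity, tolerance = 1e-12)
  env0 <- toy_three_box(E = 0)
  res0 <- solve_steady_state(env0)
  expect_true(all(res0$table$fugacity == 0))
  expect_true(all(res0$ledger$flow_mol_h == 0))
})

test_that("non-negative emissions give non-negative fugacities", {
  set.seed(42)
  for (i in 1:10) {
    E <- runif(1, 0, 1)
    env <- toy_three_box(E = E)
    # randomize some transport intensities
    env$links$rate[env$links$kind == "mixing"] <- runif(1, 1, 5000)
    res <- solve_steady_state(env)
    expect_true(all(res$table$fugacity >= 0))
  }
})

test_that("the flux ledger balances every chemical", {
  res <- solve_steady_state(toy_three_box())
  expect_true(all(res$residuals$residual < 1e-9))
  # parent moles lost to transformation equal product moles formed
  led <- res$ledger
  to_tp <- sum(led$flow_mol_h[led$chemical == "PAR" &
                                startsWith(led$kind, "reaction_") &
                                led$target == "TP"])
  formed <- res$residuals$inputs_mol_h[res$residuals$chemical == "TP"]
  expect_equal(to_tp, formed, tolerance = 1e-12)
})

test_that("steady state equals the dynamic long-time limit", {
  env <- toy_three_box()
  ss <- solve_steady_state(env)
  dyn <- dynamic_integrate(env, duration = 4000, n_out = 20)
  final <- dyn[dyn$time_h == max(dyn$time_h), ]
  key <- paste(ss$table$compartment, ss$table$chemical)
  fkey <- paste(final$compartment, final$chemical)
  expect_equal(final$fugacity[match(key, fkey)], ss$table$fugacity,
               tolerance = 1e-3)
  # zero emissions: any start decays to zero
  env0 <- toy_three_box(E = 0)
  f0 <- setNames(rep(1e-6, nrow(ss$table)),
                 paste(ss$table$compartment, ss$table$chemical, sep = "|"))
  dyn0 <- dynamic_integrate(env0, duration = 5e4, n_out = 10,
                            initial_fugacities = f0)
  final0 <- dyn0[dyn0$time_h == max(dyn0$time_h), ]
  expect_lt(max(final0$fugacity), 1e-9 * max(f0))
})

test_that("effluent-bearing lake compartments equilibrate within days", {
  env <- ns_env_cached()
  ss <- ns_result_cached()
  dyn <- dynamic_integrate(env, duration = 14 * 24, n_out = 14)
  final <- dyn[dyn$time_h == max(dyn$time_h), ]
  for (cc in c("NL2", "NL3", "SL2", "SL3")) {
    for (ch in c("IBU", "DCF", "CBZ")) {
      f_ss <- ss$table$fugacity[ss$table$compartment == cc &
                                  ss$table$chemical == ch]
      f_dyn <- final$fugacity[final$compartment == cc & final$chemical == ch]
      expect_gt(f_dyn, 0.99 * f_ss)
    }
  }
})
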