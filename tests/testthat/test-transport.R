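test_that("sinking average mixes each layer with the one above", {
  m <- matrix(c(10, 10, 10, 10, 0, 0, 100, 0), ncol = 2,
              dimnames = list(paste0("TL", 1:4), c("A", "B")))
  out <- sinking_average(m)
  expect_equal(out[, "A"], c(TL1 = 10, TL2 = 10, TL3 = 10, TL4 = 10))
  expect_equal(out[, "B"], c(TL1 = 0, TL2 = 0, TL3 = 50, TL4 = 50))
  # monotone profiles stay monotone
  mono <- matrix(c(1, 2, 5, 9), ncol = 1,
                 dimnames = list(paste0("TL", 1:4), "A"))
  expect_true(all(diff(sinking_average(mono)[, 1]) >= 0))
})

test_that("a zero input with no upstream products yields zero output", {
  env <- build_transport_env(1, 1, 300)
  input <- matrix(0, 4, 3, dimnames = list(paste0("TL", 1:4),
                                           c("IBU", "DCF", "CBZ")))
  seg <- run_segment(env, input)
  expect_true(all(seg$output == 0))
  expect_error(run_segment(env, matrix(1, 4, 1,
                                       dimnames = list(paste0("TL", 1:4),
                                                       "GHOST"))),
               "GHOST")
})

test_that("with reactions off and no burial the throughput is conserved", {
  env <- build_transport_env(1, 1, 3000, overrides = list(u_bur = 0),
                             reactions = no_reactions())
  input <- matrix(c(10, 20, 30, 40), 4, 1,
                  dimnames = list(paste0("TL", 1:4), "CBZ"))
  seg <- run_segment(env, input)
  adv <- env$links[env$links$kind == "advection" &
                     env$links$source == "inflow", ]
  G <- adv$rate[match(paste0("TL", 1:4), adv$target)]
  expect_equal(sum(G * seg$output[, 1]), sum(G * input[, 1]),
               tolerance = 1e-9)
})

test_that("a near-conservative tracer passes the deep layer almost unchanged", {
  # CBZ: no reactions below 5 m and weak photolysis above
  env <- build_transport_env(1, 1, 3000)
  ns <- ns_result_cached()
  input <- sinking_average(transport_input(ns))
  seg <- run_segment(env, input)
  expect_equal(seg$output["TL4", "CBZ"], input["TL4", "CBZ"],
               tolerance = 0.05)
})

test_that("parents fall while first-generation products can rise", {
  env <- build_transport_env(1, 1, 3000)
  ns <- ns_result_cached()
  input <- sinking_average(transport_input(ns))
  seg <- run_segment(env, input)
  expect_lt(max(seg$output[, "DCF"]), max(input[, "DCF"]))
  expect_gt(max(seg$output[, "IBAP"]), max(input[, "IBAP"]))
})

test_that("a pure decaying parent peaks at the chain origin", {
  env <- build_transport_env(1, 1, 3000)
  input <- matrix(c(5, 5, 5, 5), 4, 1,
                  dimnames = list(paste0("TL", 1:4), "DCF"))
  chain <- suppressWarnings(run_until_plateau(env, input, max_segments = 6,
                                              tp_ids = character()))
  pk <- chain$peaks[chain$peaks$chemical == "DCF", ]
  expect_equal(pk$peak_distance_m, 0)
  tr <- chain$trajectory[chain$trajectory$chemical == "DCF", ]
  expect_true(all(diff(tr$conc_max) < 0))
})

test_that("sequential-decay peak location matches the plug-flow closed form", {
  # single well-mixed layer so the discrete recursion has an analytic twin
  ch <- list(PAR = make_chem("PAR"), TP = make_chem("TP", mw = 180))
  reacts <- reaction_table(c("PAR", "TP"), c("TP", "other"),
                           c("photo", "photo"), c(300, 60))
  comps <- compartment_spec("TL1", "surface_water", volume = 3000 * 30,
                           temperature = 25, ph = 7,
                           ss_volume_fraction = 0, photolysis_multiplier = 1)
  G <- 36 * 30 # 1 cm/s through a 30 m2 cross-section
  links <- rbind(flow_link("advection", "inflow", "TL1", rate = G),
                 flow_link("advection", "TL1", "outflow", rate = G))
  emis <- data.frame(compartment = character(), chemical = character(),
                     water_flow = numeric(), mol_h = numeric())
  env <- environment_spec(comps, links, emis, ch, reacts,
                          options = list(scenario = "transport",
                                         velocity_cm_s = 1,
                                         segment_length = 3000))
  input <- matrix(c(100, 0), 1, 2, dimnames = list("TL1", c("PAR", "TP")))
  chain <- suppressWarnings(run_until_plateau(env, input, rel_tol = 0.005,
                                              max_segments = 40))
  k1 <- log(2) / 300; k2 <- log(2) / 60
  t_star <- log(k2 / k1) / (k2 - k1)  # h
  d_star <- t_star * 36               # m at 1 cm/s
  pk <- chain$peaks$peak_distance_m[chain$peaks$chemical == "TP"]
  expect_lt(abs(pk - d_star), max(3000, 0.25 * d_star))
})

test_that("conjugate pseudo-chemical plumbs deconjugation into the chain", {
  env <- add_conjugate(build_transport_env(1, 1, 3000))
  expect_true("IBU-CONJ" %in% names(env$chemicals))
  expect_error(add_conjugate(env), "already present")
  rx <- env$reactions[env$reactions$kind == "deconjugation", ]
  expect_identical(rx$product, "IBU")
  expect_equal(rx$half_life_h, 2)
  ns <- ns_result_cached()
  input <- conjugate_input(env, sinking_average(transport_input(ns)))
  expect_equal(input[, "IBU-CONJ"], 3 * input[, "IBU"])
  # factor 0 reproduces the conjugate-free run
  env0 <- add_conjugate(build_transport_env(1, 1, 3000), conc_factor = 0)
  in0 <- conjugate_input(env0, sinking_average(transport_input(ns)))
  seg0 <- run_segment(env0, in0)
  seg <- run_segment(build_transport_env(1, 1, 3000),
                     sinking_average(transport_input(ns)))
  expect_equal(seg0$output[, colnames(seg$output)], seg$output,
               tolerance = 1e-12)
  # parent + conjugate molar total never increases downstream
  env3 <- add_conjugate(build_transport_env(1, 1, 3000))
  in3 <- conjugate_input(env3, sinking_average(transport_input(ns)))
  chain <- suppressWarnings(run_until_plateau(env3, in3, max_segments = 8))
  tr <- chain$trajectory
  tot <- vapply(1:8, function(s) {
    sum(tr$water_mass_mol[tr$segment == s &
                            tr$chemical %in% c("IBU", "IBU-CONJ")])
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})
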