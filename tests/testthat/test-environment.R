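test_that("trapezoidal layer volumes interpolate width linearly", {
  # rectangular prism
  expect_equal(layer_volume(0, 0.1, 300, 200, 200, 25), 6000)
  # hand interpolation: widths 200->150 over 0-25 m, layer 1-5 m
  w <- function(d) 200 + (150 - 200) * d / 25
  expect_equal(layer_volume(1, 5, 300, 200, 150, 25),
               300 * mean(c(w(1), w(5))) * 4)
  expect_error(layer_volume(2, 2, 300, 200, 150, 25), "degenerate")
})

test_that("mixing rates derive from diffusivity or turnover time", {
  # (1e-4 m2/s / 0.5 m) * 1 m2 * 3600 s/h
  expect_equal(mixing_rate_from_diffusivity(1, 0.5, 1), 0.72)
  expect_equal(mixing_rate_from_diffusivity(1, 0.5, 2),
               2 * mixing_rate_from_diffusivity(1, 0.5, 1))
  expect_error(mixing_rate_from_diffusivity(1, 0, 1), "midpoint")
  expect_equal(mixing_rate_from_turnover(6000, 0.014), 6000 / 0.014)
  expect_equal(mixing_rate_from_turnover(1000, 20),
               2 * mixing_rate_from_turnover(1000, 40))
  expect_equal(mixing_rate_from_turnover(1000, Inf), 0)
  expect_error(mixing_rate_from_turnover(-1, 10), "must be > 0")
})

test_that("environment validation is exhaustive and catches broken plumbing", {
  comps <- rbind(
    compartment_spec("A", "surface_water", volume = 100,
                     photolysis_multiplier = 1),
    compartment_spec("B", "surface_water", volume = 100,
                     photolysis_multiplier = 0))
  ch <- list(PAR = make_chem())
  # unbalanced advection
  links <- rbind(flow_link("advection", "inflow", "A", rate = 10),
                 flow_link("advection", "A", "B", rate = 5),
                 flow_link("advection", "B", "outflow", rate = 5))
  expect_error(environment_spec(comps, links, emission_spec("A", "PAR",
                                                            mol_h = 1),
                                ch, no_reactions()),
               "hydraulic continuity")
  # unknown endpoint and unknown emission chemical reported together
  links2 <- rbind(flow_link("advection", "inflow", "A", rate = 10),
                  flow_link("advection", "A", "NOPE", rate = 10))
  err <- tryCatch(environment_spec(comps, links2,
                                   emission_spec("A", "GHOST", mol_h = 1),
                                   ch, no_reactions()),
                  error = conditionMessage)
  expect_match(err, "NOPE")
  expect_match(err, "GHOST")
  # disconnected water graph
  links3 <- rbind(flow_link("advection", "inflow", "A", rate = 10),
                  flow_link("advection", "A", "outflow", rate = 10))
  expect_error(environment_spec(comps, links3,
                                emission_spec("A", "PAR", mol_h = 1),
                                ch, no_reactions()),
               "disconnected")
})

test_that("the packaged N-S scenario is built to its stated structure", {
  env <- ns_env_cached()
  comp <- env$compartments
  expect_equal(sum(comp$medium == "surface_water"), 11) # NL1-5 + SL1-6
  expect_equal(sum(comp$medium == "bottom_sediment"), 3) # ST, SM, SB
  expect_equal(comp$photolysis_multiplier[comp$id == "NL3"], 0.01)
  expect_equal(comp$photolysis_multiplier[comp$id == "NL1"], 1)
  expect_equal(comp$photolysis_multiplier[comp$id == "NL4"], 0)
  # hydraulic continuity is a construction invariant (validated on build);
  # spot-check NL3 carries the effluent water downstream
  adv <- env$links[env$links$kind == "advection", ]
  in3 <- sum(adv$rate[adv$target == "NL3"]) + 1700
  out3 <- sum(adv$rate[adv$source == "NL3"])
  expect_equal(in3, out3, tolerance = 1e-12)
  # NL1 volume: 300 m x ~200 m x 0.1 m trapezoid
  w <- function(d) 200 - 50 * d / 15
  expect_equal(comp$volume[comp$id == "NL1"],
               300 * mean(c(w(0), w(0.1))) * 0.1)
  # epilimnion/hypolimnion temperature split
  expect_equal(comp$temperature[comp$id == "NL2"], 15)
  expect_equal(comp$temperature[comp$id == "SL5"], 5)
  expect_error(build_paijanne_ns(list(nonsense = 1)), "nonsense")
})

test_that("transport variants share structure and differ in scale", {
  weak <- build_transport_env(1, 1, 3000)
  strong <- build_transport_env(3, 10, 3000)
  short <- build_transport_env(1, 1, 300)
  expect_identical(weak$compartments$id, strong$compartments$id)
  expect_identical(weak$compartments$id, short$compartments$id)
  # velocities scale advection 3x
  adv_w <- weak$links[weak$links$kind == "advection", ]
  adv_s <- strong$links[strong$links$kind == "advection", ]
  expect_equal(adv_s$rate, 3 * adv_w$rate)
  # mixing scales with the tenfold factor
  mix_w <- weak$links$rate[weak$links$kind == "mixing"]
  mix_s <- strong$links$rate[strong$links$kind == "mixing"]
  expect_equal(mix_s, 10 * mix_w)
  # 300 m variant: volumes 10x smaller, same cross-sections
  expect_equal(short$compartments$volume[1:4],
               weak$compartments$volume[1:4] / 10)
  expect_equal(adv_w$rate,
               short$links$rate[short$links$kind == "advection"])
  expect_error(build_transport_env(0), "velocity")
})
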